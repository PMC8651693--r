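# Marker-based compartment assignment: k-means clustering of max-normalized
# fraction profiles, marker majority voting per cluster, and
# precision/recall/F scoring per compartment, plus marker-centroid profile
# correlation.

#' Normalize fraction profiles to the per-feature maximum
#'
#' Divides each feature's linear-scale fraction values by its maximum, so
#' every profile lies in `[0, 1]` with its dominant fraction at exactly 1.
#' All-zero features are dropped with a warning.
#'
#' @param profiles A tibble `feature`, `fraction`, `value` (linear scale,
#'   one row per feature x fraction; a `proportion` column from
#'   [scale_profiles()] is accepted as the value column).
#' @return The tibble with `value` replaced by the max-normalized value.
#' @export
max_normalize <- function(profiles) {
  profiles <- normalize_profile_cols(profiles)
  zero <- profiles |>
    group_by(.data$feature) |>
    summarise(mx = max(.data$value), .groups = "drop") |>
    filter(.data$mx <= 0)
  if (nrow(zero) > 0) {
    warn(sprintf("dropping %d all-zero feature(s)", nrow(zero)))
    profiles <- anti_join(profiles, zero, by = "feature")
  }
  profiles |>
    group_by(.data$feature) |>
    mutate(value = .data$value / max(.data$value)) |>
    ungroup()
}

normalize_profile_cols <- function(profiles) {
  if (!"value" %in% names(profiles) && "proportion" %in% names(profiles)) {
    profiles <- rename(profiles, value = "proportion")
  }
  stopifnot(all(c("feature", "fraction", "value") %in% names(profiles)))
  profiles
}

profile_matrix <- function(profiles) {
  wide <- profiles |>
    select("feature", "fraction", "value") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "value",
                       values_fill = 0)
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$feature
  mat
}

#' Cluster fraction profiles by k-means
#'
#' Standard Euclidean k-means on the feature x fraction profile matrix,
#' keeping the best of `restarts` random initializations by within-cluster
#' sum of squares; deterministic for a fixed seed.
#'
#' @param profiles A profile tibble (see [max_normalize()]).
#' @param k Number of clusters; the convention is twice the number of
#'   compartments so mixed profiles get their own groups.
#' @param restarts Random restarts (default 25).
#' @param seed Integer seed.
#' @return A tibble `feature`, `cluster` (integer labels 1..k).
#' @export
cluster_profiles <- function(profiles, k, restarts = 25, seed = 1) {
  profiles <- normalize_profile_cols(profiles)
  stopifnot(k >= 1, restarts >= 1)
  mat <- profile_matrix(profiles)
  if (k > nrow(mat)) {
    abort(sprintf("k = %d exceeds the number of features (%d)", k, nrow(mat)))
  }
  # Hartigan-Wong requires k < n; fall back to Lloyd for the degenerate
  # one-cluster-per-feature case
  algorithm <- if (k == nrow(mat)) "Lloyd" else "Hartigan-Wong"
  km <- withr::with_seed(seed, {
    kmeans(mat, centers = k, nstart = restarts, iter.max = 100,
           algorithm = algorithm)
  })
  tibble(feature = rownames(mat), cluster = as.integer(km$cluster))
}

#' Assign clusters to compartments by marker voting
#'
#' Each cluster is assigned to the compartment with the most marker proteins
#' inside it; every feature in the cluster inherits that compartment. The
#' cluster precision is the proportion of the cluster's markers that belong
#' to the winning compartment (two cytosol markers and nothing else gives
#' precision 1; two cytosol plus one nucleus marker still assigns cytosol,
#' at precision 2/3). Clusters with no markers, or with a tied vote, are
#' left unassigned.
#'
#' @param clusters A tibble `feature`, `cluster` from [cluster_profiles()].
#' @param markers A marker map: tibble `feature`, `compartment` (one
#'   compartment per marker feature).
#' @return An object of class `compartment_assignment`: [tidy()] gives the
#'   per-feature assigned locations, `$clusters` the per-cluster vote
#'   summary (assigned compartment, marker tally, precision, two-decimal
#'   truncated precision), and [glance()] the overall marker agreement.
#' @export
assign_clusters <- function(clusters, markers) {
  stopifnot(all(c("feature", "cluster") %in% names(clusters)),
            all(c("feature", "compartment") %in% names(markers)))
  if (anyDuplicated(markers$feature)) {
    abort("markers must map each feature to a single compartment")
  }
  if (nrow(markers) == 0) abort("at least one marker is required")

  votes <- clusters |>
    inner_join(markers, by = "feature") |>
    count(.data$cluster, .data$compartment, name = "n_markers")
  cluster_call <- votes |>
    group_by(.data$cluster) |>
    summarise(
      total_markers = sum(.data$n_markers),
      top = max(.data$n_markers),
      compartment = if (sum(.data$n_markers == max(.data$n_markers)) == 1)
        .data$compartment[which.max(.data$n_markers)] else NA_character_,
      .groups = "drop") |>
    mutate(precision = if_else(is.na(.data$compartment), NA_real_,
                               .data$top / .data$total_markers),
           precision_2dp = truncate2(.data$precision)) |>
    select("cluster", "compartment", "total_markers", "precision",
           "precision_2dp")
  all_clusters <- clusters |>
    distinct(.data$cluster) |>
    left_join(cluster_call, by = "cluster") |>
    mutate(total_markers = tidyr::replace_na(.data$total_markers, 0L))
  features <- clusters |>
    left_join(select(all_clusters, "cluster",
                     assigned_compartment = "compartment"),
              by = "cluster")
  structure(
    list(features = features, clusters = all_clusters, markers = markers),
    class = "compartment_assignment")
}

# two-decimal truncation for reports (2/3 -> 0.66), full precision kept
truncate2 <- function(x) trunc(x * 100) / 100

#' @export
print.compartment_assignment <- function(x, ...) {
  cat(sprintf("<compartment_assignment> %d features in %d clusters, %d markers\n",
              nrow(x$features), nrow(x$clusters), nrow(x$markers)))
  print(x$clusters)
  invisible(x)
}

#' @rdname assign_clusters
#' @param x,object A `compartment_assignment`.
#' @param ... Unused.
#' @export
tidy.compartment_assignment <- function(x, ...) x$features

#' @rdname assign_clusters
#' @export
glance.compartment_assignment <- function(x, ...) {
  sc <- score_compartments(x)
  tibble(n_features = nrow(x$features),
         n_clusters = nrow(x$clusters),
         n_markers = nrow(x$markers),
         n_unassigned_clusters = sum(is.na(x$clusters$compartment)),
         macro_f = mean(sc$f_score, na.rm = TRUE))
}

#' Precision, recall and F-score per compartment
#'
#' Marker-level pooling over the whole assignment: for compartment c,
#' recall is the share of c's markers assigned to c, precision the share of
#' all markers assigned to c that really belong to c, and the F-score their
#' harmonic mean (0 when precision + recall is 0). Values are reported at
#' full precision and truncated to two decimals (2/3 is reported as 0.66).
#' Compartments with no markers are omitted.
#'
#' @param assignment A `compartment_assignment`, or a tibble with columns
#'   `feature`, `assigned_compartment`.
#' @param markers Marker map; taken from the assignment object when omitted.
#' @return A tibble per compartment: `n_markers`, `precision`, `recall`,
#'   `f_score` plus their two-decimal truncated versions.
#' @export
score_compartments <- function(assignment, markers = NULL) {
  if (inherits(assignment, "compartment_assignment")) {
    markers <- markers %||% assignment$markers
    features <- assignment$features
  } else {
    features <- assignment
  }
  stopifnot(!is.null(markers),
            all(c("feature", "assigned_compartment") %in% names(features)))
  marked <- markers |>
    left_join(select(features, "feature", "assigned_compartment"),
              by = "feature")
  purrr::map_dfr(sort(unique(markers$compartment)), function(comp) {
    of_c <- marked |> filter(.data$compartment == comp)
    assigned_c <- marked |>
      filter(!is.na(.data$assigned_compartment),
             .data$assigned_compartment == comp)
    tp <- sum(!is.na(of_c$assigned_compartment) &
                of_c$assigned_compartment == comp)
    recall <- tp / nrow(of_c)
    precision <- if (nrow(assigned_c) == 0) NA_real_ else tp / nrow(assigned_c)
    f <- if (is.na(precision)) 0 else
      if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall)
    tibble(compartment = comp, n_markers = nrow(of_c),
           precision = precision, recall = recall, f_score = f,
           precision_2dp = truncate2(precision),
           recall_2dp = truncate2(recall),
           f_score_2dp = truncate2(f))
  })
}

#' Assign features to compartments from fraction profiles
#'
#' Convenience wrapper: max-normalize the profiles, k-means cluster them
#' (default k = twice the number of marker compartments), and vote cluster
#' assignments with the marker map.
#'
#' @param profiles Profile tibble (`feature`, `fraction`, `value` or
#'   `proportion`), linear scale.
#' @param markers Marker map tibble (`feature`, `compartment`).
#' @param k Number of clusters; default `2 * n_compartments`.
#' @param restarts,seed Passed to [cluster_profiles()].
#' @return A `compartment_assignment`.
#' @examples
#' sim <- simulate_fractionation(n_features = 120, frac_translocating = 0,
#'                               seed = 4)
#' profiles <- preprocess(sim$data) |>
#'   dplyr::filter(condition == "ctrl") |>
#'   scale_profiles()
#' markers <- dplyr::slice_head(sim$truth$features, n = 30) |>
#'   dplyr::select(feature, compartment)
#' fit <- assign_compartments(profiles, markers, seed = 9)
#' score_compartments(fit)
#' @export
assign_compartments <- function(profiles, markers,
                                k = 2 * length(unique(markers$compartment)),
                                restarts = 25, seed = 1) {
  profiles <- normalize_profile_cols(profiles)
  normalized <- max_normalize(profiles)
  clusters <- cluster_profiles(normalized, k = k, restarts = restarts,
                               seed = seed)
  assign_clusters(clusters, markers)
}

#' Pearson correlation of marker profiles to their compartment centroid
#'
#' For each compartment with at least two markers, the centroid is the mean
#' scaled profile of its markers, and each marker is scored by its Pearson
#' correlation to that centroid (the white-to-blue gradient of marker
#' profile plots). Zero-variance profiles are flagged with `NA`.
#'
#' @param profiles Profile tibble (`feature`, `fraction`, `value` or
#'   `proportion`).
#' @param markers Marker map tibble (`feature`, `compartment`).
#' @return A tibble `feature`, `compartment`, `centroid_cor`.
#' @export
marker_centroid_correlation <- function(profiles, markers) {
  profiles <- normalize_profile_cols(profiles)
  mat <- profile_matrix(profiles)
  purrr::map_dfr(sort(unique(markers$compartment)), function(comp) {
    feats <- intersect(markers$feature[markers$compartment == comp],
                       rownames(mat))
    if (length(feats) < 2) return(tibble())
    sub <- mat[feats, , drop = FALSE]
    centroid <- colMeans(sub)
    r <- apply(sub, 1, function(v) {
      if (sd(v) == 0 || sd(centroid) == 0) NA_real_ else cor(v, centroid)
    })
    tibble(feature = feats, compartment = comp, centroid_cor = unname(r))
  })
}
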