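# Per-fraction filtering, normalization and two-regime imputation.
# Every step treats each fraction as an independent sub-experiment; the
# experimental group for filtering and missing-value classification is the
# fraction x condition cell (its replicates).

#' Filter features on a minimum number of valid values per group
#'
#' A feature is retained in a fraction iff at least one experimental group
#' (fraction x condition cell) within that fraction holds at least
#' `min_valid` observed values. Fractions are treated separately, so a
#' feature may be kept in some fractions and dropped in others.
#'
#' @param data A quant tibble.
#' @param min_valid Minimum number of observed replicate values required in
#'   at least one group (default 3).
#' @return The quant tibble restricted to retained (feature, fraction)
#'   pairs.
#' @export
filter_min_valid <- function(data, min_valid = 3) {
  check_quant_tbl(data)
  group_sizes <- data |>
    distinct(.data$fraction, .data$condition, .data$replicate) |>
    count(.data$fraction, .data$condition)
  if (min_valid > max(group_sizes$n)) {
    abort(sprintf("min_valid = %d exceeds the largest group size (%d)",
                  min_valid, max(group_sizes$n)))
  }
  keep <- data |>
    group_by(.data$feature, .data$fraction, .data$condition) |>
    summarise(n_obs = sum(.data$observed), .groups = "drop") |>
    group_by(.data$feature, .data$fraction) |>
    summarise(retained = max(.data$n_obs) >= min_valid, .groups = "drop") |>
    filter(.data$retained) |>
    select("feature", "fraction")
  semi_join(data, keep, by = c("feature", "fraction"))
}

# Fit one cyclic-loess pass for a feature x sample matrix of a single
# fraction: offset of each sample versus the per-feature row mean, estimated
# on complete rows and subtracted from all observed cells of that sample.
loess_pass <- function(mat, span) {
  complete <- complete.cases(mat)
  ref <- rowMeans(mat, na.rm = TRUE)
  for (j in seq_len(ncol(mat))) {
    d <- mat[complete, j] - ref[complete]
    a <- ref[complete]
    fit <- loess(d ~ a, span = span, degree = 1, surface = "direct")
    obs <- which(!is.na(mat[, j]))
    # extrapolate flat beyond the fitted range
    aj <- pmin(pmax(ref[obs], min(a)), max(a))
    mat[obs, j] <- mat[obs, j] - predict(fit, newdata = data.frame(a = aj))
  }
  mat
}

#' Cyclic-loess normalization within each fraction
#'
#' Removes intensity-dependent sample biases: for each sample of a fraction,
#' a smooth offset of that sample versus the per-feature row mean (the
#' reference) is estimated on complete rows and subtracted, and the cycle is
#' repeated `iterations` times. Missing cells stay missing; fractions with
#' fewer than 10 complete rows fall back to median centering with a warning.
#'
#' @param data A quant tibble (log2 scale).
#' @param span Loess span (default 0.7).
#' @param iterations Number of normalization cycles (default 3).
#' @return The normalized quant tibble.
#' @export
normalize_cyclic_loess <- function(data, span = 0.7, iterations = 3) {
  check_quant_tbl(data)
  stopifnot(span > 0, iterations >= 1)
  out <- data |>
    tidyr::nest(.by = "fraction") |>
    mutate(data = purrr::map2(.data$data, .data$fraction, function(d, fr) {
      mat <- quant_matrix(d)
      if (ncol(mat) < 2) return(d)
      if (sum(complete.cases(mat)) < 10) {
        warn(sprintf(
          "fraction %s has < 10 complete rows; falling back to median centering", fr))
        med <- apply(mat, 2, median, na.rm = TRUE)
        mat <- sweep(mat, 2, med - mean(med))
      } else {
        for (i in seq_len(iterations)) mat <- loess_pass(mat, span)
      }
      set_quant_values(d, mat)
    })) |>
    tidyr::unnest("data")
  out[, names(data)]
}

# feature x sample matrix of one fraction's long rows
quant_matrix <- function(d) {
  wide <- d |>
    select("feature", "sample", "log2_intensity") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "log2_intensity")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$feature
  mat
}

# write matrix values back into the long rows (cells present in the tibble)
set_quant_values <- function(d, mat) {
  idx <- cbind(match(d$feature, rownames(mat)), match(d$sample, colnames(mat)))
  d$log2_intensity <- mat[idx]
  d
}

#' Impute partially observed (missing-completely-at-random) values
#'
#' Imputes cells that are missing within a group (fraction x condition cell)
#' that still holds at least one observed value for the feature — the
#' partially observed regime. The missing cell of feature i in sample j is
#' replaced by the average of sample j's values over the `k_neighbors`
#' nearest features, nearest by Euclidean distance per co-observed sample
#' within the same fraction (the distance used by the standard KNN imputer;
#' unlike a correlation distance it keeps neighbours on the feature's own
#' intensity level, so the neighbour average is an unbiased fill-in).
#' Observed values are never altered. Cells whose whole group is unobserved
#' are left for [impute_absent()].
#'
#' @param data A quant tibble.
#' @param k_neighbors Number of neighbouring features to average
#'   (default 10); fewer are used when fewer candidates exist, and cells
#'   with no usable neighbour are left missing (with a message).
#' @param min_overlap Minimum number of co-observed samples required to
#'   compute a distance between two features (default 3).
#' @return The quant tibble with an `imputed` column ("knn" where filled).
#' @export
impute_partial <- function(data, k_neighbors = 10, min_overlap = 3) {
  check_quant_tbl(data)
  stopifnot(k_neighbors >= 1)
  if (!"imputed" %in% names(data)) data$imputed <- NA_character_

  # target cells: missing, but some replicate of the same group is observed
  partial <- data |>
    group_by(.data$feature, .data$fraction, .data$condition) |>
    mutate(group_has_obs = any(.data$observed)) |>
    ungroup()
  target <- which(is.na(partial$log2_intensity) & partial$group_has_obs)
  if (length(target) == 0) return(data)

  filled <- 0L
  for (fr in unique(data$fraction[target])) {
    rows_fr <- data$fraction == fr
    d <- data[rows_fr, ]
    mat <- quant_matrix(d)
    if (nrow(mat) < 2) next
    cells <- partial[rows_fr, ]
    todo <- which(is.na(cells$log2_intensity) & cells$group_has_obs)
    vals <- d$log2_intensity
    for (feat in unique(d$feature[todo])) {
      i <- match(feat, rownames(mat))
      xi <- mat[i, ]
      sq <- sweep(mat, 2, xi)^2
      overlap <- rowSums(!is.na(sq))
      dist <- sqrt(rowMeans(sq, na.rm = TRUE))
      dist[i] <- NA
      dist[overlap < min_overlap] <- NA
      for (idx in todo[d$feature[todo] == feat]) {
        j <- match(d$sample[idx], colnames(mat))
        cand <- which(!is.na(dist) & !is.na(mat[, j]))
        if (length(cand) == 0) next
        k <- min(k_neighbors, length(cand))
        nn <- cand[order(dist[cand])[seq_len(k)]]
        vals[idx] <- mean(mat[nn, j])
        filled <- filled + 1L
      }
    }
    imput <- is.na(d$log2_intensity) & !is.na(vals)
    d$log2_intensity <- vals
    d$imputed[imput] <- "knn"
    data[rows_fr, ] <- d
  }
  skipped <- length(target) - filled
  if (skipped > 0) {
    inform(sprintf(
      "%d partially-missing cell(s) had no usable neighbour and were left for impute_absent()",
      skipped))
  }
  data
}

#' Impute values missing in whole conditions (missing-not-at-random)
#'
#' Deterministic low-quantile imputation for cells of features that are
#' unobserved in an entire group — the below-detection regime. Every such
#' cell in sample j is set to the `probs` quantile (linear interpolation
#' between closest order statistics) of sample j's observed values.
#'
#' @param data A quant tibble.
#' @param probs Quantile used for the imputed constant (default 0.025, i.e.
#'   the 2.5th percentile).
#' @return The quant tibble, complete for all retained features, with the
#'   `imputed` column set to "detquant" where filled.
#' @export
impute_absent <- function(data, probs = 0.025) {
  check_quant_tbl(data)
  stopifnot(probs >= 0, probs <= 1)
  if (!"imputed" %in% names(data)) data$imputed <- NA_character_
  todo <- is.na(data$log2_intensity)
  if (!any(todo)) return(data)
  qs <- data |>
    filter(.data$observed) |>
    group_by(.data$sample) |>
    summarise(n_obs = n(),
              q_value = quantile(.data$log2_intensity, probs,
                                 type = 7, names = FALSE),
              .groups = "drop")
  short <- qs |> filter(.data$n_obs < 10)
  needed <- unique(data$sample[todo])
  if (any(short$sample %in% needed)) {
    abort(sprintf("sample(s) with < 10 observed values: %s",
                  paste(intersect(short$sample, needed), collapse = ", ")))
  }
  fill <- qs$q_value[match(data$sample, qs$sample)]
  data |>
    mutate(imputed = if_else(todo, "detquant", .data$imputed),
           log2_intensity = if_else(todo, fill, .data$log2_intensity))
}

#' Run the full preprocessing chain
#'
#' Filter on minimum valid values, cyclic-loess normalize, then impute in
#' two regimes (partial/MCAR by neighbour averaging, whole-condition/MNAR by
#' the low-quantile rule), each fraction treated separately throughout.
#'
#' @param data A quant tibble (log2 scale).
#' @inheritParams filter_min_valid
#' @inheritParams normalize_cyclic_loess
#' @inheritParams impute_partial
#' @inheritParams impute_absent
#' @return A complete quant tibble for all retained (feature, fraction)
#'   pairs, with provenance columns `observed` and `imputed`.
#' @examples
#' sim <- simulate_fractionation(n_features = 60, seed = 3)
#' clean <- preprocess(sim$data)
#' sum(is.na(clean$log2_intensity))
#' @export
preprocess <- function(data, min_valid = 3, span = 0.7, iterations = 3,
                       k_neighbors = 10, probs = 0.025) {
  data |>
    filter_min_valid(min_valid = min_valid) |>
    normalize_cyclic_loess(span = span, iterations = iterations) |>
    impute_partial(k_neighbors = k_neighbors) |>
    impute_absent(probs = probs)
}
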