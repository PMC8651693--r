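# Movement-score translocation calling: scale per-feature intensities to
# fraction proportions per condition, find the donor/acceptor fraction pair
# with the largest signed change versus the reference condition, score the
# moved mass, and test it by Fisher-combining the per-fraction moderated
# p-values of the donor and acceptor fractions.

#' Scale intensities to per-condition fraction proportions
#'
#' De-logs the (complete, post-imputation) intensities and, per feature,
#' condition and replicate, divides each fraction's intensity by the sum
#' over fractions; the replicate-wise scaled vectors are then averaged per
#' condition. Fractions where the feature was filtered out contribute 0.
#'
#' @param data A complete quant tibble, log2 scale.
#' @param n_fractions Total number of fractions; defaults to the maximum
#'   fraction index present.
#' @return A tibble `feature`, `condition`, `fraction`, `proportion`; per
#'   feature x condition the proportions sum to 1 wherever the feature is
#'   quantified in at least one fraction.
#' @examples
#' sim <- simulate_fractionation(n_features = 40, seed = 5)
#' profiles <- preprocess(sim$data) |> scale_profiles()
#' @export
scale_profiles <- function(data, n_fractions = max(data$fraction)) {
  check_quant_tbl(data)
  if (anyNA(data$log2_intensity)) {
    abort("scale_profiles() expects a complete (imputed) table")
  }
  per_rep <- data |>
    mutate(intensity = 2^.data$log2_intensity) |>
    group_by(.data$feature, .data$condition, .data$replicate) |>
    mutate(proportion = .data$intensity / sum(.data$intensity)) |>
    ungroup()
  per_rep |>
    group_by(.data$feature, .data$condition, .data$fraction) |>
    summarise(proportion = mean(.data$proportion), .groups = "drop") |>
    tidyr::complete(.data$feature, .data$condition,
                    fraction = seq_len(n_fractions),
                    fill = list(proportion = 0)) |>
    arrange(.data$feature, .data$condition, .data$fraction)
}

#' Movement score between two scaled profiles
#'
#' The per-fraction change is `delta_f = profile_t[f] - profile_ref[f]`; the
#' acceptor is the fraction with the largest gain, the donor the fraction
#' with the largest loss (ties broken toward the lowest fraction index), and
#' the score is the mean of the largest gain and largest absolute loss —
#' equal to the moved mass for a clean two-fraction move and a lower bound
#' otherwise. The alternative total-variation score `sum(|delta|)/2` is
#' available via `variant = "total"`.
#'
#' @param profile_t,profile_ref Equal-length numeric vectors of fraction
#'   proportions (treated condition and reference condition).
#' @param variant `"pair"` (default) or `"total"`.
#' @return A list with `score`, `donor`, `acceptor` (donor/acceptor are `NA`
#'   when all deltas are zero).
#' @examples
#' movement_score(c(0.4, 0, 0, 0.6, 0, 0), c(0.6, 0, 0, 0.4, 0, 0))
#' @export
movement_score <- function(profile_t, profile_ref, variant = c("pair", "total")) {
  variant <- match.arg(variant)
  if (length(profile_t) != length(profile_ref)) {
    abort("profiles must have equal length")
  }
  delta <- profile_t - profile_ref
  if (all(delta == 0)) {
    return(list(score = 0, donor = NA_integer_, acceptor = NA_integer_))
  }
  acceptor <- which.max(delta)
  donor <- which.min(delta)
  score <- if (variant == "pair") {
    (delta[acceptor] + abs(delta[donor])) / 2
  } else {
    sum(abs(delta)) / 2
  }
  list(score = unname(score), donor = as.integer(donor),
       acceptor = as.integer(acceptor))
}

#' Classify a donor/acceptor pair into a fraction-neighbourhood category
#'
#' Fractions are grouped into three neighbourhoods — cytosol (FR1-2),
#' membrane-bound organelles (FR3-4) and nuclear compartment (FR5-6) by
#' default — and a move is labelled by the pair of neighbourhoods it
#' connects: `"cytosol-membrane"`, `"cytosol-nuclear"`,
#' `"membrane-nuclear"`, or `"within"` when both fractions share a
#' neighbourhood. Unset donors/acceptors give `"none"`.
#'
#' @param donor,acceptor Integer fraction indices (vectorized).
#' @param grouping Named integer vector mapping fraction index to
#'   neighbourhood; names are the neighbourhood labels.
#' @return Character vector of categories.
#' @examples
#' classify_neighborhood(1, 4)  # cytosol-membrane
#' classify_neighborhood(5, 6)  # within
#' @export
classify_neighborhood <- function(donor, acceptor,
                                  grouping = default_neighborhoods()) {
  labels <- names(grouping)
  purrr::map2_chr(donor, acceptor, function(d, a) {
    if (is.na(d) || is.na(a)) return("none")
    if (grouping[[d]] == grouping[[a]]) return("within")
    paste(sort(c(labels[d], labels[a])), collapse = "-")
  })
}

#' Default fraction-to-neighbourhood grouping for six fractions
#'
#' @return Named integer vector: FR1-2 cytosol, FR3-4 membrane, FR5-6
#'   nuclear.
#' @export
default_neighborhoods <- function() {
  setNames(c(1L, 1L, 2L, 2L, 3L, 3L),
           c("cytosol", "cytosol", "membrane", "membrane",
             "nuclear", "nuclear"))
}

#' Combine donor and acceptor p-values by Fisher's method
#'
#' A confident translocation must change in both compartments, so the
#' per-fraction moderated-test p-values of the donor and acceptor fractions
#' are combined: `X2 = -2 (ln p_donor + ln p_acceptor)` referred to the
#' upper tail of a chi-square distribution with 4 degrees of freedom.
#' P-values of exactly 0 are floored at 1e-300.
#'
#' @param p_donor,p_acceptor Numeric vectors of p-values.
#' @return A tibble with `statistic` (X2) and `p_value` (combined).
#' @examples
#' fisher_combine(0.05, 0.05)
#' @export
fisher_combine <- function(p_donor, p_acceptor) {
  stopifnot(length(p_donor) == length(p_acceptor))
  pd <- pmax(p_donor, 1e-300)
  pa <- pmax(p_acceptor, 1e-300)
  x2 <- -2 * (log(pd) + log(pa))
  tibble(statistic = x2,
         p_value = pchisq(x2, df = 4, lower.tail = FALSE))
}

#' Threshold movement scores and combined q-values into calls
#'
#' Applies BH correction to the combined p-values within each time point and
#' flags features passing both the movement-score and FDR thresholds
#' (score >= `score_min` and q < `fdr_max`).
#'
#' @param data A tibble with columns `feature`, `condition`, `score`,
#'   `p_combined` (and any others, carried through).
#' @param score_min Minimum movement score (default 0.1, i.e. 10% of
#'   profile mass).
#' @param fdr_max BH-corrected combined-p threshold (default 0.05).
#' @return The tibble with `q_value` and logical `called`, sorted by
#'   `q_value` then descending score within condition.
#' @export
call_translocations <- function(data, score_min = 0.1, fdr_max = 0.05) {
  stopifnot(all(c("feature", "condition", "score", "p_combined") %in%
                  names(data)))
  data |>
    group_by(.data$condition) |>
    mutate(q_value = bh_adjust(.data$p_combined)) |>
    ungroup() |>
    mutate(called = .data$score >= score_min & .data$q_value < fdr_max) |>
    arrange(.data$condition, .data$q_value, dplyr::desc(.data$score))
}

#' Detect protein translocations across a stimulation time course
#'
#' End-to-end movement-score analysis on a preprocessed (complete) quant
#' tibble: scaled fraction profiles per condition, movement score and
#' donor/acceptor pair for every treated condition versus the reference,
#' per-fraction moderated tests supplying donor/acceptor p-values, Fisher
#' combination, BH correction per time point, and thresholding. Features
#' whose donor or acceptor fraction lacks a moderated p-value for a contrast
#' are excluded from calling for that time point.
#'
#' @param data A complete quant tibble (post [preprocess()]).
#' @param reference Reference (control) condition; defaults to the first
#'   condition in the data.
#' @param score_min,fdr_max Calling thresholds (defaults 0.1 and 0.05).
#' @param variant Movement-score variant, see [movement_score()].
#' @param grouping Fraction-neighbourhood grouping, see
#'   [classify_neighborhood()].
#' @param min_valid Passed to [fit_moderated()].
#' @return An object of class `translocation_result`; [tidy()] returns the
#'   per feature x time point table (score, donor, acceptor, category,
#'   Fisher statistic, combined p, q, called), [glance()] the per-time-point
#'   call counts, and [ggplot2::autoplot()] the score-versus-significance
#'   plot.
#' @examples
#' sim <- simulate_fractionation(n_features = 60, seed = 11)
#' res <- preprocess(sim$data) |> translocation_analysis(reference = "ctrl")
#' glance(res)
#' @export
translocation_analysis <- function(data,
                                   reference = NULL,
                                   score_min = 0.1,
                                   fdr_max = 0.05,
                                   variant = c("pair", "total"),
                                   grouping = NULL,
                                   min_valid = 3) {
  check_quant_tbl(data)
  variant <- match.arg(variant)
  conditions <- unique(data$condition)
  reference <- reference %||% conditions[1]
  if (!reference %in% conditions) abort("`reference` not found in data")
  treated <- setdiff(conditions, reference)
  if (length(treated) == 0) abort("no treated conditions to compare")
  n_fractions <- max(data$fraction)
  if (is.null(grouping)) {
    grouping <- if (n_fractions == 6) default_neighborhoods() else
      setNames(rep(1L, n_fractions), rep("all", n_fractions))
  }

  profiles <- scale_profiles(data, n_fractions = n_fractions)
  ref_prof <- profiles |> filter(.data$condition == reference)

  # per-fraction moderated p-values for every treated-vs-reference contrast
  pvals <- purrr::map_dfr(treated, function(cond) {
    purrr::map_dfr(sort(unique(data$fraction)), function(fr) {
      present <- data |>
        filter(.data$fraction == fr, .data$condition %in% c(cond, reference))
      if (length(unique(present$condition)) < 2) return(tibble())
      fit <- fit_moderated(data, contrast = c(cond, reference),
                           fraction = fr, min_valid = min_valid)
      fit$table |>
        mutate(condition = cond, fraction = fr) |>
        select("feature", "condition", "fraction", "p_value", "logFC")
    })
  })

  scores <- purrr::map_dfr(treated, function(cond) {
    wide_t <- profiles |>
      filter(.data$condition == cond) |>
      tidyr::pivot_wider(names_from = "fraction", values_from = "proportion",
                         id_cols = "feature")
    wide_r <- ref_prof |>
      tidyr::pivot_wider(names_from = "fraction", values_from = "proportion",
                         id_cols = "feature")
    common <- intersect(wide_t$feature, wide_r$feature)
    mt <- as.matrix(wide_t[match(common, wide_t$feature), -1])
    mr <- as.matrix(wide_r[match(common, wide_r$feature), -1])
    purrr::map_dfr(seq_along(common), function(i) {
      ms <- movement_score(mt[i, ], mr[i, ], variant = variant)
      tibble(feature = common[i], condition = cond,
             score = ms$score, donor = ms$donor, acceptor = ms$acceptor)
    })
  })

  joined <- scores |>
    left_join(pvals |> rename(p_donor = "p_value", logFC_donor = "logFC"),
              by = c("feature", "condition", donor = "fraction")) |>
    left_join(pvals |> rename(p_acceptor = "p_value", logFC_acceptor = "logFC"),
              by = c("feature", "condition", acceptor = "fraction")) |>
    mutate(category = classify_neighborhood(.data$donor, .data$acceptor,
                                            grouping = grouping))
  excluded <- joined |>
    filter(!is.na(.data$donor) &
             (is.na(.data$p_donor) | is.na(.data$p_acceptor)))
  if (nrow(excluded) > 0) {
    inform(sprintf(
      "%d feature/time-point pair(s) lacked a donor or acceptor p-value and were excluded from calling",
      nrow(excluded)))
  }
  testable <- joined |>
    filter(!is.na(.data$p_donor), !is.na(.data$p_acceptor))
  fisher <- fisher_combine(testable$p_donor, testable$p_acceptor)
  calls <- testable |>
    mutate(fisher_x2 = fisher$statistic, p_combined = fisher$p_value) |>
    call_translocations(score_min = score_min, fdr_max = fdr_max)

  structure(
    list(calls = calls,
         excluded = excluded,
         profiles = profiles,
         reference = reference,
         score_min = score_min,
         fdr_max = fdr_max,
         variant = variant),
    class = "translocation_result")
}

#' @export
print.translocation_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<translocation_result> reference '%s', score >= %.2g, q < %.2g\n",
              x$reference, x$score_min, x$fdr_max))
  print(g)
  invisible(x)
}

#' @rdname translocation_analysis
#' @param x,object A `translocation_result`.
#' @param ... Unused.
#' @export
tidy.translocation_result <- function(x, ...) x$calls

#' @rdname translocation_analysis
#' @export
glance.translocation_result <- function(x, ...) {
  x$calls |>
    group_by(.data$condition) |>
    summarise(n_tested = n(),
              n_called = sum(.data$called),
              .groups = "drop")
}
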