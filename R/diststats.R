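# Distribution statistics for protein groups (e.g. ribosomal subunits)
# across fractions: percentage-of-total profiles per replicate x condition,
# and paired condition tests within a fraction.

#' Percentage of a group's summed intensity per fraction
#'
#' For a set of member features (for example all large-ribosomal-subunit
#' proteins), computes per replicate and condition the percentage of the
#' group's total linear-scale intensity found in each fraction. Members not
#' quantified in a fraction contribute 0 to that fraction's sum, so the
#' percentages always total 100 per replicate x condition.
#'
#' @param data A complete quant tibble, log2 scale.
#' @param members Character vector of member feature ids.
#' @param group Label attached to the output (default "group").
#' @param n_fractions Total number of fractions; defaults to the maximum
#'   fraction index present.
#' @return A tibble `group`, `condition`, `replicate`, `fraction`,
#'   `percentage`.
#' @examples
#' sim <- simulate_fractionation(n_features = 40, seed = 8)
#' clean <- preprocess(sim$data)
#' members <- unique(clean$feature)[1:5]
#' group_fraction_percentages(clean, members, group = "demo")
#' @export
group_fraction_percentages <- function(data, members, group = "group",
                                       n_fractions = max(data$fraction)) {
  check_quant_tbl(data)
  sub <- data |>
    filter(.data$feature %in% members, !is.na(.data$log2_intensity))
  if (nrow(sub) == 0) abort("no group member is quantified")
  sub |>
    mutate(intensity = 2^.data$log2_intensity) |>
    group_by(.data$condition, .data$replicate, .data$fraction) |>
    summarise(total = sum(.data$intensity), .groups = "drop_last") |>
    tidyr::complete(fraction = seq_len(n_fractions),
                    fill = list(total = 0)) |>
    mutate(percentage = 100 * .data$total / sum(.data$total)) |>
    ungroup() |>
    mutate(group = group) |>
    select("group", "condition", "replicate", "fraction", "percentage")
}

#' Paired two-sample t-test on group percentages within a fraction
#'
#' Compares the per-replicate fraction percentages of a group between two
#' conditions with a standard two-sided paired t-test (replicates paired
#' across conditions), `df = n_pairs - 1`. All-equal nonzero differences
#' (zero variance) are flagged rather than tested.
#'
#' @param dist_a,dist_b Group distributions from
#'   [group_fraction_percentages()], one condition each (or filtered to one
#'   condition), sharing replicate ids.
#' @param fraction Fraction index to test.
#' @return A one-row tibble `fraction`, `n_pairs`, `estimate` (mean
#'   difference a - b), `statistic`, `df`, `p_value`, `zero_variance`.
#' @export
paired_fraction_test <- function(dist_a, dist_b, fraction) {
  fr <- fraction
  a <- dist_a |> filter(.data$fraction == fr) |> arrange(.data$replicate)
  b <- dist_b |> filter(.data$fraction == fr) |> arrange(.data$replicate)
  common <- intersect(a$replicate, b$replicate)
  if (length(common) < 2) abort("need at least 2 paired replicates")
  av <- a$percentage[match(common, a$replicate)]
  bv <- b$percentage[match(common, b$replicate)]
  diffs <- av - bv
  if (sd(diffs) == 0) {
    warn("zero-variance differences; p-value undefined")
    return(tibble(fraction = fr, n_pairs = length(common),
                  estimate = mean(diffs), statistic = NA_real_,
                  df = length(common) - 1L, p_value = NA_real_,
                  zero_variance = TRUE))
  }
  tt <- t.test(av, bv, paired = TRUE)
  tibble(fraction = fr, n_pairs = length(common),
         estimate = unname(tt$estimate),
         statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         zero_variance = FALSE)
}
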