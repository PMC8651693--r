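# Empirical-Bayes moderated two-group testing per fraction x contrast.
# Per-feature residual variances are shrunk toward a prior estimated by
# moment matching on the log residual variances (digamma/trigamma
# inversion), the moderated t uses the augmented degrees of freedom
# d0 + d_g, and p-values are BH-corrected across features.

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (-dif / x < 1e-8) break
    }
    x
  }, double(1))
}

# Moment-matching estimate of the variance prior (d0, s0^2) from per-feature
# sample variances s2 on df degrees of freedom: the log variances follow a
# scaled log-chi-square whose mean/variance involve digamma/trigamma.
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_sq = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  excess <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.na(excess) || excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-group test within one fraction
#'
#' Fits per-feature ordinary two-group statistics for a condition contrast
#' within a single fraction, shrinks the residual variances toward an
#' empirical-Bayes prior, and reports moderated t statistics with BH-adjusted
#' two-sided p-values. Features lacking `min_valid` originally observed
#' values in both conditions (the `observed` column, if present) are
#' excluded from the contrast, as are features with zero residual degrees of
#' freedom.
#'
#' @param data A complete quant tibble (post-imputation), log2 scale.
#' @param contrast Length-2 character vector `c(condition, reference)`; the
#'   log2 fold change is condition minus reference.
#' @param fraction Fraction index to test.
#' @param min_valid Minimum originally-observed values required in at least
#'   one of the two conditions (default 3).
#' @param prior_df Override for the prior degrees of freedom d0: `NULL`
#'   (default) estimates it by moment matching; `0` disables shrinkage
#'   (ordinary pooled t); large values approach full shrinkage to the prior
#'   variance (capped at 1e6).
#' @return An object of class `moderated_fit`; use [tidy()] for the
#'   per-feature table (logFC, t, df, p, q, group means and sizes) and
#'   [glance()] for the prior (d0, s0_sq).
#' @examples
#' sim <- simulate_fractionation(n_features = 80, seed = 2)
#' fit <- preprocess(sim$data) |>
#'   fit_moderated(contrast = c("stim1", "ctrl"), fraction = 1)
#' glance(fit)
#' @export
fit_moderated <- function(data, contrast, fraction, min_valid = 3,
                          prior_df = NULL) {
  check_quant_tbl(data)
  stopifnot(length(contrast) == 2)
  d <- data |>
    filter(.data$fraction == .env$fraction,
           .data$condition %in% .env$contrast,
           !is.na(.data$log2_intensity))
  if (length(unique(d$condition)) < 2) {
    abort(sprintf("both contrast conditions must be present in fraction %s",
                  fraction))
  }
  has_obs_col <- "observed" %in% names(d)
  per_group <- d |>
    group_by(.data$feature, .data$condition) |>
    summarise(
      n = n(),
      n_obs = if (has_obs_col) sum(.data$observed) else n(),
      mean = mean(.data$log2_intensity),
      ss = sum((.data$log2_intensity - mean(.data$log2_intensity))^2),
      .groups = "drop")
  wide <- per_group |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("n", "n_obs", "mean", "ss"))
  cn <- function(prefix, cond) wide[[paste0(prefix, "_", cond)]]
  a <- contrast[1]; b <- contrast[2]
  stats_tbl <- tibble(
    feature = wide$feature,
    n1 = cn("n", a) %||% NA_integer_,
    n2 = cn("n", b) %||% NA_integer_,
    n_obs1 = cn("n_obs", a),
    n_obs2 = cn("n_obs", b),
    mean1 = cn("mean", a),
    mean2 = cn("mean", b),
    ss1 = cn("ss", a),
    ss2 = cn("ss", b)
  ) |>
    filter(!is.na(.data$n1), !is.na(.data$n2)) |>
    filter(pmax(.data$n_obs1, .data$n_obs2) >= min_valid) |>
    mutate(
      df_residual = .data$n1 + .data$n2 - 2,
      s2 = (.data$ss1 + .data$ss2) / .data$df_residual,
      logFC = .data$mean1 - .data$mean2
    ) |>
    filter(.data$df_residual > 0)
  n_zero_df <- sum(stats_tbl$df_residual <= 0)
  if (nrow(stats_tbl) == 0) abort("no features eligible for this contrast")

  prior <- if (is.null(prior_df)) {
    estimate_variance_prior(stats_tbl$s2, stats_tbl$df_residual)
  } else {
    list(d0 = min(prior_df, 1e6),
         s0_sq = estimate_variance_prior(stats_tbl$s2,
                                         stats_tbl$df_residual)$s0_sq)
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  d0_eff <- min(d0, 1e6)
  # certainty about the variance cannot exceed pooling every feature
  df_pooled <- sum(stats_tbl$df_residual)

  out <- stats_tbl |>
    mutate(
      s2_post = if (is.infinite(d0)) s0_sq else
        (d0_eff * s0_sq + .data$df_residual * .data$s2) /
        (d0_eff + .data$df_residual),
      df_total = pmin(d0_eff + .data$df_residual, df_pooled),
      t = .data$logFC /
        sqrt(.data$s2_post * (1 / .data$n1 + 1 / .data$n2)),
      p_value = 2 * pt(-abs(.data$t), df = .data$df_total),
      q_value = p.adjust(.data$p_value, method = "BH")
    ) |>
    select("feature", "logFC", "mean1", "mean2", "n1", "n2",
           "s2", "df_residual", "s2_post", "t", "df_total",
           "p_value", "q_value")
  structure(
    list(table = out, d0 = d0, s0_sq = s0_sq,
         contrast = contrast, fraction = fraction,
         n_excluded_zero_df = n_zero_df),
    class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> fraction %s: %s vs %s, %d features\n",
              x$fraction, x$contrast[1], x$contrast[2], nrow(x$table)))
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.4g\n",
              x$d0, x$s0_sq))
  invisible(x)
}

#' @rdname fit_moderated
#' @param x,object A `moderated_fit`.
#' @param ... Unused.
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @rdname fit_moderated
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(fraction = x$fraction,
         contrast = paste(x$contrast, collapse = " vs "),
         n_features = nrow(x$table),
         d0 = x$d0, s0_sq = x$s0_sq)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `q_i` is the minimum over ranks
#' `j >= rank(i)` of `p_(j) * m / j`, capped at 1. Thin wrapper over
#' [stats::p.adjust()] kept as the package's single corrector so every stage
#' adjusts identically.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
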