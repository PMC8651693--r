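# Builders for small in-code fixtures.

# Long quant tibble from a feature x sample matrix and a design; NA cells
# are missing. Sample columns of `mat` must match design$sample.
quant_from_matrix <- function(mat, design) {
  stopifnot(all(colnames(mat) %in% design$sample))
  as.data.frame(mat) |>
    tibble::rownames_to_column("feature") |>
    tidyr::pivot_longer(-feature, names_to = "sample",
                        values_to = "log2_intensity") |>
    dplyr::left_join(design, by = "sample") |>
    dplyr::mutate(observed = !is.na(log2_intensity)) |>
    dplyr::select(feature, sample, fraction, condition, replicate,
                  log2_intensity, observed)
}

# One-fraction design shortcut.
flat_design <- function(conditions = c("a", "b"), replicates = 4,
                        n_fractions = 1) {
  fraction_design(n_fractions = n_fractions, conditions = conditions,
                  replicates = replicates)
}

# Gaussian null matrix: no condition effect, shared mean per feature.
null_matrix <- function(n_features, design, sd = 0.3, mean_range = c(20, 30)) {
  mu <- runif(n_features, mean_range[1], mean_range[2])
  mat <- matrix(rnorm(n_features * nrow(design), mean = mu, sd = sd),
                nrow = n_features)
  rownames(mat) <- sprintf("F%04d", seq_len(n_features))
  colnames(mat) <- design$sample
  mat
}

# 50-feature heteroscedastic two-group fixture used for the
# moderated-statistics oracle comparisons.
moderated_fixture <- function(seed = 42, n = 50, n_rep = 4) {
  withr::with_seed(seed, {
    s2_true <- 0.09 * 8 / rchisq(n, df = 8)
    beta <- rnorm(n, 0, 0.5)
    design <- flat_design(conditions = c("a", "b"), replicates = n_rep)
    mat <- cbind(
      25 + beta + matrix(rnorm(n * n_rep, 0, sqrt(s2_true)), n),
      25 + matrix(rnorm(n * n_rep, 0, sqrt(s2_true)), n))
    rownames(mat) <- sprintf("F%02d", seq_len(n))
    colnames(mat) <- design$sample
    list(mat = mat, design = design, data = quant_from_matrix(mat, design))
  })
}

# Run the default-condition pipeline for one seed and score recovery of the
# injected translocators.
recovery_run <- function(seed) {
  sim <- simulate_fractionation(seed = seed)
  clean <- preprocess(sim$data)
  res <- suppressMessages(translocation_analysis(clean, reference = "ctrl"))
  calls <- tidy(res)
  truthf <- sim$truth$translocations$feature
  called <- unique(calls$feature[calls$called])
  c(sensitivity = mean(truthf %in% called),
    fdr = if (length(called) > 0) mean(!(called %in% truthf)) else 0)
}
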