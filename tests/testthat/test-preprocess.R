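make_filter_fixture <- function() {
  # two fractions x two conditions x 4 replicates
  design <- fraction_design(n_fractions = 2, conditions = c("a", "b"),
                            replicates = 4)
  mat <- matrix(NA_real_, nrow = 3, ncol = nrow(design),
                dimnames = list(c("kept3", "gone2", "low1"), design$sample))
  grp <- function(fr, cond) design$sample[design$fraction == fr &
                                            design$condition == cond]
  mat["kept3", grp(1, "a")[1:3]] <- 20          # 3 of 4 in one group
  for (fr in 1:2) for (cond in c("a", "b")) {
    mat["gone2", grp(fr, cond)[1:2]] <- 21      # 2 everywhere
  }
  mat["low1", grp(2, "b")[1]] <- 22             # single observation
  quant_from_matrix(mat, design)
}

test_that("the minimum-valid filter keeps features with one full group", {
  data <- make_filter_fixture()
  kept <- filter_min_valid(data, min_valid = 3)
  expect_setequal(unique(kept$feature), "kept3")
  # per-fraction independence: kept3 survives only in fraction 1
  expect_setequal(unique(kept$fraction), 1L)

  loose <- filter_min_valid(data, min_valid = 1)
  expect_setequal(unique(loose$feature), c("kept3", "gone2", "low1"))

  expect_error(filter_min_valid(data, min_valid = 5), "largest group")
})

test_that("loess normalization removes constant and linear sample offsets", {
  design <- flat_design(conditions = "a", replicates = 2)
  withr::with_seed(1, {
    base <- sort(runif(300, 18, 30))
    mat <- cbind(base, base)
  })
  colnames(mat) <- design$sample
  rownames(mat) <- sprintf("F%03d", seq_len(nrow(mat)))

  identical_out <- normalize_cyclic_loess(quant_from_matrix(mat, design))
  expect_equal(identical_out$log2_intensity,
               quant_from_matrix(mat, design)$log2_intensity,
               tolerance = 1e-8)

  shifted <- mat
  shifted[, 2] <- shifted[, 2] + 0.8
  out <- normalize_cyclic_loess(quant_from_matrix(shifted, design))
  wide <- tidyr::pivot_wider(out[, c("feature", "sample", "log2_intensity")],
                             names_from = sample,
                             values_from = log2_intensity)
  expect_lt(abs(mean(wide[[2]] - wide[[3]])), 1e-3)

  trended <- mat
  trended[, 2] <- trended[, 2] + 0.1 * (base - mean(base))
  out2 <- normalize_cyclic_loess(quant_from_matrix(trended, design))
  wide2 <- tidyr::pivot_wider(out2[, c("feature", "sample", "log2_intensity")],
                              names_from = sample,
                              values_from = log2_intensity)
  d <- wide2[[2]] - wide2[[3]]
  a <- rowMeans(cbind(wide2[[2]], wide2[[3]]))
  expect_lt(abs(coef(lm(d ~ a))[2]), 0.01)
})

test_that("loess normalization falls back to median centering on tiny fractions", {
  design <- flat_design(conditions = "a", replicates = 2)
  mat <- matrix(c(1:5, 1:5 + 2), ncol = 2,
                dimnames = list(sprintf("F%d", 1:5), design$sample))
  expect_warning(out <- normalize_cyclic_loess(quant_from_matrix(mat, design)),
                 "median centering")
  wide <- tidyr::pivot_wider(out[, c("feature", "sample", "log2_intensity")],
                             names_from = sample,
                             values_from = log2_intensity)
  expect_equal(median(wide[[2]]), median(wide[[3]]))
})

test_that("neighbour imputation fills partial cells and nothing else", {
  design <- flat_design(conditions = c("a", "b"), replicates = 4)
  withr::with_seed(2, {
    mat <- null_matrix(30, design)
  })
  complete <- quant_from_matrix(mat, design)
  expect_identical(impute_partial(complete), {
    x <- complete
    x$imputed <- NA_character_
    x
  })

  # exact clone with one cell deleted: nearest neighbour is the clone
  mat2 <- rbind(mat, clone = mat[1, ])
  deleted <- mat2["clone", 1]
  mat2["clone", 1] <- NA
  out <- impute_partial(quant_from_matrix(mat2, design), k_neighbors = 1)
  cell <- out[out$feature == "clone" & out$sample == design$sample[1], ]
  expect_equal(cell$log2_intensity, unname(deleted), tolerance = 1e-12)
  expect_equal(cell$imputed, "knn")
  # all observed values untouched
  obs <- out[out$observed, ]
  src <- quant_from_matrix(mat2, design)
  expect_identical(obs$log2_intensity,
                   src$log2_intensity[src$observed])
})

test_that("imputation error stays within twice the noise level under MCAR", {
  sim <- simulate_fractionation(n_features = 400, frac_translocating = 0,
                                noise_sd = 0.3, mcar_rate = 0.05,
                                mnar_slope = 1, mnar_midpoint = -1000,
                                seed = 21)
  truth_values <- simulate_intensities(sim$truth,
                                       sim$design, noise_sd = 0.3,
                                       seed = 21 + 1L)
  imputed <- impute_partial(sim$data)
  mask <- sim$data$missing_reason %in% "mcar" & !is.na(imputed$log2_intensity)
  expect_gt(sum(mask), 200)
  rmse <- sqrt(mean((imputed$log2_intensity[mask] -
                       truth_values$log2_intensity[mask])^2))
  expect_lt(rmse, 2 * 0.3)
})

test_that("low-quantile imputation reproduces the interpolated quantile", {
  design <- flat_design(conditions = "a", replicates = 1)
  mat <- matrix(c(1:100, NA), ncol = 1,
                dimnames = list(c(sprintf("F%03d", 1:100), "gone"),
                                design$sample[1]))
  out <- impute_absent(quant_from_matrix(mat, design), probs = 0.025)
  expect_equal(out$log2_intensity[out$feature == "gone"], 3.475)

  out0 <- impute_absent(quant_from_matrix(mat, design), probs = 0)
  expect_equal(out0$log2_intensity[out0$feature == "gone"], 1)

  complete <- quant_from_matrix(matrix(1:100, ncol = 1,
                                       dimnames = list(sprintf("F%03d", 1:100),
                                                       design$sample[1])),
                                design)
  expect_identical(impute_absent(complete)$log2_intensity,
                   complete$log2_intensity)
})

test_that("low-quantile imputation refuses samples with too few observations", {
  design <- flat_design(conditions = "a", replicates = 1)
  mat <- matrix(c(1:5, NA), ncol = 1,
                dimnames = list(sprintf("F%d", 1:6), design$sample[1]))
  expect_error(impute_absent(quant_from_matrix(mat, design)),
               "< 10 observed")
})

test_that("the full preprocessing chain is complete, conservative and idempotent", {
  sim <- simulate_fractionation(n_features = 150, seed = 31)
  clean <- preprocess(sim$data)
  # completeness
  expect_false(anyNA(clean$log2_intensity))
  # observed values never altered by imputation (only normalization touches them)
  normalized <- sim$data |>
    filter_min_valid() |>
    normalize_cyclic_loess()
  obs_before <- normalized[normalized$observed, ]
  obs_after <- clean[clean$observed, ]
  merged <- dplyr::inner_join(obs_before, obs_after,
                              by = c("feature", "sample"))
  expect_equal(merged$log2_intensity.x, merged$log2_intensity.y,
               tolerance = 1e-12)
  # detQuant values sit at or below the per-sample median
  med <- clean |>
    dplyr::filter(observed) |>
    dplyr::group_by(sample) |>
    dplyr::summarise(med = median(log2_intensity))
  dq <- clean |>
    dplyr::filter(imputed %in% "detquant") |>
    dplyr::left_join(med, by = "sample")
  expect_true(all(dq$log2_intensity <= dq$med))
  # re-imputing a complete table changes nothing
  again <- impute_absent(impute_partial(clean))
  expect_equal(again$log2_intensity, clean$log2_intensity, tolerance = 1e-12)
})
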