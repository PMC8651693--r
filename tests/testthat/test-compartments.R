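profile_tbl <- function(mat) {
  tibble::tibble(
    feature = rep(rownames(mat), each = ncol(mat)),
    fraction = rep(seq_len(ncol(mat)), nrow(mat)),
    value = as.vector(t(mat)))
}

test_that("max normalization scales every profile to a unit maximum", {
  mat <- rbind(a = c(2, 4, 8), b = c(0, 1, 0), c = c(3, 3, 3))
  out <- max_normalize(profile_tbl(mat))
  get <- function(f) out$value[out$feature == f]
  expect_equal(get("a"), c(0.25, 0.5, 1))
  expect_equal(get("b"), c(0, 1, 0))
  expect_equal(get("c"), c(1, 1, 1))

  with_zero <- rbind(mat, z = c(0, 0, 0))
  expect_warning(out2 <- max_normalize(profile_tbl(with_zero)), "all-zero")
  expect_false("z" %in% out2$feature)
})

test_that("k-means clustering splits separable profiles deterministically", {
  mat <- rbind(
    matrix(rep(c(1, 0, 0, 0, 0, 0), 10), 10, byrow = TRUE),
    matrix(rep(c(0, 0, 0, 0, 0, 1), 10), 10, byrow = TRUE))
  rownames(mat) <- sprintf("F%02d", 1:20)
  cl <- cluster_profiles(profile_tbl(mat), k = 2, seed = 1)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_false(cl$cluster[1] == cl$cluster[11])

  expect_identical(cl, cluster_profiles(profile_tbl(mat), k = 2, seed = 1))

  # k equal to the number of (distinct) features: every point its own cluster
  small <- rbind(diag(4))
  rownames(small) <- sprintf("D%d", 1:4)
  cl4 <- cluster_profiles(profile_tbl(small), k = 4, restarts = 1, seed = 2)
  expect_equal(sort(unique(cl4$cluster)), 1:4)

  expect_error(cluster_profiles(profile_tbl(small), k = 5, seed = 1),
               "exceeds")
})

test_that("marker voting reproduces the worked precision examples", {
  clusters <- tibble::tibble(
    feature = c("m1", "m2", "x1", "x2",       # cluster 1: pure cytosol
                "m3", "m4", "n1", "y1",       # cluster 2: 2 cytosol + 1 nucleus
                "z1", "z2"),                  # cluster 3: no markers
    cluster = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L))
  markers <- tibble::tibble(
    feature = c("m1", "m2", "m3", "m4", "n1"),
    compartment = c("cytosol", "cytosol", "cytosol", "cytosol", "nucleus"))
  asg <- assign_clusters(clusters, markers)
  cl <- asg$clusters

  expect_equal(cl$compartment[cl$cluster == 1], "cytosol")
  expect_equal(cl$precision[cl$cluster == 1], 1)
  expect_equal(cl$compartment[cl$cluster == 2], "cytosol")
  expect_equal(cl$precision[cl$cluster == 2], 2 / 3)
  expect_equal(cl$precision_2dp[cl$cluster == 2], 0.66)  # truncated, not rounded
  expect_true(is.na(cl$compartment[cl$cluster == 3]))
  expect_true(is.na(cl$precision[cl$cluster == 3]))

  # every member inherits the cluster assignment
  feats <- tidy(asg)
  expect_equal(feats$assigned_compartment[feats$feature == "x1"], "cytosol")
  expect_true(is.na(feats$assigned_compartment[feats$feature == "z1"]))
})

test_that("tied marker votes leave the cluster unassigned", {
  clusters <- tibble::tibble(feature = c("a", "b"), cluster = c(1L, 1L))
  markers <- tibble::tibble(feature = c("a", "b"),
                            compartment = c("cytosol", "nucleus"))
  asg <- assign_clusters(clusters, markers)
  expect_true(is.na(asg$clusters$compartment[1]))
})

test_that("compartment scoring reproduces the worked recall/precision cases", {
  # all markers correctly assigned -> precision = recall = F = 1
  perfect <- tibble::tibble(
    feature = c("c1", "c2", "n1"),
    assigned_compartment = c("cytosol", "cytosol", "nucleus"))
  markers <- tibble::tibble(feature = c("c1", "c2", "n1"),
                            compartment = c("cytosol", "cytosol", "nucleus"))
  sc <- score_compartments(perfect, markers)
  expect_true(all(sc$precision == 1 & sc$recall == 1 & sc$f_score == 1))

  # one of three markers assigned to the wrong location, nothing foreign in:
  # the tool reports the share of the compartment's markers kept, 2/3 -> 0.66
  three <- tibble::tibble(
    feature = c("c1", "c2", "c3", "n1"),
    assigned_compartment = c("cytosol", "cytosol", "nucleus", "nucleus"))
  markers3 <- tibble::tibble(
    feature = c("c1", "c2", "c3", "n1"),
    compartment = c("cytosol", "cytosol", "cytosol", "nucleus"))
  sc3 <- score_compartments(three, markers3)
  cyt <- sc3[sc3$compartment == "cytosol", ]
  expect_equal(cyt$recall, 2 / 3)
  expect_equal(cyt$recall_2dp, 0.66)
  expect_equal(cyt$precision, 1)

  # harmonic mean arithmetic: P = 0.5, R = 1 -> F = 2/3
  half <- tibble::tibble(
    feature = c("a1", "b1"),
    assigned_compartment = c("alpha", "alpha"))
  markers_h <- tibble::tibble(feature = c("a1", "b1"),
                              compartment = c("alpha", "beta"))
  sch <- score_compartments(half, markers_h)
  alpha <- sch[sch$compartment == "alpha", ]
  expect_equal(alpha$precision, 0.5)
  expect_equal(alpha$recall, 1)
  expect_equal(alpha$f_score, 2 / 3, tolerance = 1e-12)
})

test_that("scores agree with a confusion-matrix oracle and ignore labels", {
  withr::with_seed(37, {
    for (rep in 1:10) {
      n <- sample(10:50, 1)
      comps <- paste0("C", seq_len(sample(2:4, 1)))
      truthc <- sample(comps, n, replace = TRUE)
      assigned <- sample(comps, n, replace = TRUE)
      features <- sprintf("F%02d", seq_len(n))
      markers <- tibble::tibble(feature = features, compartment = truthc)
      asg_tbl <- tibble::tibble(feature = features,
                                assigned_compartment = assigned)
      sc <- score_compartments(asg_tbl, markers)
      for (comp in comps) {
        tp <- sum(truthc == comp & assigned == comp)
        prec <- if (sum(assigned == comp) == 0) NA_real_ else
          tp / sum(assigned == comp)
        rec <- tp / sum(truthc == comp)
        row <- sc[sc$compartment == comp, ]
        expect_equal(row$precision, prec)
        expect_equal(row$recall, rec)
      }
    }
  })
  # invariance to cluster relabeling
  clusters <- tibble::tibble(feature = sprintf("F%d", 1:6),
                             cluster = c(1L, 1L, 2L, 2L, 3L, 3L))
  markers <- tibble::tibble(feature = sprintf("F%d", 1:6),
                            compartment = rep(c("a", "b", "c"), each = 2))
  relabeled <- dplyr::mutate(clusters,
                             cluster = c(3L, 3L, 1L, 1L, 2L, 2L))
  s1 <- score_compartments(assign_clusters(clusters, markers))
  s2 <- score_compartments(assign_clusters(relabeled, markers))
  expect_equal(s1, s2)
})

test_that("noiseless one-hot data reach perfect F-scores", {
  templates <- compartment_templates(spillover = 0)
  sim <- simulate_fractionation(n_features = 120, templates = templates,
                                frac_translocating = 0, noise_sd = 0,
                                missingness = FALSE, seed = 19)
  profiles <- preprocess(sim$data) |>
    dplyr::filter(condition == "ctrl") |>
    scale_profiles()
  markers <- dplyr::select(sim$truth$features, feature, compartment)
  asg <- assign_compartments(profiles, markers, k = 6, seed = 5)
  sc <- score_compartments(asg)
  expect_true(all(sc$f_score == 1))
})

test_that("marker profiles correlate with their compartment centroid", {
  # identical profiles -> r = 1 for all markers
  mat <- rbind(a = c(0.2, 0.5, 0.3), b = c(0.2, 0.5, 0.3))
  markers <- tibble::tibble(feature = c("a", "b"), compartment = "x")
  out <- marker_centroid_correlation(profile_tbl(mat), markers)
  expect_equal(out$centroid_cor, c(1, 1))

  # centroid is the element-wise mean of the marker profiles
  mat2 <- rbind(a = c(1, 0, 0, 0, 0, 0), b = c(0, 0, 1, 0, 0, 0))
  out2 <- marker_centroid_correlation(profile_tbl(mat2),
                                      tibble::tibble(feature = c("a", "b"),
                                                     compartment = "x"))
  centroid <- colMeans(mat2)
  manual_r <- function(v) {
    cv <- sum((v - mean(v)) * (centroid - mean(centroid)))
    cv / sqrt(sum((v - mean(v))^2) * sum((centroid - mean(centroid))^2))
  }
  expect_equal(out2$centroid_cor, c(manual_r(mat2["a", ]),
                                    manual_r(mat2["b", ])))

  # distinct one-hot profiles over six fractions are anti-correlated at -0.2
  e1 <- c(1, 0, 0, 0, 0, 0); e2 <- c(0, 1, 0, 0, 0, 0)
  r12 <- sum((e1 - 1 / 6) * (e2 - 1 / 6)) /
    sqrt(sum((e1 - 1 / 6)^2) * sum((e2 - 1 / 6)^2))
  expect_equal(r12, -0.2, tolerance = 1e-12)

  # a flat (zero-variance) profile is flagged, not scored
  mat3 <- rbind(a = c(1, 1, 1), b = c(0, 1, 0), c = c(0, 1, 0))
  out3 <- marker_centroid_correlation(profile_tbl(mat3),
                                      tibble::tibble(feature = c("a", "b", "c"),
                                                     compartment = "x"))
  expect_true(is.na(out3$centroid_cor[out3$feature == "a"]))
})
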