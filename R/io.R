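# Tab-separated readers/writers, YAML configuration and the pipeline
# orchestrator. Matrices are written wide (feature column + one column per
# sample named <condition>_<fraction>_<replicate>) with missing values as
# empty fields; "NA" is accepted on read. Fraction indices are 1-based
# everywhere (FR1..FR6).

#' Read a feature-by-sample quantification matrix with its design
#'
#' @param path Tab-separated matrix: a `feature` id column plus one numeric
#'   column per sample. Empty fields and "NA" are missing.
#' @param design_path Tab-separated design with columns `sample`,
#'   `fraction`, `condition`, `replicate`. Every matrix column must appear
#'   in the design.
#' @param log2 Set `FALSE` if the file stores linear-scale intensities, in
#'   which case they are log2-transformed on read.
#' @return A quant tibble.
#' @export
read_quant_table <- function(path, design_path, log2 = TRUE) {
  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            progress = FALSE)
  req <- c("sample", "fraction", "condition", "replicate")
  if (!all(req %in% names(design))) {
    abort(sprintf("design file must have columns: %s",
                  paste(req, collapse = ", ")))
  }
  # base parser: correctly rounded doubles, so written tables round-trip
  # bit-for-bit
  wide <- as_tibble(utils::read.delim(path, sep = "\t", quote = "",
                                      na.strings = c("", "NA"),
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
  if (names(wide)[1] != "feature") names(wide)[1] <- "feature"
  if (anyDuplicated(wide$feature)) {
    abort(sprintf("duplicate feature id(s): %s",
                  paste(unique(wide$feature[duplicated(wide$feature)]),
                        collapse = ", ")))
  }
  sample_cols <- setdiff(names(wide), "feature")
  unmatched <- setdiff(sample_cols, design$sample)
  if (length(unmatched) > 0) {
    abort(sprintf("matrix column(s) absent from design: %s",
                  paste(unmatched, collapse = ", ")))
  }
  bad <- !vapply(wide[sample_cols], is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("non-numeric values in column(s): %s",
                  paste(sample_cols[bad], collapse = ", ")))
  }
  long <- wide |>
    tidyr::pivot_longer(-"feature", names_to = "sample",
                        values_to = "log2_intensity") |>
    left_join(design, by = "sample")
  if (!log2) long$log2_intensity <- log2(long$log2_intensity)
  long |>
    mutate(observed = !is.na(.data$log2_intensity),
           fraction = as.integer(.data$fraction),
           replicate = as.integer(.data$replicate)) |>
    select("feature", "sample", "fraction", "condition", "replicate",
           "log2_intensity", "observed")
}

#' Write a quant tibble as a wide tab-separated matrix
#'
#' @param data A quant tibble.
#' @param path Output path for the matrix (missing cells become empty
#'   fields).
#' @param design_path Optional path for the matching design file.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(data, path, design_path = NULL) {
  check_quant_tbl(data)
  wide <- data |>
    select("feature", "sample", "log2_intensity") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "log2_intensity") |>
    # full 17-digit precision so values round-trip bit-for-bit
    mutate(across(-"feature",
                  ~ if_else(is.na(.x), NA_character_, sprintf("%.17g", .x))))
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  if (!is.null(design_path)) {
    data |>
      distinct(.data$sample, .data$fraction, .data$condition,
               .data$replicate) |>
      readr::write_tsv(design_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a two-column marker list
#'
#' @param path Tab-separated file with columns `feature`, `compartment`
#'   (header optional when exactly two columns).
#' @return A marker map tibble.
#' @export
read_marker_map <- function(path) {
  markers <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("feature", "compartment") %in% names(markers))) {
    if (ncol(markers) == 2) {
      names(markers) <- c("feature", "compartment")
    } else {
      abort("marker file must have columns `feature` and `compartment`")
    }
  }
  if (anyDuplicated(markers$feature)) {
    abort("markers must map each feature to a single compartment")
  }
  markers[, c("feature", "compartment")]
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults; any subset
#' can be overridden via `...` or by a YAML file with the same keys.
#'
#' @param ... Named overrides.
#' @param yaml_path Optional YAML file of overrides (applied before `...`).
#' @return A named list of parameters.
#' @export
pipeline_config <- function(..., yaml_path = NULL) {
  config <- list(
    # simulation
    n_features = 1000, frac_translocating = 0.05,
    delta_min = 0.2, delta_max = 0.4, noise_sd = 0.3,
    mcar_rate = 0.02, mnar_midpoint = 18.5, mnar_slope = 1,
    conditions = c("ctrl", "stim1", "stim2"), onset = "stim1",
    replicates = 4, n_fractions = 6,
    # preprocessing
    min_valid = 3, span = 0.7, iterations = 3, k_neighbors = 10,
    quantile = 0.025,
    # translocation
    score_min = 0.1, fdr_max = 0.05, score_variant = "pair",
    # assignment
    k = NULL, restarts = 25,
    seed = 1
  )
  if (!is.null(yaml_path)) {
    config <- utils::modifyList(config, yaml::read_yaml(yaml_path))
  }
  overrides <- list(...)
  if (length(overrides) > 0) {
    stopifnot(!is.null(names(overrides)), all(names(overrides) != ""))
    config <- utils::modifyList(config, overrides)
  }
  for (key in c("frac_translocating", "mcar_rate", "quantile", "score_min",
                "fdr_max")) {
    v <- config[[key]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("config `%s` must be a proportion in [0, 1]", key))
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (unless `data` is supplied) -> preprocess ->
#' per-fraction moderated testing -> translocation calling -> marker-based
#' compartment assignment -> group distribution statistics, optionally
#' writing every stage table plus a machine-readable run manifest
#' (parameters, seed, package version, stage counts).
#'
#' @param config A configuration list from [pipeline_config()].
#' @param data Optional quant tibble; when `NULL` a synthetic dataset is
#'   generated from the config's simulation parameters (its markers are the
#'   true compartment labels of the first 10% of features).
#' @param markers Optional marker map for compartment assignment.
#' @param groups Optional named list of feature-id vectors for
#'   [group_fraction_percentages()].
#' @param out_dir Optional output directory; created if needed.
#' @return A list with `preprocessed`, `fits` (per fraction x contrast),
#'   `translocations`, `assignment`, `scores`, `distributions`, `manifest`
#'   (and `truth` for simulated data).
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         markers = NULL, groups = NULL, out_dir = NULL) {
  truth <- NULL
  if (is.null(data)) {
    sim <- simulate_fractionation(
      n_features = config$n_features,
      design = fraction_design(n_fractions = config$n_fractions,
                               conditions = config$conditions,
                               replicates = config$replicates),
      frac_translocating = config$frac_translocating,
      delta_range = c(config$delta_min, config$delta_max),
      onset = config$onset, noise_sd = config$noise_sd,
      mcar_rate = config$mcar_rate, mnar_midpoint = config$mnar_midpoint,
      mnar_slope = config$mnar_slope, seed = config$seed)
    data <- sim$data
    truth <- sim$truth
    if (is.null(markers)) {
      markers <- truth$features |>
        dplyr::slice_head(n = max(2L, round(nrow(truth$features) * 0.1))) |>
        select("feature", "compartment")
    }
  }
  stage <- "preprocess"
  result <- tryCatch({
    clean <- preprocess(data, min_valid = config$min_valid,
                        span = config$span, iterations = config$iterations,
                        k_neighbors = config$k_neighbors,
                        probs = config$quantile)
    stage <- "translocation"
    reference <- unique(clean$condition)[1]
    trans <- translocation_analysis(
      clean, reference = reference, score_min = config$score_min,
      fdr_max = config$fdr_max, variant = config$score_variant,
      min_valid = config$min_valid)
    stage <- "compartments"
    profiles <- clean |>
      filter(.data$condition == reference) |>
      scale_profiles()
    assignment <- scores <- NULL
    if (!is.null(markers)) {
      k <- config$k %||% (2 * length(unique(markers$compartment)))
      assignment <- assign_compartments(profiles, markers, k = k,
                                        restarts = config$restarts,
                                        seed = config$seed)
      scores <- score_compartments(assignment)
    }
    stage <- "diststats"
    distributions <- NULL
    if (!is.null(groups)) {
      distributions <- purrr::imap_dfr(groups, function(members, label) {
        group_fraction_percentages(clean, members, group = label)
      })
    }
    list(preprocessed = clean, translocations = trans,
         assignment = assignment, scores = scores,
         distributions = distributions)
  }, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)), parent = e)
  })

  manifest <- list(
    package = "translocatr",
    version = as.character(utils::packageVersion("translocatr")),
    parameters = config[!vapply(config, is.null, logical(1))],
    counts = list(
      n_features_in = length(unique(data$feature)),
      n_features_retained = length(unique(result$preprocessed$feature)),
      n_cells_imputed_knn = sum(result$preprocessed$imputed == "knn",
                                na.rm = TRUE),
      n_cells_imputed_detquant = sum(result$preprocessed$imputed == "detquant",
                                     na.rm = TRUE),
      n_translocations_called = sum(tidy(result$translocations)$called)
    )
  )
  result$manifest <- manifest
  result$truth <- truth

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_quant_table(result$preprocessed,
                      file.path(out_dir, "preprocessed.tsv"),
                      file.path(out_dir, "design.tsv"))
    readr::write_tsv(tidy(result$translocations),
                     file.path(out_dir, "translocations.tsv"),
                     progress = FALSE)
    if (!is.null(result$scores)) {
      readr::write_tsv(result$scores,
                       file.path(out_dir, "compartment_scores.tsv"),
                       progress = FALSE)
    }
    if (!is.null(result$distributions)) {
      readr::write_tsv(result$distributions,
                       file.path(out_dir, "group_distributions.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
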