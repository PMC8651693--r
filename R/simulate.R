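# Synthetic subcellular fractionation data with known ground truth:
# compartment-enriched intensity profiles, log-normal abundance/noise,
# injected translocation events, and MCAR + intensity-dependent (MNAR)
# dropout. Every downstream stage is validated against these truths.

#' Default compartment profile templates
#'
#' Six fraction-enrichment templates, one per subcellular compartment, each
#' dominant in one fraction with a fixed spillover proportion in an adjacent
#' fraction. This mimics the marker profile shapes seen in sequential
#' chemical fractionation (cytosolic extracts in FR1-2, membrane-bound
#' organelles in FR3-4, nuclear/nucleolar material in FR5-6) while staying
#' analytically tractable: the dominant fraction of each template is the
#' donor fraction for any injected translocation.
#'
#' @param n_fractions Number of fractions (default 6).
#' @param spillover Proportion of profile mass placed in the adjacent
#'   fraction (default 0.15); the remainder sits in the dominant fraction.
#' @param compartments Compartment labels, one per fraction.
#' @return A tibble with columns `compartment`, `fraction`, `proportion`;
#'   each compartment's proportions sum to 1.
#' @export
compartment_templates <- function(n_fractions = 6,
                                  spillover = 0.15,
                                  compartments = NULL) {
  stopifnot(n_fractions >= 2, spillover >= 0, spillover < 0.5)
  if (is.null(compartments)) {
    compartments <- if (n_fractions == 6) {
      c("cytosol", "cytoskeleton", "organelles", "plasma_membrane",
        "nucleus", "nucleolus")
    } else {
      sprintf("compartment_%d", seq_len(n_fractions))
    }
  }
  stopifnot(length(compartments) == n_fractions)
  purrr::map_dfr(seq_len(n_fractions), function(i) {
    prof <- rep(0, n_fractions)
    prof[i] <- 1 - spillover
    neighbour <- if (i < n_fractions) i + 1L else i - 1L
    prof[neighbour] <- prof[neighbour] + spillover
    tibble(compartment = compartments[i],
           fraction = seq_len(n_fractions),
           proportion = prof)
  })
}

check_templates <- function(templates) {
  stopifnot(is.data.frame(templates),
            all(c("compartment", "fraction", "proportion") %in% names(templates)))
  sums <- templates |>
    group_by(.data$compartment) |>
    summarise(s = sum(.data$proportion), nf = n(), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort("every compartment template must sum to 1 (tolerance 1e-9)")
  }
  if (any(sums$nf < 2)) abort("templates need at least 2 fractions")
  if (any(templates$proportion < 0)) abort("template proportions must be nonnegative")
  invisible(templates)
}

#' Generate ground truth for a synthetic fractionation experiment
#'
#' Assigns each feature a compartment (uniformly over the templates) and a
#' base abundance (log-uniform over `abundance_range`, log2 units), and
#' designates `round(n_features * frac_translocating)` features as
#' translocators. Each translocator moves a mass `delta` (drawn uniformly
#' from `delta_range`) from the dominant fraction of its compartment template
#' (the donor) to a uniformly chosen other fraction (the acceptor), from the
#' `onset` condition onwards.
#'
#' @param n_features Number of features (proteins or phospho-sites).
#' @param templates Compartment templates, see [compartment_templates()].
#' @param frac_translocating Proportion of features that translocate, in
#'   `[0, 1)`.
#' @param delta_range Interval from which the moved mass is drawn; must not
#'   exceed any template's donor proportion.
#' @param onset Condition label at (and after) which translocations apply.
#' @param mcar_rate Completely-at-random dropout probability, in `[0, 1)`.
#' @param mnar_midpoint,mnar_slope Midpoint (log2 intensity) and slope of the
#'   logistic intensity-dependent dropout curve; dropout probability is
#'   non-increasing in intensity for `mnar_slope >= 0`.
#' @param abundance_range Range of base abundances, log2 units.
#' @param seed Integer seed; identical seeds reproduce the truth
#'   field-for-field.
#' @return An object of class `synthetic_truth`: a list with tibbles
#'   `features` (feature, compartment, abundance) and `translocations`
#'   (feature, donor, acceptor, delta, onset), the `templates`, and
#'   missingness parameters.
#' @export
generate_truth <- function(n_features,
                           templates = compartment_templates(),
                           frac_translocating = 0.05,
                           delta_range = c(0.2, 0.4),
                           onset = "stim1",
                           mcar_rate = 0.02,
                           mnar_midpoint = 18.5,
                           mnar_slope = 1,
                           abundance_range = c(20, 30),
                           seed = 1) {
  check_templates(templates)
  stopifnot(n_features >= 1,
            frac_translocating >= 0, frac_translocating < 1,
            mcar_rate >= 0, mcar_rate < 1,
            mnar_slope >= 0)
  delta_range <- sort(delta_range)
  dominant <- templates |>
    group_by(.data$compartment) |>
    slice_max(.data$proportion, n = 1, with_ties = FALSE) |>
    ungroup()
  if (frac_translocating > 0 && delta_range[2] > min(dominant$proportion)) {
    abort(sprintf(
      "delta_range upper bound %.3f exceeds a template's donor proportion %.3f",
      delta_range[2], min(dominant$proportion)))
  }

  withr::with_seed(seed, {
    comps <- sample(unique(templates$compartment), n_features, replace = TRUE)
    features <- tibble(
      feature = sprintf("P%04d", seq_len(n_features)),
      compartment = comps,
      abundance = runif(n_features, abundance_range[1], abundance_range[2])
    )
    n_moving <- round(n_features * frac_translocating)
    translocations <- if (n_moving > 0) {
      movers <- sort(sample.int(n_features, n_moving))
      donor <- dominant$fraction[match(features$compartment[movers],
                                       dominant$compartment)]
      n_frac <- max(templates$fraction)
      acceptor <- vapply(donor, function(d) {
        sample(setdiff(seq_len(n_frac), d), 1L)
      }, integer(1))
      tibble(
        feature = features$feature[movers],
        donor = as.integer(donor),
        acceptor = as.integer(acceptor),
        delta = runif(n_moving, delta_range[1], delta_range[2]),
        onset = onset
      )
    } else {
      tibble(feature = character(), donor = integer(), acceptor = integer(),
             delta = double(), onset = character())
    }
    structure(
      list(features = features,
           translocations = translocations,
           templates = templates,
           mcar_rate = mcar_rate,
           mnar_midpoint = mnar_midpoint,
           mnar_slope = mnar_slope),
      class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d features, %d translocators, %d compartments\n",
              nrow(x$features), nrow(x$translocations),
              length(unique(x$templates$compartment))))
  cat(sprintf("  missingness: mcar %.3f, mnar logistic(midpoint %.1f, slope %.2f)\n",
              x$mcar_rate, x$mnar_midpoint, x$mnar_slope))
  invisible(x)
}

# Per feature x condition x fraction expected proportions, with the
# translocation shift applied at and after the onset condition.
truth_profiles <- function(truth, conditions) {
  conditions <- as.character(conditions)
  prof <- truth$features |>
    select("feature", "compartment") |>
    left_join(truth$templates, by = "compartment",
              relationship = "many-to-many") |>
    tidyr::expand_grid(condition = conditions)
  if (nrow(truth$translocations) > 0) {
    missing_onset <- setdiff(truth$translocations$onset, conditions)
    if (length(missing_onset) > 0) {
      abort(sprintf("design lacks onset condition(s): %s",
                    paste(missing_onset, collapse = ", ")))
    }
    shifts <- truth$translocations |>
      tidyr::expand_grid(condition = conditions) |>
      filter(match(.data$condition, conditions) >=
               match(.data$onset, conditions)) |>
      tidyr::pivot_longer(c("donor", "acceptor"),
                          names_to = "role", values_to = "fraction") |>
      mutate(shift = if_else(.data$role == "donor", -.data$delta, .data$delta)) |>
      select("feature", "condition", "fraction", "shift")
    prof <- prof |>
      left_join(shifts, by = c("feature", "condition", "fraction")) |>
      mutate(proportion = .data$proportion +
               tidyr::replace_na(.data$shift, 0)) |>
      select(-"shift")
  }
  if (any(prof$proportion < -1e-12)) {
    abort("translocation delta exceeds the donor proportion")
  }
  prof |> mutate(proportion = pmax(.data$proportion, 0))
}

#' Simulate log2 intensities from a synthetic truth
#'
#' The expected linear-scale intensity of feature i in fraction f is
#' `2^abundance_i * profile_i[f]` (the profile shifted by delta for
#' translocators at and after their onset condition); Gaussian measurement
#' noise of sd `noise_sd` is added on the log2 scale. Fractions where the
#' expected proportion is exactly zero are emitted as missing (structural
#' zeros), matching how search engines report non-detection.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param design A sample design from [fraction_design()]; must cover all
#'   onset conditions referenced by the truth.
#' @param noise_sd Measurement noise sd, log2 units.
#' @param seed Integer seed.
#' @return A quant tibble (feature, sample, fraction, condition, replicate,
#'   log2_intensity, observed, missing_reason).
#' @export
simulate_intensities <- function(truth, design, noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), noise_sd >= 0)
  conditions <- unique(design$condition)
  prof <- truth_profiles(truth, conditions)
  tab <- design |>
    tidyr::expand_grid(feature = truth$features$feature) |>
    left_join(prof, by = c("feature", "condition", "fraction")) |>
    left_join(select(truth$features, "feature", "abundance"), by = "feature") |>
    arrange(.data$feature, .data$condition, .data$fraction, .data$replicate)
  withr::with_seed(seed, {
    noise <- rnorm(nrow(tab), mean = 0, sd = noise_sd)
    tab <- tab |>
      mutate(
        log2_intensity = if_else(.data$proportion > 0,
                                 .data$abundance + log2(.data$proportion) + noise,
                                 NA_real_),
        observed = .data$proportion > 0,
        missing_reason = if_else(.data$observed, NA_character_, "structural")
      )
  })
  tab |>
    select("feature", "sample", "fraction", "condition", "replicate",
           "log2_intensity", "observed", "missing_reason")
}

#' Apply two-regime missingness to a simulated quant table
#'
#' Each observed cell is dropped independently with probability
#' `mcar + (1 - mcar) * logistic(-slope * (x - midpoint))`: a constant
#' completely-at-random term plus an intensity-dependent (not-at-random)
#' term that increases as log2 intensity falls below the logistic midpoint.
#' The regime responsible for each dropped cell is recorded in the
#' `missing_reason` column ("mcar" or "mnar") for downstream assertions.
#'
#' @param table A quant tibble from [simulate_intensities()].
#' @param truth The `synthetic_truth` carrying the missingness parameters.
#' @param seed Integer seed.
#' @return The quant tibble with dropped cells set to missing.
#' @export
apply_missingness <- function(table, truth, seed = 1) {
  check_quant_tbl(table, "table")
  stopifnot(inherits(truth, "synthetic_truth"))
  obs <- table$observed
  x <- table$log2_intensity
  p_mnar <- stats::plogis(-truth$mnar_slope * (x - truth$mnar_midpoint))
  p_drop <- truth$mcar_rate + (1 - truth$mcar_rate) * p_mnar
  withr::with_seed(seed, {
    u <- runif(nrow(table))
  })
  drop <- obs & u < p_drop
  regime <- if_else(u < truth$mcar_rate, "mcar", "mnar")
  table |>
    mutate(
      missing_reason = if_else(drop, regime, .data$missing_reason),
      log2_intensity = if_else(drop, NA_real_, .data$log2_intensity),
      observed = .data$observed & !drop
    )
}

#' Simulate a complete fractionation dataset
#'
#' Convenience wrapper chaining [generate_truth()], [simulate_intensities()]
#' and [apply_missingness()]. The defaults emulate the study conditions used
#' throughout the package's validation: 1000 features across six fractions,
#' four replicates, a control plus two post-stimulus time points, 5% of
#' features translocating with delta in \[0.2, 0.4\] from the first
#' post-stimulus time point, 0.3 log2-units measurement noise, 2% MCAR
#' dropout plus logistic intensity-dependent dropout.
#'
#' @param n_features Number of features.
#' @param design Sample design; defaults to 6 fractions x
#'   (ctrl, stim1, stim2) x 4 replicates.
#' @param noise_sd Measurement noise sd, log2 units.
#' @param missingness If `FALSE`, skip the dropout step (structural zeros
#'   are still missing).
#' @param seed Integer seed; sub-seeds for the three stages are derived
#'   from it.
#' @inheritParams generate_truth
#' @return A list with elements `data` (quant tibble), `truth`
#'   (`synthetic_truth`) and `design`.
#' @examples
#' sim <- simulate_fractionation(n_features = 50, seed = 7)
#' dplyr::count(sim$data, observed)
#' @export
simulate_fractionation <- function(n_features = 1000,
                                   design = fraction_design(
                                     conditions = c("ctrl", "stim1", "stim2"),
                                     replicates = 4),
                                   templates = compartment_templates(),
                                   frac_translocating = 0.05,
                                   delta_range = c(0.2, 0.4),
                                   onset = "stim1",
                                   noise_sd = 0.3,
                                   mcar_rate = 0.02,
                                   mnar_midpoint = 18.5,
                                   mnar_slope = 1,
                                   missingness = TRUE,
                                   seed = 1) {
  if (frac_translocating > 0 && !onset %in% design$condition) {
    abort("`onset` must be one of the design's conditions")
  }
  truth <- generate_truth(
    n_features, templates = templates,
    frac_translocating = frac_translocating, delta_range = delta_range,
    onset = onset, mcar_rate = mcar_rate, mnar_midpoint = mnar_midpoint,
    mnar_slope = mnar_slope, seed = seed)
  data <- simulate_intensities(truth, design, noise_sd = noise_sd,
                               seed = seed + 1L)
  if (missingness) data <- apply_missingness(data, truth, seed = seed + 2L)
  list(data = data, truth = truth, design = design)
}
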