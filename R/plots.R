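# ggplot2 views of the result objects: translocation score-vs-significance
# plots, marker profile plots with centroids, and compartment F-score bars.

category_palette <- c(
  "cytosol-membrane" = "#1b9e77",
  "cytosol-nuclear" = "#1f78b4",
  "membrane-nuclear" = "#e31a1c",
  "within" = "grey60",
  "none" = "grey85"
)

#' Plot translocation calls per time point
#'
#' Movement score versus -log10 of the BH-corrected combined p-value, one
#' panel per time point, coloured by the neighbourhood category of the move
#' (green: cytosol to/from membrane; blue: cytosol to/from nuclear; red:
#' membrane to/from nuclear; grey: within one neighbourhood), with dashed
#' cutoff lines at the calling thresholds.
#'
#' @param object A `translocation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.translocation_result <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$score,
                                      y = -log10(.data$q_value),
                                      colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.3) +
    ggplot2::geom_vline(xintercept = object$score_min,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(object$fdr_max),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(values = category_palette) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "movement score",
                  y = expression(-log[10] ~ "q (combined)"),
                  colour = "move between") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.translocation_result
#' @param x A `translocation_result`.
#' @export
plot.translocation_result <- function(x, ...) print(autoplot.translocation_result(x, ...))

#' Plot marker fraction profiles with compartment centroids
#'
#' One panel per compartment: each marker's scaled profile as a thin line
#' shaded by its Pearson correlation to the compartment centroid, the
#' centroid itself as a thick line.
#'
#' @param profiles Profile tibble (`feature`, `fraction`, `value` or
#'   `proportion`).
#' @param markers Marker map tibble (`feature`, `compartment`).
#' @return A ggplot object.
#' @export
plot_marker_profiles <- function(profiles, markers) {
  profiles <- normalize_profile_cols(profiles)
  cors <- marker_centroid_correlation(profiles, markers)
  marker_prof <- profiles |>
    inner_join(markers, by = "feature") |>
    left_join(cors, by = c("feature", "compartment"))
  centroids <- marker_prof |>
    group_by(.data$compartment, .data$fraction) |>
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(marker_prof,
                  ggplot2::aes(x = .data$fraction, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$feature,
                                    colour = .data$centroid_cor),
                       linewidth = 0.4) +
    ggplot2::geom_line(data = centroids, colour = "goldenrod",
                       linewidth = 1.2) +
    ggplot2::scale_colour_gradient(low = "white", high = "blue",
                                   limits = c(NA, 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$compartment)) +
    ggplot2::scale_x_continuous(breaks = sort(unique(marker_prof$fraction)),
                                labels = function(b) paste0("FR", b)) +
    ggplot2::labs(x = NULL, y = "scaled intensity",
                  colour = "r to centroid") +
    ggplot2::theme_bw()
}

#' Bar plot of per-compartment F-scores
#'
#' @param scores Output of [score_compartments()].
#' @return A ggplot object.
#' @export
plot_compartment_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$compartment,
                                       y = .data$f_score)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "F-score") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot group distribution across fractions
#'
#' Percentage of the group's total intensity per fraction, replicate points
#' with per-condition mean lines — the percentage-of-total view used for
#' ribosomal subunit redistribution.
#'
#' @param distribution Output of [group_fraction_percentages()].
#' @return A ggplot object.
#' @export
plot_group_distribution <- function(distribution) {
  means <- distribution |>
    group_by(.data$group, .data$condition, .data$fraction) |>
    summarise(percentage = mean(.data$percentage), .groups = "drop")
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$fraction, y = .data$percentage,
                               colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = means, linewidth = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::scale_x_continuous(breaks = sort(unique(distribution$fraction)),
                                labels = function(b) paste0("FR", b)) +
    ggplot2::labs(x = NULL, y = "% of group total") +
    ggplot2::theme_bw()
}
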