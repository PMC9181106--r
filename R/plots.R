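# ggplot2 views of the main result types. Styling is intentionally plain;
# these are working plots, not figure reproductions.

#' Plot a log2-ratio distribution with dosage reference lines
#'
#' Frequency curves per class with the compensation (0), positive dosage
#' (+log2(3/2), solid) and inverse dosage (-log2(3/2), dashed) reference
#' verticals.
#'
#' @param records Ratio records from [group_log2_ratios()].
#' @param bin_width,range Passed to [ratio_histogram()].
#' @return A ggplot object.
#' @export
plot_ratio_distribution <- function(records, bin_width = 0.1,
                                    range = c(-3, 3)) {
  h <- ratio_histogram(records, bin_width, range)$histogram
  frame <- dosage_frame()
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$frequency,
                                  colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = frame$log2_ratio[frame$line ==
                                                        "compensation"],
                        colour = "darkgreen") +
    ggplot2::geom_vline(xintercept = frame$log2_ratio[frame$line ==
                                                        "positive_dosage"],
                        colour = "black") +
    ggplot2::geom_vline(xintercept = frame$log2_ratio[frame$line ==
                                                        "inverse_dosage"],
                        colour = "black", linetype = "dashed") +
    ggplot2::labs(x = "log2(mutant / WT)", y = "frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot lncRNA class proportions
#'
#' @param proportions Tibble from [class_proportions()].
#' @return A ggplot object.
#' @export
plot_class_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = stats::reorder(.data$class, -.data$n),
                               y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%",
                                                    100 * .data$fraction)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "fraction of lncRNAs") +
    ggplot2::theme_minimal()
}

#' Plot embryo fluorescence comparisons per stage group
#'
#' Mean relative intensity per genotype and stage with the significance
#' label of the pooled t-test above each stage.
#'
#' @param measurements Embryo measurement tibble (see
#'   [generate_embryo_table()]).
#' @return A ggplot object.
#' @export
plot_fish_comparison <- function(measurements) {
  m <- relative_intensity(measurements)
  stats_tbl <- compare_fish_groups(measurements)
  m$stage <- factor(m$stage, levels = .FISH_STAGES)
  stats_tbl$stage <- factor(stats_tbl$stage, levels = .FISH_STAGES)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$stage, y = .data$ratio,
                                  fill = .data$genotype)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_text(
      data = stats_tbl,
      ggplot2::aes(x = .data$stage, label = .data$label,
                   y = max(m$ratio) * 1.05),
      inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = "probe / DAPI intensity", fill = NULL) +
    ggplot2::theme_minimal()
}
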