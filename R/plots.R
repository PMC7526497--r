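#' Plot a cohort repair-pattern composition
#'
#' Stacked percentage bars of the four junction categories per cohort.
#'
#' @param object An `sj_cohort_table` (see [summarize_cohort()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sj_cohort_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cohort, y = .data$percent,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "stack", colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", name = "junction class") +
    ggplot2::labs(x = NULL, y = "junctions (%)") +
    ggplot2::theme_minimal()
}

#' Plot a per-category cohort comparison
#'
#' Side-by-side category proportions for the two cohorts, annotated with
#' the per-category chi-squared p-values.
#'
#' @param object An `sj_comparison` (see [compare_categories()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sj_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, prop_a = .data$prop_a, prop_b = .data$prop_b),
    cols = c("prop_a", "prop_b"), names_to = "cohort", values_to = "prop")
  long$cohort <- ifelse(long$cohort == "prop_a", "cohort A", "cohort B")
  labs <- dplyr::mutate(object,
                        lab = ifelse(is.na(.data$p_value), "n/a",
                                     sprintf("p = %.4f", .data$p_value)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$prop,
                                     fill = .data$cohort)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$class, label = .data$lab,
                                    y = pmax(.data$prop_a, .data$prop_b)),
                       inherit.aes = FALSE, vjust = -0.6, size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x,
                                expand = ggplot2::expansion(mult = c(0, .15))) +
    ggplot2::labs(x = NULL, y = "junctions (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot binned reporter-junction deletion sizes
#'
#' @param object An `sj_del_bins` (see [bin_deletion_sizes()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sj_del_bins <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "deletion size (nt)", y = "junctions") +
    ggplot2::theme_minimal()
}

#' Plot microhomology usage among deletion-bearing junctions
#'
#' @param object An `sj_mh_usage` (see [mh_usage_in_deletions()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sj_mh_usage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$mh_len),
                                       y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "microhomology length (bp)", y = "junctions") +
    ggplot2::theme_minimal()
}
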