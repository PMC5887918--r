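#' Plot methods for dietlink results
#'
#' `autoplot()` methods returning ggplot objects: selection results show
#' observed counts against null expectations with 95% limits; threshold
#' selections show the diagnostics across the grid; accumulation curves
#' show expected richness with the coverage milestones; ordinations show
#' the sample scores.
#'
#' @param object a dietlink result object.
#' @param ... unused.
#' @return a `ggplot`.
#' @name dietlink-autoplot
NULL

#' @rdname dietlink-autoplot
#' @export
autoplot.selection_result <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = stats::reorder(.data$taxon,
                                                       -.data$expected))) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower,
                                         ymax = .data$upper),
                            colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), shape = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$class), size = 2) +
    ggplot2::scale_colour_manual(values = c(preferred = "#D55E00",
                                            avoided = "#0072B2",
                                            neutral = "grey30")) +
    ggplot2::labs(x = NULL, y = "individuals positive",
                  colour = "selection",
                  title = sprintf("Prey choice vs proportional null (S = %.2f)",
                                  object$selection_strength)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname dietlink-autoplot
#' @export
autoplot.threshold_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object$diagnostics, -"threshold",
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "similarity threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname dietlink-autoplot
#' @export
autoplot.accumulation_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$n,
                                             .data$expected_richness)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$chao2, linetype = 3) +
    ggplot2::geom_vline(data = object$n_for_fraction,
                        ggplot2::aes(xintercept = .data$n_interpolated),
                        linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "individuals examined", y = "expected prey richness",
                  title = sprintf("S_obs = %d, Chao2 = %.1f",
                                  object$S_obs, object$chao2)) +
    ggplot2::theme_minimal()
}

#' @rdname dietlink-autoplot
#' @export
autoplot.nmds_ordination <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2,
                                   label = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("NMDS (stress = %.3f)", object$stress)) +
    ggplot2::theme_minimal()
}
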