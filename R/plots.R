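#' Plot an empirical semivariogram
#'
#' @param object an [empirical_semivariogram()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iv_semivariogram <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$n_pairs > 0),
                  ggplot2::aes(x = .data$bin_mid, y = .data$semivariance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::scale_size_area(name = "pairs") +
    ggplot2::labs(x = "distance", y = "semivariance") +
    ggplot2::theme_minimal()
}

#' Plot per-species and pooled semivariogram curves
#'
#' The pooled ("all") curve sitting above the per-species curves at short
#' distances is the signature of intraspecific variability being smaller
#' than interspecific variability locally.
#'
#' @param object a [semivariogram_curves()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iv_semivariogram_set <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$n_pairs > 0),
                  ggplot2::aes(x = .data$bin_mid, y = .data$semivariance,
                               colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(linewidth = .data$group == "all"),
                       show.legend = c(linewidth = FALSE)) +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 1.2, `FALSE` = 0.6)) +
    ggplot2::labs(x = "distance", y = "semivariance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a variance partition
#'
#' @param object a [partition_variance()] result.
#' @param ... unused.
#' @return a ggplot (horizontal bars, percentage labels).
#' @export
autoplot.iv_variance_partition <- function(object, ...) {
  df <- dplyr::mutate(object,
                      component = stats::reorder(.data$component,
                                                 .data$percentage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percentage, y = .data$component)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percentage)),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "% of summed variance components", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a posterior predictive envelope
#'
#' Mean response curve and credible band against the observed covariate,
#' per species; optionally overlay the data points the model was fitted to.
#'
#' @param object a [predictive_envelope()] result.
#' @param data optional tibble with `X1`, `Y`, `j` columns to overlay.
#' @param ... unused.
#' @return a ggplot (log Y scale on the y axis).
#' @export
autoplot.iv_envelope <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$x1, colour = factor(.data$species),
                                    fill = factor(.data$species)))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, inherit.aes = FALSE,
      mapping = ggplot2::aes(x = .data$X1, y = log(.data$Y),
                             colour = factor(.data$j)),
      alpha = 0.3)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.9) +
    ggplot2::labs(x = "X1", y = "ln Y", colour = "species", fill = "species") +
    ggplot2::theme_minimal()
}
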