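# ggplot2 views of the result objects.

#' Plot the 12-class substitution profile of an error report
#'
#' @param object An `error_report`.
#' @param ... Unused.
#' @return A ggplot: per-class error rates, complementary classes side by
#'   side (the oxidative signature shows as a G>T bar towering over C>A).
#' @method autoplot error_report
#' @export
autoplot.error_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "substitution (reference > observed)",
                  y = "per-base error rate") +
    ggplot2::theme_minimal()
}

#' Plot the stream sizes of a pipeline run
#'
#' @param object A `duplex_run`.
#' @param ... Unused.
#' @return A ggplot of read/consensus counts per output stream.
#' @method autoplot duplex_run
#' @export
autoplot.duplex_run <- function(object, ...) {
  d <- tidy(object)
  d$stream <- factor(d$stream, levels = rev(d$stream))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$stream)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "count", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the family-size distribution of a run
#'
#' @param run A `duplex_run`.
#' @return A ggplot histogram of read-family sizes.
#' @export
plot_family_sizes <- function(run) {
  d <- family_size_distribution(run$pairs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family_size,
                                  y = .data$n_families)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "reads per family", y = "families") +
    ggplot2::theme_minimal()
}

#' Plot a depth sweep
#'
#' @param sweep Output of [depth_sweep()].
#' @param metric Column of the sweep to chart against depth.
#' @return A ggplot: the metric versus log10 mean target coverage, one
#'   line per correction mode, averaged over repeats.
#' @export
plot_depth_sweep <- function(sweep, metric = "recovery_dcs") {
  d <- dplyr::summarise(
    dplyr::group_by(sweep, .data$target, .data$sc),
    value = mean(.data[[metric]], na.rm = TRUE), .groups = "drop")
  d$mode <- ifelse(d$sc, "Singleton Correction", "traditional")
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$target), y = .data$value,
                                  colour = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "log10 mean target coverage", y = metric,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
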