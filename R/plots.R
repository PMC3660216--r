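#' Plot a true-positive power curve
#'
#' Mean true positives against effect size with one-standard-deviation
#' error bars, one curve per normalization method (faceted by test when
#' several were run).
#'
#' @param x A `power_summary` tibble from [power_curve()].
#' @param object Same as `x` (for `autoplot`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(x, ...) {
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$e, y = .data$tp_mean,
                                       colour = .data$method)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$tp_mean - .data$tp_sd,
                                        ymax = .data$tp_mean + .data$tp_sd),
                           width = 0.05, alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = x$m1[1], linetype = "dotted") +
    ggplot2::labs(x = "effect size e", y = "mean true positives",
                  colour = "normalization") +
    ggplot2::theme_minimal()
  if (length(unique(x$test)) > 1) {
    p <- p + ggplot2::facet_wrap(~test)
  }
  p
}

#' @rdname plot_power_curve
#' @method autoplot power_summary
#' @export
autoplot.power_summary <- function(object, ...) plot_power_curve(object, ...)

#' Plot the median |t| curve
#'
#' Median absolute DEG t-statistic against effect size per normalization
#' method: linear growth for raw data, a bounded curve after quantile
#' normalization.
#'
#' @param x A `median_t_curve` tibble from [median_abs_t_curve()].
#' @param object Same as `x` (for `autoplot`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_median_t_curve <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$e, y = .data$median_abs_t,
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "effect size e", y = "median |t| over DEGs",
                  colour = "normalization") +
    ggplot2::theme_minimal()
}

#' @rdname plot_median_t_curve
#' @method autoplot median_t_curve
#' @export
autoplot.median_t_curve <- function(object, ...) {
  plot_median_t_curve(object, ...)
}

#' Plot DEG t-statistic densities
#'
#' Kernel density estimates of the DEG t-statistics, faceted by effect
#' size, one curve per normalization method; after quantile normalization
#' at large effect sizes the interior (doubly noncentral) and outer
#' (noncentral) modes of the mixture are visible.
#'
#' @param x A `t_density` tibble from [t_density_estimate()].
#' @param object Same as `x` (for `autoplot`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_t_density <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$x, y = .data$density,
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~e, scales = "free", labeller = ggplot2::label_both) +
    ggplot2::labs(x = "t statistic", y = "density",
                  colour = "normalization") +
    ggplot2::theme_minimal()
}

#' @rdname plot_t_density
#' @method autoplot t_density
#' @export
autoplot.t_density <- function(object, ...) plot_t_density(object, ...)

#' Overlay a theoretical mixture density on simulated t-statistics
#'
#' @param density_tbl One (`e`, `method`) cell of [t_density_estimate()].
#' @param params A [mixture_t_params()] object, e.g. from
#'   [calibrate_mixture_params()].
#' @return A ggplot object with the empirical estimate (solid) and the
#'   mixture density (dashed).
#' @export
plot_mixture_overlay <- function(density_tbl, params) {
  theo <- tibble::tibble(x = density_tbl$x,
                         density = mixture_density(density_tbl$x, params))
  ggplot2::ggplot(density_tbl, ggplot2::aes(x = .data$x,
                                            y = .data$density)) +
    ggplot2::geom_line(ggplot2::aes(linetype = "simulated")) +
    ggplot2::geom_line(data = theo,
                       ggplot2::aes(linetype = "mixture theory")) +
    ggplot2::labs(x = "t statistic", y = "density", linetype = NULL) +
    ggplot2::theme_minimal()
}
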