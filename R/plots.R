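#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pixel-wise fit map
#'
#' Raster view of the T2* (default), R^2 or retained-echo-count map over
#' the myocardium.
#'
#' @param object A `t2star_fitmaps` object.
#' @param what One of `"t2star"`, `"r2"`, `"nte"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.t2star_fitmaps <- function(object, what = c("t2star", "r2", "nte"),
                                    ...) {
  what <- match.arg(what)
  px <- tidy.t2star_fitmaps(object)
  px$value <- switch(what, t2star = px$t2star_ms, r2 = px$r2,
                     nte = px$n_te_used)
  lab <- switch(what, t2star = "T2* (ms)", r2 = expression(R^2),
                nte = "echoes used")
  ggplot2::ggplot(px, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(title = sprintf("%s map (%s)", what, object$method),
                  x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Plot an AHA segment label map
#'
#' @param object A `segment_label_map`.
#' @param ... Unused.
#' @return A ggplot with one colour per segment.
#' @export
autoplot.segment_label_map <- function(object, ...) {
  px <- tidy.segment_label_map(object)
  ggplot2::ggplot(px, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$segment_id))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("AHA segments (%s slice)",
                                  attr(object, "slice_level")),
                  x = "column", y = "row", fill = "segment") +
    ggplot2::theme_minimal()
}

#' Histogram of pixel T2* by coronary territory
#'
#' @param pools Tibble from [pool_by_territory()] (or the study's
#'   `territory_pools`), optionally spanning several methods.
#' @param binwidth Histogram bin width in ms.
#' @return A ggplot faceted by method when several are present.
#' @export
plot_territory_pools <- function(pools, binwidth = 2) {
  p <- ggplot2::ggplot(pools,
                       ggplot2::aes(x = .data$t2star_ms,
                                    fill = .data$artery)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "pixel T2* (ms)", y = "pixels",
                  fill = "territory") +
    ggplot2::theme_minimal()
  if (length(unique(pools$method)) > 1) {
    p <- p + ggplot2::facet_wrap(~method)
  }
  p
}

#' Bias/RMSE curves from a recovery experiment
#'
#' @param results Tibble from [recovery_experiment()].
#' @param metric `"median_bias_pct"` or `"rmse_ms"`.
#' @return A ggplot of the metric against true T2*, coloured by method.
#' @export
plot_recovery <- function(results, metric = c("median_bias_pct", "rmse_ms")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$t2star_ms,
                               y = .data[[metric]],
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(snr ~ plateau_frac,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "true T2* (ms)", y = metric) +
    ggplot2::theme_minimal()
}
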