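IRON_CLASSES <- c("normal", "moderate", "severe")

#' Median and median absolute deviation of a segment's pixel T2* values
#'
#' The segmental summary statistic pair used throughout: the median and the
#' unscaled MAD (median of absolute deviations from the median, no
#' normal-consistency constant).
#'
#' @param t2star_values Numeric vector of pixel T2* values (ms), >= 1 finite
#'   value.
#' @return One-row tibble with `median_t2star_ms`, `mad_ms`, `n_pixels`.
#' @export
summarize_segment <- function(t2star_values) {
  v <- t2star_values[is.finite(t2star_values)]
  assert_that(length(v) >= 1L, "segment has no finite T2* values")
  m <- median(v)
  tibble::tibble(median_t2star_ms = m, mad_ms = median(abs(v - m)),
                 n_pixels = length(v))
}

#' Iron-deposition class from a segmental median T2*
#'
#' At 1.5 T: normal (no iron deposition) for T2* > 20 ms, moderate iron
#' deposition for 10 ms <= T2* <= 20 ms, severe for T2* < 10 ms. The lower
#' moderate boundary is closed by default; set `moderate_lower_closed =
#' FALSE` for the open variant (T2* = 10 ms then classifies as severe).
#'
#' @param median_t2star_ms Numeric vector of positive segmental medians (ms).
#' @param moderate_lower_closed Whether T2* exactly 10 ms is moderate
#'   (default) rather than severe.
#' @return Factor with levels `normal`, `moderate`, `severe`.
#' @export
classify_iron <- function(median_t2star_ms, moderate_lower_closed = TRUE) {
  assert_that(all(is.finite(median_t2star_ms)) && all(median_t2star_ms > 0),
              "T2* medians must be positive")
  cls <- ifelse(median_t2star_ms > 20, "normal",
         ifelse(median_t2star_ms > 10 |
                  (moderate_lower_closed & median_t2star_ms == 10),
                "moderate", "severe"))
  factor(cls, levels = IRON_CLASSES)
}

#' Per-segment T2* summary with iron classification
#'
#' Collapses a pixel-wise fit map over an AHA label map into one row per
#' segment: median T2*, MAD, pixel count and iron class.
#'
#' @param fit_maps A `t2star_fitmaps` object.
#' @param labels A `segment_label_map` aligned with the maps.
#' @param moderate_lower_closed Passed to [classify_iron()].
#' @return Tibble with `segment_id`, `median_t2star_ms`, `mad_ms`,
#'   `n_pixels`, `iron_class`, `method`.
#' @export
segment_summary <- function(fit_maps, labels, moderate_lower_closed = TRUE) {
  stopifnot(inherits(fit_maps, "t2star_fitmaps"))
  px <- tidy.t2star_fitmaps(fit_maps)
  lab <- tidy.segment_label_map(labels)[, c("row", "col", "segment_id")]
  px |>
    dplyr::inner_join(lab, by = c("row", "col")) |>
    dplyr::reframe(summarize_segment(.data$t2star_ms),
                   .by = "segment_id") |>
    dplyr::mutate(iron_class = classify_iron(.data$median_t2star_ms,
                                             moderate_lower_closed),
                  method = fit_maps$method) |>
    dplyr::arrange(.data$segment_id)
}

#' TE-usage breakdown of truncated fits by iron class
#'
#' Cross-tabulates pixel-wise fits by iron class, method and number of
#' echoes retained (8 down to the 4-point floor), reporting median +/- MAD
#' of pixel T2* and the percentage of the class total in each cell. The
#' class of every pixel is the one its segment receives under the classic
#' (untruncated) fit, so the same pixel population is followed across
#' methods.
#'
#' @param pixel_fits Tibble of per-pixel fits carrying at least
#'   `t2star_ms`, `n_te_used`, `method` and `iron_class` (the classic-fit
#'   class), e.g. assembled from [tidy()] outputs joined with
#'   [segment_summary()] classes.
#' @return Tibble with one row per (iron_class, method, n_te_used):
#'   `median_t2star_ms`, `mad_ms`, `n_pixels`, `pct_of_class`.
#' @export
te_usage_breakdown <- function(pixel_fits) {
  assert_that(all(c("t2star_ms", "n_te_used", "method", "iron_class") %in%
                    names(pixel_fits)),
              "pixel_fits needs t2star_ms, n_te_used, method, iron_class")
  cells <- pixel_fits |>
    dplyr::reframe(summarize_segment(.data$t2star_ms),
                   .by = c("iron_class", "method", "n_te_used"))
  cells |>
    dplyr::mutate(pct_of_class = 100 * .data$n_pixels / sum(.data$n_pixels),
                  .by = c("iron_class", "method")) |>
    dplyr::arrange(.data$iron_class, .data$method,
                   dplyr::desc(.data$n_te_used))
}

#' Attach classic-fit iron classes to pixel fits
#'
#' Convenience assembler for [te_usage_breakdown()]: joins tidied fit maps
#' from several methods with the per-segment classes derived from the
#' classic fit.
#'
#' @param fit_maps_list List of `t2star_fitmaps`, one of which has
#'   `method == "classic"`.
#' @param labels A `segment_label_map`.
#' @return Tibble of pixel fits with an `iron_class` column.
#' @export
pixel_fits_with_class <- function(fit_maps_list, labels) {
  methods <- vapply(fit_maps_list, function(m) m$method, "")
  assert_that("classic" %in% methods,
              "a classic fit map is required to define the iron classes")
  classic <- fit_maps_list[[match("classic", methods)]]
  classes <- segment_summary(classic, labels)[, c("segment_id", "iron_class")]
  lab <- tidy.segment_label_map(labels)[, c("row", "col", "segment_id")]
  purrr::map_dfr(fit_maps_list, tidy.t2star_fitmaps) |>
    dplyr::inner_join(lab, by = c("row", "col")) |>
    dplyr::inner_join(classes, by = "segment_id")
}
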