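ARTERIES <- c("LAD", "RCA", "LCx")

#' Traditional coronary-artery territory table
#'
#' The all-or-nothing mapping of AHA 16 segments to the three coronary
#' territories: LAD supplies the anterior/anteroseptal segments
#' \{1, 2, 7, 8, 13, 14\}, RCA the inferior/inferoseptal segments
#' \{3, 4, 9, 10, 15\}, and LCx the lateral segments \{5, 6, 11, 12, 16\}.
#' Detailed per-segment contribution percentages (most segments are served
#' by more than one artery) can be supplied instead via
#' [read_territory_table()].
#'
#' @return Tibble with columns `segment_id`, `artery`, `fraction` (all 1).
#' @export
traditional_territories <- function() {
  tbl <- tibble::tibble(
    segment_id = c(1L, 2L, 7L, 8L, 13L, 14L,
                   3L, 4L, 9L, 10L, 15L,
                   5L, 6L, 11L, 12L, 16L),
    artery = rep(ARTERIES, c(6L, 5L, 5L)),
    fraction = 1)
  dplyr::arrange(tbl, .data$segment_id)
}

validate_territory_table <- function(tbl) {
  assert_that(all(c("segment_id", "artery", "fraction") %in% names(tbl)),
              "territory table needs columns segment_id, artery, fraction")
  assert_that(all(tbl$artery %in% ARTERIES),
              "artery must be one of LAD, RCA, LCx")
  assert_that(all(tbl$fraction >= 0 & tbl$fraction <= 1),
              "fractions must lie in [0, 1]")
  sums <- tbl |>
    dplyr::summarise(s = sum(.data$fraction), .by = "segment_id")
  assert_that(setequal(sums$segment_id, 1:16),
              "every segment 1-16 must be present")
  assert_that(all(abs(sums$s - 1) <= 1e-6),
              "per-segment contribution fractions must sum to 1")
  invisible(tbl)
}

#' Read a coronary contribution table from CSV
#'
#' Columns `segment_id`, `artery` (LAD/RCA/LCx), `fraction`; fractions per
#' segment must sum to 1 and all 16 segments must be present.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_territory_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(segment_id = "i",
                                                 artery = "c",
                                                 fraction = "d"))
  validate_territory_table(tbl)
  tbl
}

#' Segments dominated by a single coronary artery
#'
#' Groups segments by the artery holding their largest contribution
#' fraction, keeping only segments whose top fraction reaches the
#' exclusivity threshold. With the traditional all-or-nothing table and
#' threshold 1, every segment is assigned; with a detailed contribution
#' table, only dominantly supplied segments survive (e.g. segments 1, 7,
#' 13 exclusively supplied by the LAD, segment 5 by the LCx).
#'
#' @param table A territory contribution tibble
#'   (default [traditional_territories()]).
#' @param exclusivity_threshold Minimum top fraction in (0, 1].
#' @return Named list (`LAD`, `RCA`, `LCx`) of integer segment-ID vectors.
#' @export
dominant_segments <- function(table = traditional_territories(),
                              exclusivity_threshold = 1) {
  validate_territory_table(table)
  assert_that(is_scalar_number(exclusivity_threshold) &&
                exclusivity_threshold > 0 && exclusivity_threshold <= 1,
              "exclusivity_threshold must lie in (0, 1]")
  top <- table |>
    dplyr::slice_max(.data$fraction, n = 1, by = "segment_id",
                     with_ties = FALSE) |>
    dplyr::filter(.data$fraction >= exclusivity_threshold)
  lapply(setNames(ARTERIES, ARTERIES),
         function(a) sort(top$segment_id[top$artery == a]))
}

#' Pool pixel-wise T2* by coronary territory
#'
#' Routes every fitted myocardial pixel to the artery owning its AHA
#' segment under the given assignment; pixels of unassigned segments are
#' excluded. Each pixel appears in exactly one artery's pool.
#'
#' @param fit_maps A `t2star_fitmaps` object (see [fit_map()]).
#' @param labels A `segment_label_map` aligned with the maps.
#' @param assignment Named list of per-artery segment IDs, as returned by
#'   [dominant_segments()].
#' @return Tibble with columns `artery`, `segment_id`, `row`, `col`,
#'   `t2star_ms`, `method`.
#' @export
pool_by_territory <- function(fit_maps, labels,
                              assignment = dominant_segments()) {
  stopifnot(inherits(fit_maps, "t2star_fitmaps"))
  px <- tidy.t2star_fitmaps(fit_maps)
  lab <- tidy.segment_label_map(labels)[, c("row", "col", "segment_id")]
  map_tbl <- purrr::imap_dfr(assignment, function(segs, artery) {
    tibble::tibble(artery = artery, segment_id = as.integer(segs))
  })
  px |>
    dplyr::inner_join(lab, by = c("row", "col")) |>
    dplyr::inner_join(map_tbl, by = "segment_id") |>
    dplyr::select("artery", "segment_id", "row", "col", "t2star_ms", "method")
}
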