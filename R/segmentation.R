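#' Rasterize the myocardium between the epicardial and endocardial contours
#'
#' A pixel (0-based centre coordinates) belongs to the myocardium when it
#' lies inside the epicardial polygon and outside the endocardial polygon
#' (even-odd rule).
#'
#' @param contours A [contour_set()].
#' @param shape Length-2 integer, the image `(rows, cols)`.
#' @return Logical matrix of the given shape; errors if the resulting ring
#'   is empty.
#' @export
rasterize_myocardium <- function(contours, shape) {
  stopifnot(inherits(contours, "contour_set"))
  assert_that(length(shape) == 2L && all(shape >= 1),
              "shape must be (rows, cols)")
  epi <- contours$epicardial
  endo <- contours$endocardial
  # restrict point-in-polygon tests to the epicardial bounding box
  r_rng <- pmax(0L, pmin(shape[1] - 1L,
                         c(floor(min(epi[, 1])), ceiling(max(epi[, 1])))))
  c_rng <- pmax(0L, pmin(shape[2] - 1L,
                         c(floor(min(epi[, 2])), ceiling(max(epi[, 2])))))
  rows <- r_rng[1]:r_rng[2]
  cols <- c_rng[1]:c_rng[2]
  grid <- expand.grid(row = rows, col = cols)
  in_epi <- pracma::inpolygon(grid$col, grid$row, epi[, 2], epi[, 1])
  in_endo <- pracma::inpolygon(grid$col, grid$row, endo[, 2], endo[, 1])
  keep <- in_epi & !in_endo
  assert_that(any(keep), "contours produce an empty myocardium ring")
  mask <- matrix(FALSE, shape[1], shape[2])
  mask[cbind(grid$row[keep] + 1L, grid$col[keep] + 1L)] <- TRUE
  mask
}

#' AHA segment IDs used per slice level
#' @param slice_level One of `"apical"`, `"mid"`, `"basal"`.
#' @return Integer vector of segment IDs (basal 1-6, mid 7-12, apical 13-16).
#' @export
aha_segment_ids <- function(slice_level = c("mid", "apical", "basal")) {
  switch(match.arg(slice_level), basal = 1:6, mid = 7:12, apical = 13:16)
}

#' Standard myocardial region groups
#'
#' Segment-ID sets for the regions analysed in segmental iron studies: the
#' septum (basal anteroseptal/inferoseptal, mid anteroseptal/inferoseptal,
#' apical septal), the artifact-prone inferolateral wall (mid and basal
#' inferolateral), and the global myocardium.
#'
#' @return Named list `septal`, `inferolateral`, `global`.
#' @export
aha_region_groups <- function() {
  list(septal = c(2L, 3L, 8L, 9L, 14L),
       inferolateral = c(5L, 11L),
       global = 1:16)
}

#' Assign AHA 16-segment labels within the myocardium mask
#'
#' Divides the ring into equal angular sectors measured from the ray
#' running from the myocardial centroid to the anterior RV-insertion
#' landmark, proceeding counterclockwise in the anatomical (y-up) frame:
#' 6 sectors of 60 deg on basal and mid slices, 4 sectors of 90 deg on
#' apical slices. Numbering starts at the anterior segment adjacent to the
#' insertion (basal 1-6, mid 7-12, apical 13-16).
#'
#' @param mask Logical myocardium matrix.
#' @param rv_insertion 0-based (row, col) of the anterior RV insertion.
#' @param slice_level One of `"apical"`, `"mid"`, `"basal"`.
#' @param centroid Optional 0-based (row, col) centre; defaults to the mean
#'   of the mask pixel coordinates.
#' @return An object of class `segment_label_map`: integer matrix (0 outside
#'   the mask) with attributes `slice_level` and `segment_ids`.
#' @export
assign_aha_segments <- function(mask, rv_insertion,
                                slice_level = c("mid", "apical", "basal"),
                                centroid = NULL) {
  slice_level <- match.arg(slice_level)
  assert_that(is.matrix(mask) && any(mask), "mask must be a non-empty matrix")
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(centroid)) {
    centroid <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
  }
  dr <- rv_insertion[1] - centroid[1]
  dc <- rv_insertion[2] - centroid[2]
  assert_that(abs(dr) + abs(dc) > 1e-9,
              "rv_insertion landmark coincides with the centroid")
  # anatomical angle: y up, so image row increasing downwards is negated
  theta_ref <- atan2(-dr, dc)
  theta <- atan2(-(idx[, 1] - 1 - centroid[1]), idx[, 2] - 1 - centroid[2])
  offset <- (theta - theta_ref) %% (2 * pi)
  ids <- aha_segment_ids(slice_level)
  width <- 2 * pi / length(ids)
  sector <- pmin(length(ids) - 1L, as.integer(floor(offset / width)))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[idx] <- ids[sector + 1L]
  structure(labels, slice_level = slice_level, segment_ids = ids,
            class = c("segment_label_map", "matrix", "array"))
}

#' @export
print.segment_label_map <- function(x, ...) {
  cat(sprintf("<segment_label_map> %s slice, segments %s, %d myocardial pixels\n",
              attr(x, "slice_level"),
              paste(range(attr(x, "segment_ids")), collapse = "-"),
              sum(x > 0)))
  invisible(x)
}

#' Tidy a segment label map
#' @param x A `segment_label_map`.
#' @param ... Unused.
#' @return Tibble with 0-based `row`, `col` and `segment_id` per myocardial
#'   pixel.
#' @export
tidy.segment_label_map <- function(x, ...) {
  idx <- which(unclass(x) > 0, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                 segment_id = x[idx],
                 slice_level = attr(x, "slice_level"))
}

#' Total segment count of a study
#'
#' Counts the distinct (slice, segment) pairs across a study's label maps:
#' 4 per apical slice and 6 per mid or basal slice when every segment is
#' populated.
#'
#' @param label_maps List of `segment_label_map` objects.
#' @return Integer total.
#' @export
study_segment_count <- function(label_maps) {
  if (length(label_maps) == 0L) return(0L)
  sum(vapply(label_maps,
             function(m) length(unique(m[unclass(m) > 0])), integer(1)))
}
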