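#' Echo-time scheme of a multi-gradient-echo train
#'
#' A validated set of echo times (TE, in milliseconds) for one MGE
#' acquisition. Bright-blood cardiac MGE protocols at 1.5 T typically use
#' eight echoes, e.g. 2.59--18.20 ms at 2.23 ms increments; at least four
#' echoes are required because the truncation rules never fit fewer than
#' four points.
#'
#' @param te_ms Numeric vector of echo times in ms; strictly increasing,
#'   all positive, length >= 4.
#' @param scanner_label Free-text label for the scheme (scanner or protocol).
#' @return An object of class `te_scheme`: a numeric vector of TEs with a
#'   `scanner_label` attribute.
#' @examples
#' te_scheme(2.59 + 2.23 * 0:7, "Avanto")
#' @export
te_scheme <- function(te_ms, scanner_label = "") {
  te_ms <- as.numeric(te_ms)
  assert_that(length(te_ms) >= 4L, "a TE scheme needs at least 4 echoes")
  assert_that(all(is.finite(te_ms)) && all(te_ms > 0),
              "echo times must be positive and finite")
  assert_that(all(diff(te_ms) > 0), "echo times must be strictly increasing")
  structure(te_ms, scanner_label = as.character(scanner_label)[1],
            class = "te_scheme")
}

#' @export
print.te_scheme <- function(x, ...) {
  cat(sprintf("<te_scheme> %d echoes, %.2f-%.2f ms  [%s]\n",
              length(x), x[1], x[length(x)], attr(x, "scanner_label")))
  invisible(x)
}

#' Multi-echo magnitude image series for one short-axis slice
#'
#' Bundles the echo-indexed stack of 2-D magnitude images with its TE scheme,
#' pixel spacing and slice level. Intensities must be non-negative (magnitude
#' reconstruction) and finite.
#'
#' @param images 3-D numeric array `[rows, cols, echoes]` of magnitude images.
#' @param te A [te_scheme()] whose length matches `dim(images)[3]`.
#' @param pixel_spacing_mm Length-2 positive numeric, row/col spacing in mm.
#' @param slice_level One of `"apical"`, `"mid"`, `"basal"`.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(images, te,
                        pixel_spacing_mm = c(1.56, 1.56),
                        slice_level = c("mid", "apical", "basal")) {
  slice_level <- match.arg(slice_level)
  if (is.list(images)) images <- simplify2array(images)
  assert_that(is.array(images) && length(dim(images)) == 3L,
              "images must be a rows x cols x echoes array")
  if (!inherits(te, "te_scheme")) te <- te_scheme(te)
  assert_that(dim(images)[3] == length(te),
              sprintf("number of images (%d) must equal number of TEs (%d)",
                      dim(images)[3], length(te)))
  assert_that(all(is.finite(images)) && all(images >= 0),
              "magnitude intensities must be finite and >= 0")
  assert_that(length(pixel_spacing_mm) == 2L && all(pixel_spacing_mm > 0),
              "pixel_spacing_mm must be two positive numbers")
  structure(list(images = images, te = te,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_level = slice_level),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<echo_series> %dx%d px, %d echoes (%.2f-%.2f ms), %s slice\n",
              d[1], d[2], d[3], x$te[1], x$te[length(x$te)], x$slice_level))
  invisible(x)
}

#' Background (air) region of interest
#'
#' Pixel coordinates of an air region used to estimate the per-echo noise
#' level sigma_b for the SNR truncation rule. Coordinates are 0-based
#' `(row, col)` pairs, the convention used throughout the package.
#'
#' @param pixels Two-column matrix or data frame of 0-based (row, col)
#'   indices; at least 25 pixels.
#' @return An object of class `background_roi` (integer matrix).
#' @export
background_roi <- function(pixels) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  assert_that(ncol(pixels) == 2L, "pixels must have two columns (row, col)")
  pixels <- unique(pixels)
  assert_that(nrow(pixels) >= 25L,
              "background ROI needs at least 25 distinct pixels")
  assert_that(all(pixels >= 0L), "pixel indices are 0-based and non-negative")
  colnames(pixels) <- c("row", "col")
  structure(pixels, class = c("background_roi", class(pixels)))
}

#' Epicardial/endocardial contour pair with RV-insertion landmark
#'
#' Closed polygons delineating the left-ventricular myocardium on a
#' short-axis slice, plus the anterior right-ventricular insertion point that
#' anchors the angular origin of the AHA parcellation. All coordinates are
#' 0-based `(row, col)` in the image frame.
#'
#' @param epicardial,endocardial Two-column matrices of ordered polygon
#'   vertices (row, col); the closing edge is implicit.
#' @param rv_insertion Length-2 numeric, the (row, col) landmark.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(epicardial, endocardial, rv_insertion) {
  epicardial <- as_vertex_matrix(epicardial, "epicardial")
  endocardial <- as_vertex_matrix(endocardial, "endocardial")
  assert_that(length(rv_insertion) == 2L && all(is.finite(rv_insertion)),
              "rv_insertion must be a finite (row, col) pair")
  # endocardial strictly inside epicardial: every endo vertex inside epi
  inside <- pracma::inpolygon(endocardial[, 2], endocardial[, 1],
                              epicardial[, 2], epicardial[, 1],
                              boundary = FALSE)
  assert_that(all(inside),
              "endocardial contour must lie strictly inside the epicardial contour")
  structure(list(epicardial = epicardial, endocardial = endocardial,
                 rv_insertion = as.numeric(rv_insertion)),
            class = "contour_set")
}

as_vertex_matrix <- function(v, what) {
  v <- as.matrix(v)
  assert_that(ncol(v) == 2L && nrow(v) >= 3L && all(is.finite(v)),
              sprintf("%s contour must be a matrix of >= 3 finite (row, col) vertices", what))
  colnames(v) <- c("row", "col")
  v
}

#' Load a multi-echo series from NIfTI files
#'
#' Accepts either a single NIfTI file holding the echo train (echoes as the
#' 3rd or 4th dimension) or one NIfTI file per echo. Echo times come from a
#' JSON sidecar (`{"te_ms": [...]}`, same stem as the single file with
#' extension `.json`) or from `te_override`; NIfTI itself carries no TE
#' field. Echoes are returned sorted by ascending TE, images permuted
#' consistently.
#'
#' @param paths Character vector of NIfTI file paths (one file, or one per
#'   echo).
#' @param te_override Optional numeric vector of echo times in ms,
#'   overriding/replacing the sidecar.
#' @param pixel_spacing_mm,slice_level Passed to [echo_series()].
#' @return An [echo_series()].
#' @export
load_echo_series <- function(paths, te_override = NULL,
                             pixel_spacing_mm = c(1.56, 1.56),
                             slice_level = "mid") {
  assert_that(length(paths) >= 1L && all(file.exists(paths)),
              "all input files must exist", class = "t2star_format_error")
  vols <- lapply(paths, function(p) {
    v <- as.array(RNifti::readNifti(p))
    # drop trailing singleton dims (NIfTI writers often pad to 4-D)
    d <- dim(v)
    while (length(d) > 2L && d[length(d)] == 1L) {
      d <- d[-length(d)]
      dim(v) <- d
    }
    v
  })
  if (length(vols) == 1L) {
    img <- vols[[1]]
    assert_that(length(dim(img)) %in% c(3L, 4L),
                "single-file input must be a 3-D or 4-D NIfTI volume",
                class = "t2star_format_error")
    if (length(dim(img)) == 4L) {
      assert_that(dim(img)[3] == 1L,
                  "4-D input must have a singleton 3rd dimension (one slice)",
                  class = "t2star_format_error")
      img <- img[, , 1, , drop = TRUE]
    }
  } else {
    shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), "")
    assert_that(length(unique(shapes)) == 1L,
                "per-echo images must all share the same shape",
                class = "t2star_format_error")
    assert_that(all(vapply(vols, function(v) length(dim(v)) == 2L, TRUE)),
                "per-echo files must be 2-D images",
                class = "t2star_format_error")
    img <- simplify2array(vols)
  }

  te <- te_override
  if (is.null(te)) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", paths[1]), ".json")
    assert_that(file.exists(sidecar),
                "echo times missing: supply te_override or a JSON sidecar with te_ms")
    te <- jsonlite::fromJSON(sidecar)$te_ms
    assert_that(!is.null(te), "sidecar JSON must contain a te_ms field")
  }
  assert_that(length(te) == dim(img)[3],
              sprintf("got %d echo times for %d images", length(te), dim(img)[3]))
  ord <- order(te)
  echo_series(img[, , ord, drop = FALSE], te_scheme(te[ord]),
              pixel_spacing_mm = pixel_spacing_mm, slice_level = slice_level)
}

#' Write a multi-echo series to NIfTI + TE sidecar
#'
#' Writes the echo stack as one NIfTI-1 file (double precision, so the
#' round trip is bit-exact) and the TE scheme as a JSON sidecar.
#'
#' @param series An [echo_series()].
#' @param stem Output path stem; `<stem>.nii.gz` and `<stem>.json` are
#'   written.
#' @return Invisibly, the two paths written.
#' @export
write_echo_series <- function(series, stem) {
  stopifnot(inherits(series, "echo_series"))
  nii_path <- paste0(stem, ".nii.gz")
  RNifti::writeNifti(series$images, nii_path, datatype = "double")
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(list(te_ms = as.numeric(series$te),
                            scanner_label = attr(series$te, "scanner_label"),
                            pixel_spacing_mm = series$pixel_spacing_mm,
                            slice_level = series$slice_level),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(nii_path, json_path))
}

#' Read contours from JSON or CSV
#'
#' JSON layout: `{"epicardial": [[row,col],...], "endocardial": [...],
#' "rv_insertion": [row,col]}`. CSV layout: columns `polygon` (one of
#' `epicardial`, `endocardial`, `rv_insertion`), `row`, `col`.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return A [contour_set()].
#' @export
read_contours <- function(path) {
  assert_that(file.exists(path), "contour file not found",
              class = "t2star_format_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    contour_set(x$epicardial, x$endocardial, unlist(x$rv_insertion))
  } else {
    x <- readr::read_csv(path, show_col_types = FALSE)
    assert_that(all(c("polygon", "row", "col") %in% names(x)),
                "contour CSV needs columns polygon, row, col",
                class = "t2star_format_error")
    pick <- function(id) as.matrix(x[x$polygon == id, c("row", "col")])
    rv <- pick("rv_insertion")
    contour_set(pick("epicardial"), pick("endocardial"), rv[1, ])
  }
}

#' Write contours as JSON
#' @param contours A [contour_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  jsonlite::write_json(list(epicardial = unclass(contours$epicardial),
                            endocardial = unclass(contours$endocardial),
                            rv_insertion = contours$rv_insertion),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Per-echo background noise level
#'
#' Standard deviation of the air-background ROI on each echo image, the
#' sigma_b entering the pixel SNR definition `SNR = NF * SI / sigma_b`.
#' Computed per echo (not pooled across the train) with the sample (n-1)
#' standard deviation.
#'
#' @param series An [echo_series()].
#' @param roi A [background_roi()].
#' @return A tibble with columns `echo`, `te_ms`, `sigma_b`.
#' @export
background_sigma <- function(series, roi) {
  stopifnot(inherits(series, "echo_series"))
  if (!inherits(roi, "background_roi")) roi <- background_roi(roi)
  d <- dim(series$images)
  assert_that(all(roi[, "row"] < d[1]) && all(roi[, "col"] < d[2]),
              "background ROI extends outside the image bounds")
  idx <- cbind(roi[, "row"] + 1L, roi[, "col"] + 1L)
  sig <- vapply(seq_len(d[3]), function(e) sd(series$images[, , e][idx]),
                numeric(1))
  tibble::tibble(echo = seq_len(d[3]), te_ms = as.numeric(series$te),
                 sigma_b = sig)
}

#' Write a 2-D map as NIfTI-1
#' @param map Numeric matrix (NA outside the region of support is fine).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixel_spacing_mm Length-2 voxel spacing recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_map_nifti <- function(map, path, pixel_spacing_mm = c(1.56, 1.56)) {
  img <- RNifti::asNifti(map, pixdim = c(pixel_spacing_mm, 1))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
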