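test_that("te_scheme enforces its invariants", {
  expect_s3_class(te_scheme(c(2.59, 4.82, 7.05, 9.28)), "te_scheme")
  expect_error(te_scheme(c(2, 4, 6)), "at least 4")
  expect_error(te_scheme(c(2, 4, 4, 6)), "increasing")
  expect_error(te_scheme(c(-1, 2, 3, 4)), "positive")
})

test_that("echo_series validates image/TE consistency and intensities", {
  img <- array(1, dim = c(8, 8, 8))
  expect_s3_class(echo_series(img, avanto), "echo_series")
  expect_error(echo_series(array(1, dim = c(8, 8, 7)), avanto), "equal")
  neg <- img; neg[1, 1, 1] <- -2
  expect_error(echo_series(neg, avanto), "0")
})

test_that("series round-trips through NIfTI + sidecar bit-exactly", {
  ph <- generate_phantom(phantom_spec(sigma = 2, seed = 11))
  stem <- file.path(withr::local_tempdir(), "mid")
  write_echo_series(ph$series, stem)
  back <- load_echo_series(paste0(stem, ".nii.gz"))
  expect_identical(dim(back$images), dim(ph$series$images))
  expect_equal(as.numeric(back$te), as.numeric(ph$series$te),
               tolerance = 1e-12)
  expect_identical(order(back$te), seq_along(back$te))
  expect_equal(back$images, ph$series$images, tolerance = 0)
})

test_that("load_echo_series sorts echoes by TE and rejects mismatches", {
  dir <- withr::local_tempdir()
  te_shuf <- c(4.82, 2.59, 9.28, 7.05, 11.51, 13.74, 15.97, 18.20)
  paths <- vapply(seq_along(te_shuf), function(i) {
    p <- file.path(dir, sprintf("echo%d.nii.gz", i))
    RNifti::writeNifti(matrix(te_shuf[i], 4, 4), p, datatype = "double")
    p
  }, "")
  ser <- load_echo_series(paths, te_override = te_shuf)
  expect_equal(as.numeric(ser$te), sort(te_shuf))
  # image stack permuted consistently with the TE sort
  expect_equal(ser$images[1, 1, ], sort(te_shuf))
  expect_error(load_echo_series(paths, te_override = te_shuf[-1]), "echo")
  bad <- c(paths[1:7],
           RNifti::writeNifti(matrix(0, 5, 5), file.path(dir, "odd.nii.gz"),
                              datatype = "double"))
  expect_error(load_echo_series(bad, te_override = te_shuf), "shape")
})

test_that("background_sigma computes per-echo sample sd over the ROI", {
  img <- array(0, dim = c(10, 10, 4))
  # one echo with values {3,5,7} in part of the ROI, rest structured
  roi_px <- as.matrix(expand.grid(row = 0:4, col = 0:4))
  img[1:3, 1, 2] <- c(3, 5, 7)
  ser <- echo_series(img, te_scheme(c(2, 4, 6, 8)))
  sig <- background_sigma(ser, background_roi(roi_px))
  expect_equal(sig$sigma_b[1], 0)                      # all-zero background
  expect_equal(sig$sigma_b[2], sd(c(3, 5, 7, rep(0, 22))))
  expect_equal(sd(c(3, 5, 7)), 2.0)                    # the hand value
  expect_equal(nrow(sig), 4L)

  # permutation invariance in ROI pixel order
  perm <- roi_px[sample(nrow(roi_px)), ]
  expect_equal(background_sigma(ser, background_roi(perm))$sigma_b,
               sig$sigma_b)

  out <- background_roi(cbind(rep(0:4, 5), rep(20:24, each = 5)))
  expect_error(background_sigma(ser, out), "bounds")
})

test_that("Rayleigh background sd matches the closed form within 5%", {
  sigma <- 5
  n <- 1e4
  img <- array(0, dim = c(100, 100, 4))
  set.seed(42)
  for (e in 1:4) {
    img[, , e] <- sqrt(rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2)
  }
  ser <- echo_series(img, te_scheme(c(2, 4, 6, 8)))
  roi <- background_roi(as.matrix(expand.grid(row = 0:99, col = 0:99)))
  sig <- background_sigma(ser, roi)
  expected <- sigma * sqrt(2 - pi / 2)
  expect_true(all(abs(sig$sigma_b - expected) / expected < 0.05))
})

test_that("contour_set rejects an endocardium not inside the epicardium", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- function(r, c0 = 20) cbind(c0 + r * sin(th), c0 + r * cos(th))
  expect_s3_class(contour_set(circ(10), circ(5), c(5, 20)), "contour_set")
  expect_error(contour_set(circ(10), circ(10), c(5, 20)), "inside")
  expect_error(contour_set(circ(5), circ(10), c(5, 20)), "inside")
})

test_that("contour files round-trip through JSON and read from CSV", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  cs <- contour_set(cbind(20 + 10 * sin(th), 20 + 10 * cos(th)),
                    cbind(20 + 5 * sin(th), 20 + 5 * cos(th)),
                    c(8, 20))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "contours.json")
  write_contours(cs, jp)
  back <- read_contours(jp)
  expect_equal(back$epicardial, cs$epicardial, tolerance = 1e-12)
  expect_equal(back$rv_insertion, cs$rv_insertion)

  cp <- file.path(dir, "contours.csv")
  readr::write_csv(tibble::tibble(
    polygon = c(rep("epicardial", 24), rep("endocardial", 24), "rv_insertion"),
    row = c(cs$epicardial[, 1], cs$endocardial[, 1], 8),
    col = c(cs$epicardial[, 2], cs$endocardial[, 2], 20)), cp)
  back2 <- read_contours(cp)
  expect_equal(back2$endocardial, cs$endocardial, tolerance = 1e-12)
})
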