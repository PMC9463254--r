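ring_contours <- function(r_epi = 30, r_endo = 20, c0 = c(63.5, 63.5),
                          n = 128, rv = NULL) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  if (is.null(rv)) rv <- c(c0[1] - (r_epi + 2), c0[2])
  contour_set(cbind(c0[1] - r_epi * sin(th), c0[2] + r_epi * cos(th)),
              cbind(c0[1] - r_endo * sin(th), c0[2] + r_endo * cos(th)),
              rv)
}

test_that("rasterized ring area matches the annulus area within 3%", {
  mask <- rasterize_myocardium(ring_contours(), c(128, 128))
  expect_lt(abs(sum(mask) - pi * (30^2 - 20^2)) / (pi * (30^2 - 20^2)), 0.03)
})

test_that("translating both contours translates the mask identically", {
  cs1 <- ring_contours(c0 = c(50, 50))
  cs2 <- ring_contours(c0 = c(57, 61))
  m1 <- rasterize_myocardium(cs1, c(128, 128))
  m2 <- rasterize_myocardium(cs2, c(128, 128))
  shifted <- matrix(FALSE, 128, 128)
  idx <- which(m1, arr.ind = TRUE)
  shifted[cbind(idx[, 1] + 7L, idx[, 2] + 11L)] <- TRUE
  expect_identical(m2, shifted)
})

test_that("mid slices get 6 segments 7..12 and apical slices 4 segments 13..16", {
  cs <- ring_contours()
  mask <- rasterize_myocardium(cs, c(128, 128))
  mid <- assign_aha_segments(mask, cs$rv_insertion, "mid")
  expect_setequal(unique(mid[mid > 0]), 7:12)
  api <- assign_aha_segments(mask, cs$rv_insertion, "apical")
  expect_setequal(unique(api[api > 0]), 13:16)
  bas <- assign_aha_segments(mask, cs$rv_insertion, "basal")
  expect_setequal(unique(bas[bas > 0]), 1:6)
  # labels partition the mask
  expect_identical(unclass(mid) > 0, mask)
})

test_that("sector pixel counts on an ideal annulus are balanced within 2%", {
  cs <- ring_contours()
  mask <- rasterize_myocardium(cs, c(128, 128))
  mid <- assign_aha_segments(mask, cs$rv_insertion, "mid")
  counts <- table(mid[mid > 0])
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.04)
  expect_true(all(abs(counts - mean(counts)) / mean(counts) < 0.02))
})

test_that("rotating the landmark by 60 degrees permutes mid labels cyclically", {
  c0 <- c(63.5, 63.5)
  cs <- ring_contours(c0 = c0)
  mask <- rasterize_myocardium(cs, c(128, 128))
  base <- assign_aha_segments(mask, cs$rv_insertion, "mid", centroid = c0)
  rv60 <- c(c0[1] - 32 * sin(pi / 2 + pi / 3), c0[2] + 32 * cos(pi / 2 + pi / 3))
  rot <- assign_aha_segments(mask, rv60, "mid", centroid = c0)
  # counterclockwise landmark shift: each pixel's sector index drops by one
  expected <- ifelse(unclass(base) > 0, (unclass(base) - 7 + 5) %% 6 + 7, 0)
  expect_equal(unclass(rot), expected, ignore_attr = TRUE)
  expect_equal(sort(as.vector(table(rot[rot > 0]))),
               sort(as.vector(table(base[base > 0]))))
})

test_that("landmark at the centroid is rejected", {
  cs <- ring_contours(c0 = c(40, 40))
  mask <- rasterize_myocardium(cs, c(100, 100))
  expect_error(assign_aha_segments(mask, c(40, 40), "mid",
                                   centroid = c(40, 40)), "coincides")
})

test_that("study segment counts follow the 4/6/6 rule", {
  cs <- ring_contours(r_epi = 14, r_endo = 9, c0 = c(20, 20), rv = c(4, 20))
  mask <- rasterize_myocardium(cs, c(40, 40))
  maps <- lapply(c("apical", "mid", "basal"), function(lv) {
    assign_aha_segments(mask, cs$rv_insertion, lv)
  })
  expect_identical(study_segment_count(maps), 16L)
  expect_identical(study_segment_count(list()), 0L)

  # the full study design: 22 apical + 37 mid + 22 basal slices
  design <- c(rep(list(maps[[1]]), 22), rep(list(maps[[2]]), 37),
              rep(list(maps[[3]]), 22))
  expect_identical(study_segment_count(design), 442L)
  expect_identical(22L * 4L + 37L * 6L + 22L * 6L, 442L)
})
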