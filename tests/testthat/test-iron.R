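test_that("segmental median and unscaled MAD follow the definitions", {
  s <- summarize_segment(c(10, 20, 30))
  expect_equal(s$median_t2star_ms, 20)
  expect_equal(s$mad_ms, 10)
  one <- summarize_segment(17.3)
  expect_equal(one$median_t2star_ms, 17.3)
  expect_equal(one$mad_ms, 0)
  expect_error(summarize_segment(numeric(0)), "no finite")

  # large-sample median consistency against the lognormal closed form
  set.seed(9)
  draws <- rlnorm(1e4, meanlog = 3, sdlog = 0.4)
  est <- summarize_segment(draws)
  expect_lt(abs(est$median_t2star_ms - exp(3)) / exp(3), 0.02)
})

test_that("iron classes follow the 10/20 ms thresholds with a closed lower bound", {
  expect_equal(as.character(classify_iron(c(25, 20.01, 20, 10.5, 10, 9.99, 3))),
               c("normal", "normal", "moderate", "moderate", "moderate",
                 "severe", "severe"))
  # the open-lower-bound variant sends exactly 10 ms to severe
  expect_equal(as.character(classify_iron(10, moderate_lower_closed = FALSE)),
               "severe")
  expect_error(classify_iron(-1), "positive")
})

test_that("segment summaries classify every segment and conserve counts", {
  spec <- phantom_spec(t2star_by_segment = setNames(
    c(30, 8, 15, 30, 30, 30), 7:12), sigma = 0)
  ph <- generate_phantom(spec)
  fm <- fit_map(ph$series, ph$truth$mask, "classic")
  s <- segment_summary(fm, ph$truth$labels)
  expect_equal(s$segment_id, 7:12)
  expect_equal(as.character(s$iron_class[s$segment_id == 8]), "severe")
  expect_equal(as.character(s$iron_class[s$segment_id == 9]), "moderate")
  counts <- table(s$iron_class)
  expect_equal(sum(counts), nrow(s))
  expect_equal(unname(counts[c("normal", "moderate", "severe")]),
               c(4L, 1L, 1L), ignore_attr = TRUE)
})

test_that("TE-usage breakdown percentages sum to 100 per class and method", {
  spec <- phantom_spec(sigma = 0)
  ph <- generate_phantom(spec)
  fits <- lapply(c("classic", "snr_trunc", "r2_trunc"), function(m) {
    fit_map(ph$series, ph$truth$mask, m, background = ph$background)
  })
  px <- pixel_fits_with_class(fits, ph$truth$labels)
  tbl <- te_usage_breakdown(px)
  sums <- tapply(tbl$pct_of_class, paste(tbl$iron_class, tbl$method), sum)
  expect_true(all(abs(sums - 100) < 0.1))
  # noiseless phantom: no truncation anywhere, 100% in the 8-TE column
  expect_true(all(tbl$n_te_used == 8L))

  # strong plateau drives the R^2 rule to the 4-point floor on every pixel
  spec2 <- phantom_spec(t2star_by_segment = 5, plateau = 25, sigma = 0)
  ph2 <- generate_phantom(spec2)
  fits2 <- lapply(c("classic", "r2_trunc"), function(m) {
    fit_map(ph2$series, ph2$truth$mask, m, background = ph2$background)
  })
  tbl2 <- te_usage_breakdown(pixel_fits_with_class(fits2, ph2$truth$labels))
  r2_rows <- tbl2[tbl2$method == "r2_trunc", ]
  expect_equal(r2_rows$n_te_used, 4L)
  expect_equal(r2_rows$pct_of_class, 100)
})

test_that("segment classification from fitted medians recovers the truth", {
  # segments with true T2* at least 1 ms from a class boundary, pixels at
  # first-echo SNR 40; >= 95% of >= 200 segments must classify correctly
  set.seed(31)
  n_seg <- 200
  px_per_seg <- 40
  true_t2 <- runif(n_seg, 3, 50)
  shift <- function(v) {
    near <- abs(v - 10) < 1 | abs(v - 20) < 1
    v[near] <- v[near] + 2.5
    v
  }
  true_t2 <- shift(true_t2)
  hits <- vapply(true_t2, function(t2) {
    sig <- sigma_for_first_echo_snr(40, t2)
    s <- t2star:::simulate_decays(px_per_seg, t2, avanto, 100, sig)
    est <- vapply(seq_len(px_per_seg), function(i) {
      fit_monoexp(s[i, ], avanto)$t2star_ms
    }, numeric(1))
    classify_iron(median(est)) == classify_iron(t2)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
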