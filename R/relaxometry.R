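#' Coefficient of determination of a fit
#'
#' `R^2 = 1 - SS_res / SS_tot` over the retained echoes, the goodness-of-fit
#' measure driving the R-squared truncation rule.
#'
#' @param signal Per-echo signal intensities.
#' @param fitted_curve Model values at the same echoes.
#' @param retained Indices of the retained echoes (default: all).
#' @return A single numeric; `NA` (flagged degenerate) when the retained
#'   signal has zero variance, so that SS_tot = 0.
#' @export
goodness_of_fit <- function(signal, fitted_curve,
                            retained = seq_along(signal)) {
  assert_that(length(retained) >= 2L, "R^2 needs at least 2 retained points")
  y <- signal[retained]
  f <- fitted_curve[retained]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - f)^2) / ss_tot
}

# Profile residual sum of squares for y ~ K exp(-TE/T2*): the model is
# separable, so for fixed T2* the optimal amplitude is closed-form,
# K(T2*) = max(0, <y,w>/<w,w>) with w = exp(-TE/T2*). Returns rss over a
# vector of candidate T2* values.
monoexp_profile_rss <- function(y, te, t2_values) {
  w <- exp(-outer(t2_values, te, function(t2, te) te / t2))
  wy <- as.numeric(w %*% y)
  sw2 <- rowSums(w * w)
  k <- pmax(0, wy / sw2)
  sum(y^2) - 2 * k * wy + k^2 * sw2
}

T2STAR_MAX_MS <- 500
T2_GRID <- exp(seq(log(0.05), log(T2STAR_MAX_MS), length.out = 300))

#' Monoexponential T2* fit of one pixel's echo train
#'
#' Nonlinear least squares of `y = K exp(-TE/T2*)` with `K >= 0` and
#' `T2* in (0, 500]` ms on a retained prefix of the echo train. The model is
#' separable in K, so the fit is an exact bounded 1-D minimisation over T2*
#' (coarse log-spaced scan followed by local refinement); it is deterministic
#' and needs no starting values.
#'
#' @param signal Per-echo magnitude intensities (finite, non-negative).
#' @param te A [te_scheme()] (or numeric TE vector, ms) aligned with
#'   `signal`.
#' @param retained Integer prefix of echo indices to fit on; at least 4.
#' @param method Method tag recorded in the result.
#' @return A one-row tibble (class `pixel_fit`) with columns `K`,
#'   `t2star_ms`, `r2`, `n_te_used`, `method`, `converged`, `capped`.
#'   An all-zero signal yields a non-converged row (NA estimates) that
#'   downstream steps exclude.
#' @examples
#' te <- te_scheme(2.59 + 2.23 * 0:7)
#' fit_monoexp(100 * exp(-te / 20), te)
#' @export
fit_monoexp <- function(signal, te, retained = seq_along(signal),
                        method = "classic") {
  te <- as.numeric(te)
  assert_that(length(signal) == length(te), "signal and te lengths differ")
  assert_that(all(is.finite(signal)) && all(signal >= 0),
              "signal must be finite and non-negative")
  retained <- as.integer(retained)
  assert_that(identical(retained, seq_len(length(retained))),
              "retained must be a prefix 1..n of the echo train")
  assert_that(length(retained) >= 4L, "at least 4 retained echoes required")

  y <- signal[retained]
  t <- te[retained]
  if (sd(y) == 0) {
    return(pixel_fit_row(NA_real_, NA_real_, NA_real_, length(retained),
                         method, FALSE, FALSE))
  }

  grid <- T2_GRID
  rss <- monoexp_profile_rss(y, t, grid)
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(t2) monoexp_profile_rss(y, t, t2),
                  interval = c(lo, hi), tol = 1e-10)
  t2_hat <- opt$minimum
  if (rss[i] < opt$objective) t2_hat <- grid[i]

  w <- exp(-t / t2_hat)
  k_hat <- max(0, sum(y * w) / sum(w * w))
  r2 <- goodness_of_fit(y, k_hat * w)
  pixel_fit_row(k_hat, t2_hat, r2, length(retained), method,
                k_hat > 0 && !is.na(r2),
                t2_hat >= T2STAR_MAX_MS * (1 - 1e-9))
}

# fast one-row tibble constructor for the per-pixel hot path
pixel_fit_row <- function(K, t2star_ms, r2, n_te_used, method, converged,
                          capped) {
  tibble::new_tibble(list(K = K, t2star_ms = t2star_ms, r2 = r2,
                          n_te_used = as.integer(n_te_used), method = method,
                          converged = converged, capped = capped),
                     nrow = 1L, class = "pixel_fit")
}

#' Per-echo pixel SNR profile
#'
#' `SNR = NF * SI / sigma_b` per echo, where NF is the noise factor
#' correcting for the noise-level underestimation inherent in
#' sum-of-squares magnitude reconstruction (0.71 for up to 32 coil
#' elements), SI the pixel signal and sigma_b the air-background standard
#' deviation of the same echo.
#'
#' @param signal Per-echo signal intensities for one pixel.
#' @param sigma_b Per-echo background standard deviations (numeric vector
#'   or the tibble from [background_sigma()]); all > 0.
#' @param noise_factor Dimensionless NF in (0, 1].
#' @return An object of class `snr_profile`: list with `snr_values`,
#'   `noise_factor`, `sigma_b`.
#' @export
snr_profile <- function(signal, sigma_b, noise_factor = 0.71) {
  if (is.data.frame(sigma_b)) sigma_b <- sigma_b$sigma_b
  assert_that(length(sigma_b) == length(signal),
              "sigma_b and signal lengths differ")
  assert_that(all(sigma_b > 0),
              "sigma_b must be positive for every echo (degenerate background ROI)")
  assert_that(is_scalar_number(noise_factor) &&
                noise_factor > 0 && noise_factor <= 1,
              "noise_factor must lie in (0, 1]")
  structure(list(snr_values = noise_factor * signal / sigma_b,
                 noise_factor = noise_factor,
                 sigma_b = as.numeric(sigma_b)),
            class = "snr_profile")
}

#' SNR truncation of the echo train
#'
#' Truncates the echo train where the pixel signal reaches the noise
#' level: every echo from the first sub-threshold echo (default SNR < 2.5)
#' onward is excluded, so the retained set is always a contiguous prefix
#' ending before the earliest removable echo that fails the threshold.
#' Echoes with TE below the floor (10 ms) are never removed, and at least
#' `min_points` echoes are always retained, whichever protection keeps
#' more.
#'
#' @param snr An [snr_profile()] or numeric vector of per-echo SNR.
#' @param te A [te_scheme()] (or numeric TEs, ms) aligned with `snr`.
#' @param threshold SNR cutoff below which a tail echo is dropped.
#' @param te_floor_ms Echoes earlier than this TE are protected.
#' @param min_points Minimum number of retained echoes.
#' @return Integer vector `1:k`, the retained prefix.
#' @export
truncate_by_snr <- function(snr, te, threshold = 2.5, te_floor_ms = 10,
                            min_points = 4) {
  if (inherits(snr, "snr_profile")) snr <- snr$snr_values
  te <- as.numeric(te)
  assert_that(length(snr) == length(te), "snr and te lengths differ")
  protected_n <- max(min_points, sum(te < te_floor_ms))
  low <- which(snr < threshold)
  low <- low[low > protected_n]
  k <- if (length(low)) max(protected_n, low[1] - 1L) else length(te)
  seq_len(k)
}

#' R-squared truncation of the echo train
#'
#' Fits the monoexponential on the full train, then repeatedly drops the
#' longest remaining TE and refits while the fit's R^2 stays below the
#' threshold (default 0.995) and more than `min_points` echoes remain. The
#' returned fit therefore satisfies `r2 >= threshold` or uses exactly
#' `min_points` early echoes.
#'
#' @inheritParams fit_monoexp
#' @param threshold R^2 value that stops further truncation. The rule
#'   accepts a fit at `r2 >= threshold`.
#' @param min_points Minimum number of retained echoes.
#' @return A one-row `pixel_fit` tibble with `method = "r2_trunc"`.
#' @export
truncate_by_r2 <- function(signal, te, threshold = 0.995, min_points = 4) {
  n <- length(signal)
  assert_that(n >= min_points, "fewer echoes than min_points")
  fit <- fit_monoexp(signal, te, seq_len(n), method = "r2_trunc")
  while (!is.na(fit$r2) && fit$r2 < threshold && n > min_points) {
    n <- n - 1L
    fit <- fit_monoexp(signal, te, seq_len(n), method = "r2_trunc")
  }
  fit
}

# one pixel through the selected method; sigma_b/noise_factor only needed
# for snr_trunc
fit_pixel <- function(signal, te, method, sigma_b = NULL, noise_factor = 0.71,
                      snr_threshold = 2.5, te_floor_ms = 10, min_points = 4,
                      r2_threshold = 0.995) {
  switch(method,
    classic = fit_monoexp(signal, te),
    snr_trunc = {
      # a zero-noise background means infinite SNR on that echo: the
      # truncation rule is then a no-op there (noiseless series pass through)
      if (is.data.frame(sigma_b)) sigma_b <- sigma_b$sigma_b
      snr <- ifelse(sigma_b > 0, noise_factor * signal / sigma_b, Inf)
      keep <- truncate_by_snr(snr, te, snr_threshold, te_floor_ms, min_points)
      fit_monoexp(signal, te, keep, method = "snr_trunc")
    },
    r2_trunc = truncate_by_r2(signal, te, r2_threshold, min_points),
    t2_abort(sprintf("unknown method '%s'", method))
  )
}

#' Pixel-wise T2* maps over a myocardium mask
#'
#' Applies the selected fitting method to every mask pixel of a multi-echo
#' series, producing T2*, R^2 and retained-echo-count maps. Non-converged
#' pixels (e.g. all-zero signal) are excluded from the maps and counted in
#' the report.
#'
#' @param series An [echo_series()].
#' @param mask Logical matrix, same in-plane shape as the series.
#' @param method One of `"classic"`, `"snr_trunc"`, `"r2_trunc"`.
#' @param background A [background_roi()]; required for `snr_trunc`.
#' @param noise_factor,snr_threshold,te_floor_ms,min_points,r2_threshold
#'   Truncation parameters (defaults: NF 0.71, SNR cutoff 2.5, TE floor
#'   10 ms, floor of 4 echoes, R^2 cutoff 0.995).
#' @return An object of class `t2star_fitmaps`: matrices `t2star_map`,
#'   `r2_map`, `n_te_map`, `k_map` (NA off-mask and at excluded pixels),
#'   the `mask`, the `method` tag and a `report` list with pixel counts.
#' @export
fit_map <- function(series, mask,
                    method = c("classic", "snr_trunc", "r2_trunc"),
                    background = NULL, noise_factor = 0.71,
                    snr_threshold = 2.5, te_floor_ms = 10, min_points = 4,
                    r2_threshold = 0.995) {
  method <- match.arg(method)
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$images)
  assert_that(is.matrix(mask) && all(dim(mask) == d[1:2]),
              "mask shape must match the image shape")
  sigma_b <- NULL
  if (method == "snr_trunc") {
    assert_that(!is.null(background),
                "snr_trunc needs a background ROI to estimate sigma_b",
                class = "t2star_config_error")
    sigma_b <- background_sigma(series, background)$sigma_b
  }

  idx <- which(mask, arr.ind = TRUE)
  te <- series$te
  maps <- list(t2star_map = matrix(NA_real_, d[1], d[2]),
               r2_map = matrix(NA_real_, d[1], d[2]),
               n_te_map = matrix(NA_integer_, d[1], d[2]),
               k_map = matrix(NA_real_, d[1], d[2]))
  n_excluded <- 0L
  for (p in seq_len(nrow(idx))) {
    r <- idx[p, 1]; c <- idx[p, 2]
    fit <- fit_pixel(series$images[r, c, ], te, method,
                     sigma_b = sigma_b, noise_factor = noise_factor,
                     snr_threshold = snr_threshold, te_floor_ms = te_floor_ms,
                     min_points = min_points, r2_threshold = r2_threshold)
    if (!fit$converged) {
      n_excluded <- n_excluded + 1L
      next
    }
    maps$t2star_map[r, c] <- fit$t2star_ms
    maps$r2_map[r, c] <- fit$r2
    maps$n_te_map[r, c] <- fit$n_te_used
    maps$k_map[r, c] <- fit$K
  }
  structure(c(maps,
              list(mask = mask, method = method,
                   report = list(n_mask_pixels = nrow(idx),
                                 n_fitted = nrow(idx) - n_excluded,
                                 n_excluded = n_excluded))),
            class = "t2star_fitmaps")
}

#' @export
print.t2star_fitmaps <- function(x, ...) {
  cat(sprintf("<t2star_fitmaps> method=%s, %d/%d mask pixels fitted (%d excluded)\n",
              x$method, x$report$n_fitted, x$report$n_mask_pixels,
              x$report$n_excluded))
  invisible(x)
}

#' @rdname fit_map
#' @param x A `t2star_fitmaps` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per fitted pixel with 0-based `row`,
#'   `col` and columns `t2star_ms`, `r2`, `n_te_used`, `K`, `method`.
#' @export
tidy.t2star_fitmaps <- function(x, ...) {
  idx <- which(!is.na(x$t2star_map), arr.ind = TRUE)
  tibble::tibble(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                 t2star_ms = x$t2star_map[idx], r2 = x$r2_map[idx],
                 n_te_used = x$n_te_map[idx], K = x$k_map[idx],
                 method = x$method)
}

#' Write fit maps to NIfTI files
#' @param maps A `t2star_fitmaps` object.
#' @param dir Output directory.
#' @param stem File-name stem (default, the method tag).
#' @param pixel_spacing_mm Voxel spacing recorded in the headers.
#' @return Invisibly, the paths written.
#' @export
write_fit_maps <- function(maps, dir, stem = maps$method,
                           pixel_spacing_mm = c(1.56, 1.56)) {
  stopifnot(inherits(maps, "t2star_fitmaps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_map_nifti(maps$t2star_map, file.path(dir, paste0(stem, "_t2star.nii.gz")),
                    pixel_spacing_mm),
    write_map_nifti(maps$r2_map, file.path(dir, paste0(stem, "_r2.nii.gz")),
                    pixel_spacing_mm),
    write_map_nifti(maps$n_te_map + 0, file.path(dir, paste0(stem, "_nte.nii.gz")),
                    pixel_spacing_mm))
  invisible(paths)
}
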