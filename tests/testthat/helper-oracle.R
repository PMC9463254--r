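# Independent brute-force least-squares oracle for y ~ K exp(-TE/T2*):
# exhaustive search over a dense 2-D (K, T2*) grid, written with explicit
# loops over T2* so it shares no code path with the package's fit.
grid_search_fit <- function(y, te, k_max = 200, t2_range = c(0.5, 500),
                            n_t2 = 1500, n_k = 800) {
  te <- as.numeric(te)
  t2_grid <- exp(seq(log(t2_range[1]), log(t2_range[2]), length.out = n_t2))
  k_grid <- seq(0, k_max, length.out = n_k)
  best <- list(rss = Inf, K = NA, t2 = NA)
  sweep_grid <- function(t2_vals, k_vals, best) {
    for (t2 in t2_vals) {
      w <- exp(-te / t2)
      # residual sum of squares for every K at once
      rss <- colSums((outer(w, k_vals) - y)^2)
      i <- which.min(rss)
      if (rss[i] < best$rss) {
        best <- list(rss = rss[i], K = k_vals[i], t2 = t2)
      }
    }
    best
  }
  best <- sweep_grid(t2_grid, k_grid, best)
  # local refinement pass around the coarse optimum
  t2_fine <- seq(best$t2 * 0.97, best$t2 * 1.03, length.out = 300)
  k_fine <- seq(max(0, best$K - 2), best$K + 2, length.out = 300)
  sweep_grid(t2_fine, k_fine, best)
}

avanto <- te_scheme_avanto()
te_ms <- as.numeric(avanto)
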