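#' @importFrom stats aov kruskal.test shapiro.test pairwise.t.test pnorm
#'   p.adjust
NULL

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie correction
#' `sum(t^3 - t) / (12 (N - 1))` subtracted from `N (N + 1) / 12`, and
#' two-sided p-values Bonferroni-adjusted over the `k (k - 1) / 2` pairs.
#'
#' @param x Numeric response.
#' @param g Grouping vector (coerced to factor), same length as `x`.
#' @return Tibble with `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  assert_that(length(x) == length(g), "x and g lengths differ")
  assert_that(nlevels(g) >= 2L, "need at least two groups")
  n_tot <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
             (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
                 p_value = p, p_adjusted = p.adjust(p, "bonferroni"))
}

# Shapiro-Wilk is defined for 3 <= n <= 5000; for larger groups test a
# deterministic evenly-spaced subsample of the order statistics
shapiro_p <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) > 5000L) {
    v <- sort(v)[round(seq(1, length(v), length.out = 5000L))]
  }
  if (sd(v) == 0) return(0)  # degenerate: treat as non-normal
  shapiro.test(v)$p.value
}

#' Normality-gated group comparison with Bonferroni-family post hoc tests
#'
#' The comparison procedure used for segmental and territory T2* values:
#' Shapiro-Wilk on every group; when all groups pass at `alpha`, one-way
#' ANOVA with Bonferroni-adjusted pairwise t tests (pooled SD); otherwise
#' Kruskal-Wallis with Dunn's post hoc test under Bonferroni adjustment.
#' P < alpha (default 0.05) is considered significant.
#'
#' @param data Data frame with the response and grouping columns.
#' @param value,group Column names (tidy-eval) of the response and the
#'   grouping variable.
#' @param alpha Significance level for both the normality gate and the
#'   final flags.
#' @return An object of class `t2star_comparison`; see
#'   [tidy.t2star_comparison()] and [glance.t2star_comparison()].
#' @examples
#' df <- data.frame(t2 = c(rnorm(30, 30), rnorm(30, 30), rnorm(30, 36)),
#'                  territory = rep(c("LAD", "LCx", "RCA"), each = 30))
#' cmp <- choose_and_run_tests(df, t2, territory)
#' tidy(cmp)
#' @export
choose_and_run_tests <- function(data, value, group, alpha = 0.05) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  x <- rlang::eval_tidy(value, data)
  g <- factor(rlang::eval_tidy(group, data))
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  n <- tapply(x, g, length)
  assert_that(nlevels(g) >= 2L, "need at least two groups")
  assert_that(all(n >= 3L), "every group needs at least 3 values")

  shapiro <- tibble::tibble(
    group = levels(g),
    n = as.integer(n),
    shapiro_p = vapply(levels(g), function(l) shapiro_p(x[g == l]),
                       numeric(1)))
  all_normal <- all(shapiro$shapiro_p > alpha)

  if (all_normal) {
    branch <- "anova_bonferroni"
    fit <- aov(x ~ g)
    tab <- summary(fit)[[1]]
    omnibus <- list(test = "one-way ANOVA", statistic = tab[["F value"]][1],
                    p_value = tab[["Pr(>F)"]][1])
    pw <- pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                          pool.sd = TRUE)$p.value
    pairs <- which(!is.na(pw), arr.ind = TRUE)
    pairwise <- tibble::tibble(
      group1 = colnames(pw)[pairs[, 2]],
      group2 = rownames(pw)[pairs[, 1]],
      statistic = NA_real_,
      p_adjusted = pw[pairs])
  } else {
    branch <- "kruskal_dunn"
    kw <- kruskal.test(x, g)
    omnibus <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                    p_value = kw$p.value)
    dunn <- dunn_test(x, g)
    pairwise <- tibble::tibble(group1 = dunn$group1, group2 = dunn$group2,
                               statistic = dunn$z,
                               p_adjusted = dunn$p_adjusted)
  }
  pairwise$significant <- pairwise$p_adjusted < alpha
  structure(list(branch = branch, shapiro = shapiro, omnibus = omnibus,
                 pairwise = pairwise, alpha = alpha),
            class = "t2star_comparison")
}

#' @export
print.t2star_comparison <- function(x, ...) {
  cat(sprintf("<t2star_comparison> %s; omnibus %s p = %.4g (alpha = %g)\n",
              x$branch, x$omnibus$test, x$omnibus$p_value, x$alpha))
  print(x$pairwise)
  invisible(x)
}

#' Tidy the pairwise comparisons
#' @param x A `t2star_comparison`.
#' @param ... Unused.
#' @return Tibble of pairwise results (`group1`, `group2`, `statistic`,
#'   `p_adjusted`, `significant`).
#' @export
tidy.t2star_comparison <- function(x, ...) x$pairwise

#' One-row summary of a comparison
#' @param x A `t2star_comparison`.
#' @param ... Unused.
#' @return One-row tibble with the branch taken, the omnibus test, its
#'   statistic and p-value, and the number of significant pairs.
#' @export
glance.t2star_comparison <- function(x, ...) {
  tibble::tibble(branch = x$branch, omnibus_test = x$omnibus$test,
                 statistic = x$omnibus$statistic,
                 p_value = x$omnibus$p_value,
                 n_groups = nrow(x$shapiro),
                 n_significant_pairs = sum(x$pairwise$significant),
                 alpha = x$alpha)
}

#' Write a comparison result as CSV + JSON report
#' @param x A `t2star_comparison`.
#' @param stem Output stem; writes `<stem>_pairwise.csv` and
#'   `<stem>_report.json`.
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(x, stem) {
  stopifnot(inherits(x, "t2star_comparison"))
  csv <- paste0(stem, "_pairwise.csv")
  readr::write_csv(x$pairwise, csv)
  js <- paste0(stem, "_report.json")
  jsonlite::write_json(list(branch = x$branch, omnibus = x$omnibus,
                            alpha = x$alpha, shapiro = x$shapiro),
                       js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv, js))
}
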