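# t2star

Pixel-wise myocardial T2* relaxometry for bright-blood multi-gradient-echo
(MGE) cardiac MRI, with the two echo-train truncation strategies used to
suppress the late-TE signal plateau, AHA 16-segment analysis, iron-deposition
classification, and coronary-artery-territory statistics. It is written for
imaging scientists who need a reproducible, fully testable implementation of
the segmental T2* pipeline — including a synthetic phantom with known ground
truth, so every stage can be validated without patient data.

## The model

Each myocardial pixel's magnitude decay across echo times TE is fitted by
nonlinear least squares to the monoexponential

    y(TE) = K * exp(-TE / T2*),        K >= 0,  T2* > 0,

three ways:

* **classic** — all echoes;
* **snr_trunc** — echoes are cut where the pixel SNR drops below 2.5, with
  SNR = NF * SI / sigma_b (sigma_b from an air-background ROI per echo,
  noise factor NF = 0.71 for sum-of-squares coil combination);
* **r2_trunc** — the longest remaining TE is dropped and the pixel refitted
  until R^2 >= 0.995.

Both rules keep at least the four echoes below TE = 10 ms. Segments get
median ± MAD summaries and an iron class (normal T2* > 20 ms, moderate
10–20 ms, severe < 10 ms); segmental or pixel pools are compared with a
Shapiro–Wilk-gated choice of one-way ANOVA + Bonferroni or Kruskal–Wallis +
Dunn–Bonferroni. The fit itself uses variable projection (closed-form K given
T2*, bounded 1-D minimisation over T2*), so it is deterministic and has no
convergence failures; see the methods vignette
(`vignettes/t2star-methods.Rmd`) for every numerical choice.

## Worked example

Simulate a mid-ventricular slice with a severe-iron inferoseptal segment
(8 ms), a moderate anteroseptal-adjacent segment (15 ms) and normal
myocardium elsewhere, then run the SNR-truncated fit and summarize:

```r
library(t2star)

spec <- phantom_spec(
  t2star_by_segment = setNames(c(30, 8, 15, 30, 30, 30), 7:12),
  sigma = 3.5, seed = 42)
ph   <- generate_phantom(spec)
fm   <- fit_map(ph$series, ph$truth$mask, "snr_trunc",
                background = ph$background)
segment_summary(fm, ph$truth$labels)
#> # A tibble: 6 × 6
#>   segment_id median_t2star_ms mad_ms n_pixels iron_class method
#>        <int>            <dbl>  <dbl>    <int> <fct>      <chr>
#> 1          7            30.2   2.11       106 normal     snr_trunc
#> 2          8             8.09  0.347      106 severe     snr_trunc
#> 3          9            15.1   0.707      106 moderate   snr_trunc
#> 4         10            30.1   2.21       106 normal     snr_trunc
#> 5         11            28.8   1.62       106 normal     snr_trunc
#> 6         12            30.5   2.93       106 normal     snr_trunc
```

The fitted medians recover the programmed 30 / 8 / 15 ms ground truth and the
classes follow the 10/20 ms thresholds. Pixel pools by coronary territory
feed the comparison machinery:

```r
pools <- pool_by_territory(fm, ph$truth$labels)
cmp   <- choose_and_run_tests(pools, t2star_ms, artery)
glance(cmp)
#> # A tibble: 1 × 7
#>   branch       omnibus_test   statistic  p_value n_groups n_significant_pairs alpha
#>   <chr>        <chr>              <dbl>    <dbl>    <int>               <int> <dbl>
#> 1 kruskal_dunn Kruskal-Wallis      103. 4.43e-23        3                   3  0.05
```

Here every pairwise territory contrast is flagged because the short-T2*
segments sit in the LAD and RCA territories while the LCx stays normal.
`autoplot(fm)` renders the T2* map; `analyze_study()` and `run_study()`
(YAML-configured, with a thin CLI at `inst/cli/t2star`) orchestrate the full
multi-slice pipeline including the TE-usage breakdown tables.

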