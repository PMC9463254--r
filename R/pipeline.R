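#' Analysis configuration
#'
#' Collects every tunable constant of the study pipeline with the standard
#' defaults: SNR cutoff 2.5, R^2 cutoff 0.995, 4-echo floor, 10 ms TE
#' floor, noise factor 0.71, iron class boundaries 10/20 ms, alpha 0.05.
#'
#' @param methods Fitting methods to run.
#' @param snr_threshold,r2_threshold,min_points,te_floor_ms,noise_factor
#'   Truncation parameters.
#' @param moderate_lower_closed Whether T2* = 10 ms classifies as moderate.
#' @param territory_table Coronary contribution tibble (default the
#'   traditional all-or-nothing map) or a CSV path.
#' @param exclusivity_threshold Dominance threshold for territory pooling.
#' @param alpha Significance level.
#' @param seed Seed recorded in the run report (the analysis itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(methods = c("classic", "snr_trunc", "r2_trunc"),
                       snr_threshold = 2.5, r2_threshold = 0.995,
                       min_points = 4, te_floor_ms = 10,
                       noise_factor = 0.71,
                       moderate_lower_closed = TRUE,
                       territory_table = traditional_territories(),
                       exclusivity_threshold = 1,
                       alpha = 0.05, seed = 1L) {
  assert_that(length(methods) >= 1L, "methods must be non-empty")
  assert_that(all(methods %in% c("classic", "snr_trunc", "r2_trunc")),
              "unknown method name")
  assert_that(all(c(snr_threshold, r2_threshold, min_points, te_floor_ms,
                    noise_factor, alpha) > 0), "thresholds must be positive")
  if (is.character(territory_table)) {
    territory_table <- read_territory_table(territory_table)
  }
  validate_territory_table(territory_table)
  structure(list(methods = methods, snr_threshold = snr_threshold,
                 r2_threshold = r2_threshold, min_points = min_points,
                 te_floor_ms = te_floor_ms, noise_factor = noise_factor,
                 moderate_lower_closed = moderate_lower_closed,
                 territory_table = territory_table,
                 exclusivity_threshold = exclusivity_threshold,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full segmental T2* study on loaded slices
#'
#' Orchestrates the whole analysis for a set of short-axis slices: pixel
#' fitting by every configured method, AHA parcellation, segmental
#' median/MAD summaries with iron classes, region grouping (global, septal,
#' inferolateral), the TE-usage breakdown, coronary-territory pooling with
#' the group comparison, and a run report counting pixels and segments at
#' every stage.
#'
#' @param slices List of slices; each a list with `series`
#'   ([echo_series()]), `contours` ([contour_set()]) and `background`
#'   ([background_roi()]).
#' @param config A [run_config()].
#' @return A list of class `t2star_study` with elements `fits` (per slice
#'   x method), `labels`, `segment_summaries`, `region_segments`,
#'   `te_usage`, `territory_pools`, `territory_comparisons` (per method),
#'   `method_comparisons` (per region), and `report`.
#' @export
analyze_study <- function(slices, config = run_config()) {
  assert_that(length(slices) >= 1L, "no slices supplied")
  regions <- aha_region_groups()
  assignment <- dominant_segments(config$territory_table,
                                  config$exclusivity_threshold)

  per_slice <- purrr::imap(slices, function(sl, i) {
    stopifnot(inherits(sl$series, "echo_series"))
    shp <- dim(sl$series$images)[1:2]
    mask <- rasterize_myocardium(sl$contours, shp)
    labels <- assign_aha_segments(mask, sl$contours$rv_insertion,
                                  sl$series$slice_level)
    fits <- lapply(setNames(config$methods, config$methods), function(m) {
      fit_map(sl$series, mask, m, background = sl$background,
              noise_factor = config$noise_factor,
              snr_threshold = config$snr_threshold,
              te_floor_ms = config$te_floor_ms,
              min_points = config$min_points,
              r2_threshold = config$r2_threshold)
    })
    list(slice = i, labels = labels, fits = fits)
  })

  summaries <- purrr::map_dfr(per_slice, function(ps) {
    purrr::map_dfr(ps$fits, function(fm) {
      segment_summary(fm, ps$labels, config$moderate_lower_closed)
    }) |> dplyr::mutate(slice = ps$slice)
  })

  # the TE-usage breakdown is anchored on classic-fit classes; without a
  # classic run it is not defined
  if ("classic" %in% config$methods) {
    pixel_fits <- purrr::map_dfr(per_slice, function(ps) {
      pixel_fits_with_class(ps$fits, ps$labels) |>
        dplyr::mutate(slice = ps$slice)
    })
    te_usage <- te_usage_breakdown(pixel_fits)
  } else {
    pixel_fits <- NULL
    te_usage <- NULL
  }

  pools <- purrr::map_dfr(per_slice, function(ps) {
    purrr::map_dfr(ps$fits, function(fm) {
      pool_by_territory(fm, ps$labels, assignment)
    }) |> dplyr::mutate(slice = ps$slice)
  })
  territory_cmp <- lapply(setNames(config$methods, config$methods),
    function(m) {
      sub <- pools[pools$method == m, ]
      if (length(unique(sub$artery)) < 2 ||
          any(table(sub$artery) < 3)) return(NULL)
      choose_and_run_tests(sub, t2star_ms, artery,
                           alpha = config$alpha)
    })

  # per-region comparison of segmental medians between methods
  method_cmp <- lapply(regions, function(segs) {
    sub <- summaries[summaries$segment_id %in% segs, ]
    if (length(unique(sub$method)) < 2 ||
        any(table(sub$method) < 3)) return(NULL)
    choose_and_run_tests(sub, median_t2star_ms, method,
                         alpha = config$alpha)
  })

  n_excl <- sum(purrr::map_dbl(per_slice, function(ps) {
    sum(purrr::map_dbl(ps$fits, function(f) f$report$n_excluded))
  }))
  report <- list(
    n_slices = length(slices),
    n_segments = study_segment_count(lapply(per_slice, `[[`, "labels")),
    n_myocardial_pixels = sum(purrr::map_dbl(per_slice,
                                             function(ps) sum(ps$labels > 0))),
    n_excluded_pixels = as.integer(n_excl),
    class_counts = summaries |>
      dplyr::count(.data$method, .data$iron_class, .drop = FALSE),
    seed = config$seed)

  structure(list(fits = per_slice, segment_summaries = summaries,
                 pixel_fits = pixel_fits, te_usage = te_usage,
                 territory_pools = pools,
                 territory_comparisons = territory_cmp,
                 method_comparisons = method_cmp,
                 region_segments = regions, report = report,
                 config = config),
            class = "t2star_study")
}

#' @export
print.t2star_study <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<t2star_study> %d slices, %d segments, %d myocardial",
                     " pixels (%d excluded)\n"),
              r$n_slices, r$n_segments, r$n_myocardial_pixels,
              r$n_excluded_pixels))
  invisible(x)
}

#' Run a study from a YAML config and write the output bundle
#'
#' File-level front end over [analyze_study()]. The YAML config lists the
#' input files per slice and the analysis constants, e.g.:
#' ```yaml
#' slices:
#'   - image: mid.nii.gz        # NIfTI + JSON TE sidecar
#'     contours: mid_contours.json
#'     slice_level: mid
#' background: {row0: 1, col0: 1, rows: 8, cols: 8}
#' output_dir: out/
#' ```
#' plus optional keys matching [run_config()] arguments. Writes per-method
#' T2*/R^2/n-TE maps (NIfTI), segment summaries, TE-usage and territory
#' tables (CSV), comparison reports (CSV/JSON) and a JSON run report with
#' the stage counts.
#'
#' @param config_path Path to the YAML config.
#' @return Invisibly, the `t2star_study` result.
#' @export
run_study <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  assert_that(!is.null(cfg$slices) && length(cfg$slices) >= 1L,
              "config must list at least one slice",
              class = "t2star_config_error")
  base <- dirname(config_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  bg <- cfg$background %||% list(row0 = 1, col0 = 1, rows = 8, cols = 8)
  roi <- background_roi(as.matrix(expand.grid(
    row = bg$row0 + seq_len(bg$rows) - 1L,
    col = bg$col0 + seq_len(bg$cols) - 1L)))
  slices <- lapply(cfg$slices, function(sl) {
    list(series = load_echo_series(resolve(sl$image),
                                   te_override = sl$te_ms,
                                   slice_level = sl$slice_level %||% "mid"),
         contours = read_contours(resolve(sl$contours)),
         background = roi)
  })
  keys <- intersect(names(cfg), names(formals(run_config)))
  config <- do.call(run_config, cfg[keys])

  study <- analyze_study(slices, config)

  out <- cfg$output_dir %||% "t2star_out"
  if (!file.exists(out)) dir.create(out, recursive = TRUE)
  for (ps in study$fits) {
    for (fm in ps$fits) {
      write_fit_maps(fm, out, sprintf("slice%02d_%s", ps$slice, fm$method))
    }
  }
  readr::write_csv(study$segment_summaries,
                   file.path(out, "segment_summaries.csv"))
  if (!is.null(study$te_usage)) {
    readr::write_csv(study$te_usage, file.path(out, "te_usage.csv"))
  }
  readr::write_csv(study$territory_pools,
                   file.path(out, "territory_pools.csv"))
  for (m in names(study$territory_comparisons)) {
    cmp <- study$territory_comparisons[[m]]
    if (!is.null(cmp)) {
      write_comparison(cmp, file.path(out, paste0("territory_", m)))
    }
  }
  jsonlite::write_json(study$report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       factor = "string")
  invisible(study)
}
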