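#' Configuration of an end-to-end run
#'
#' @param areas Path to the area-unit table (CSV or GeoJSON).
#' @param events Path to the event table CSV.
#' @param std Path to the standard-population CSV.
#' @param out_dir Output directory (created if absent).
#' @param radii Local calibration radii in km; default `c(10, 20, 30)`.
#' @param threshold_pct Top-percent dichotomization cut; default 15.
#' @param categories Diagnostic categories to analyze; default all four.
#' @param alpha Two-sided error rate for CIs; default 0.05.
#' @param min_window_size Minimum local window size for a determinate
#'   flag; default 10.
#' @param crude_rate Standard crude rate if not in the std file.
#' @param weights Optional named ADI weight vector (see [adi_weights()]).
#' @param seed Seed for any simulation step; default 1.
#' @return Object of class `run_config`.
#' @export
run_config <- function(areas, events, std, out_dir,
                       radii = c(10, 20, 30), threshold_pct = 15,
                       categories = c("total", "respiratory", "circulatory", "mental"),
                       alpha = 0.05, min_window_size = 10,
                       crude_rate = NULL, weights = NULL, seed = 1L) {
  if (any(radii <= 0)) stop("`radii` must be positive", call. = FALSE)
  if (threshold_pct <= 0 || threshold_pct >= 100) {
    stop("`threshold_pct` must be in (0, 100)", call. = FALSE)
  }
  structure(list(areas = areas, events = events, std = std,
                 out_dir = out_dir, radii = radii,
                 threshold_pct = threshold_pct, categories = categories,
                 alpha = alpha, min_window_size = min_window_size,
                 crude_rate = crude_rate, weights = weights,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips losslessly through the file.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$radii <- as.numeric(y$radii)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- unclass(config)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Reads the area, event and standard-population inputs; computes raw ADI
#' scores, regional and local calibrations; indirectly age-adjusts each
#' category's rates; estimates the Mantel-Haenszel odds ratio of each
#' deprivation flag scale against each category; and writes `adi.csv`,
#' `adjusted_rates.csv`, `or_table.csv`, `region_annotated.geojson` and
#' `run_log.txt` into the output directory. Deterministic given inputs
#' and config; every output carries a provenance header with the config
#' hash.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `region`, `adi` (per-scale calibration
#'   tables), `adjusted` (per-category adjusted rates), `or_table`, and
#'   the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warn_log <- character(0)
  wh <- function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    region <- .stage("read_areas", read_areas(config$areas))
    events_raw <- .stage("read_events", read_events(config$events))
    std <- .stage("read_standard_pop",
                  read_standard_pop(config$std, config$crude_rate))
    events <- .stage("average_years",
                     if (length(unique(events_raw$year)) > 1) {
                       average_years(events_raw)
                     } else events_raw)
    .stage("validate_categories", {
      absent <- setdiff(config$categories, unique(events$category))
      if (length(absent) > 0) {
        stop("event table has no rows for category(ies): ",
             paste(absent, collapse = ", "),
             "; set `categories` to those present", call. = FALSE)
      }
    })

    weights <- .stage("weights",
                      if (is.null(config$weights)) adi_weights() else
                        adi_weights(unlist(config$weights)))
    raw <- .stage("compute_raw_adi", compute_raw_adi(region$profile, weights))
    dist <- .stage("pairwise_distance", pairwise_distance(region))
    calib <- .stage("calibration",
                    adi_by_scale(region, raw, config$radii,
                                 config$threshold_pct,
                                 config$min_window_size, dist = dist))

    adjusted <- .stage("indirect_adjust", do.call(rbind, lapply(
      config$categories, function(cat) indirect_adjust(region, events, std, cat))))

    or_table <- .stage("association", do.call(rbind, lapply(
      config$categories, function(cat) {
        compare_scales(region, raw, events, cat, config$radii,
                       config$threshold_pct, config$min_window_size,
                       config$alpha, dist = dist)
      })))
  }, warning = wh)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    adi = file.path(config$out_dir, "adi.csv"),
    adjusted = file.path(config$out_dir, "adjusted_rates.csv"),
    or_table = file.path(config$out_dir, "or_table.csv"),
    geojson = file.path(config$out_dir, "region_annotated.geojson"),
    log = file.path(config$out_dir, "run_log.txt"))
  .stage("write_outputs", {
    write_adi(calib, paths$adi, config)
    .write_csv_prov(adjusted, paths$adjusted, config)
    write_or_table(or_table, paths$or_table, config)
    export_geojson(region, calib, paths$geojson, config)
    writeLines(c(.provenance_line(config),
                 sprintf("units: %d; strata: %d; categories: %s",
                         n_units(region), ncol(region$pop),
                         paste(config$categories, collapse = ", ")),
                 sprintf("warnings (%d):", length(warn_log)),
                 paste0("  - ", warn_log)),
               paths$log)
  })

  invisible(list(region = region, adi = calib, adjusted = adjusted,
                 or_table = or_table, paths = paths))
}

#' Write a simulated scenario to disk in the pipeline's input formats
#'
#' Produces `areas.csv`, `events.csv` and `std.csv` in `out_dir`, so a
#' synthetic scenario can be fed straight back through [run_pipeline()]
#' or the command-line interface.
#'
#' @param config A [scenario_config()] or preset name.
#' @param out_dir Output directory.
#' @param ... Preset overrides when `config` is a name.
#' @return Invisibly, the list from [simulate_scenario()] plus `paths`.
#' @export
write_scenario <- function(config, out_dir, ...) {
  sim <- simulate_scenario(config, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(areas = file.path(out_dir, "areas.csv"),
                events = file.path(out_dir, "events.csv"),
                std = file.path(out_dir, "std.csv"))
  write_areas(sim$region, paths$areas, sim$config)
  write_events(sim$events, paths$events, sim$config)
  write_standard_pop(sim$std, paths$std, sim$config)
  sim$paths <- paths
  invisible(sim)
}
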