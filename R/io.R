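.provenance_line <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("localADI"))
  hash <- if (is.null(config)) "none" else {
    cfg <- unclass(config)
    cfg$out_dir <- NULL # hash the analysis parameters, not the output location
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(cfg, tf)
    unname(tools::md5sum(tf))
  }
  sprintf("# localADI %s | config_md5 %s", ver, hash)
}

.write_csv_prov <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_line(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Read an area-unit table
#'
#' CSV: columns `unit_id`, `centroid_lon`/`centroid_lat` (or
#' `centroid_x`/`centroid_y` in meters), `pop_<stratum>` columns, and the
#' 17 census variables of [adi_variables()]. GeoJSON (`.geojson`/`.json`):
#' a FeatureCollection whose feature properties carry the same fields;
#' centroids are taken from Point geometries or computed as the vertex
#' average of a Polygon's outer ring when absent from the properties.
#'
#' @param path Path to the CSV or GeoJSON file.
#' @return A [study_region()].
#' @export
read_areas <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    return(.read_areas_geojson(path))
  }
  df <- .read_csv(path)
  need <- c("unit_id", adi_variables())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("areas file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  study_region(df)
}

.read_areas_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    props <- f$properties
    if (is.null(props$centroid_lon) || is.null(props$centroid_lat)) {
      cen <- .geojson_centroid(f$geometry)
      props$centroid_lon <- cen[1]
      props$centroid_lat <- cen[2]
    }
    as.data.frame(props, stringsAsFactors = FALSE)
  })
  study_region(do.call(rbind, rows), coords = "lonlat")
}

# Point coordinates directly; Polygon: vertex average of the outer ring
# (adequate for the small, compact units simulated and exported here).
.geojson_centroid <- function(geom) {
  if (is.null(geom)) stop("feature without geometry or centroid properties", call. = FALSE)
  if (geom$type == "Point") return(unlist(geom$coordinates))
  if (geom$type == "Polygon") {
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], unlist))
    # drop the closing vertex if the ring is explicitly closed
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    return(colMeans(ring))
  }
  stop("unsupported geometry type: ", geom$type, call. = FALSE)
}

#' Write a calibration result table to CSV
#'
#' Columns `unit_id`, `raw_score`, `percentile`, `flag`, `scale`,
#' `threshold_pct` (plus `window_size`), preceded by a provenance comment
#' line.
#'
#' @param results One calibration data frame or a list of them (e.g. from
#'   [adi_by_scale()]), row-bound into one table.
#' @param path Output CSV path.
#' @param config Optional config whose hash goes into the provenance line.
#' @return The path, invisibly.
#' @export
write_adi <- function(results, path, config = NULL) {
  if (is.data.frame(results)) results <- list(results)
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  invisible(.write_csv_prov(out, path, config))
}

#' Read an event table
#'
#' CSV with columns `unit_id`, `age_stratum`, `year`, `count`, and either
#' `category` (used as-is) or `icd9_code` (classified with
#' [classify_icd9()]; each classifiable row contributes to its named
#' category and to `total`, V/E-codes per `include_ve_in_total`).
#'
#' @param path Path to the CSV file.
#' @param include_ve_in_total Passed to [icd9_in_total()] when classifying
#'   codes.
#' @return A validated event table.
#' @export
read_events <- function(path, include_ve_in_total = FALSE) {
  df <- .read_csv(path)
  if (!"category" %in% names(df)) {
    if (!"icd9_code" %in% names(df)) {
      stop("events file needs a `category` or `icd9_code` column", call. = FALSE)
    }
    cat <- classify_icd9(df$icd9_code)
    in_total <- icd9_in_total(df$icd9_code, include_ve_in_total)
    n_dropped <- sum(!in_total & is.na(cat))
    if (n_dropped > 0) {
      message(n_dropped, " event row(s) with V/E or unparseable ICD-9 codes excluded from all categories")
    }
    named <- df[!is.na(cat), , drop = FALSE]
    named$category <- cat[!is.na(cat)]
    tot <- df[in_total, , drop = FALSE]
    if (nrow(tot) > 0) tot$category <- "total"
    df <- rbind(named, tot)
    df$icd9_code <- NULL
  }
  validate_events(df)
}

#' Write an event table to CSV
#' @param events An event table.
#' @param path Output CSV path.
#' @param config Optional config for the provenance line.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path, config = NULL) {
  invisible(.write_csv_prov(validate_events(events), path, config))
}

#' Read a standard population
#'
#' CSV with columns `age_stratum`, `rate`; the crude rate comes from a
#' `crude_rate` column (constant), from the `crude_rate` argument, or — if
#' neither is given — is left to error, since it cannot be derived from
#' stratum rates alone.
#'
#' @param path Path to the CSV file.
#' @param crude_rate Standard crude rate, if not a column of the file.
#' @return A [standard_population()].
#' @export
read_standard_pop <- function(path, crude_rate = NULL) {
  df <- .read_csv(path)
  need <- c("age_stratum", "rate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("standard-population file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(crude_rate)) {
    if (!"crude_rate" %in% names(df)) {
      stop("supply `crude_rate` or include a crude_rate column", call. = FALSE)
    }
    crude_rate <- unique(df$crude_rate)
    if (length(crude_rate) != 1) {
      stop("crude_rate column must be constant", call. = FALSE)
    }
  }
  standard_population(stats::setNames(df$rate, df$age_stratum), crude_rate)
}

#' Write a standard population to CSV
#' @param std A [standard_population()].
#' @param path Output CSV path.
#' @param config Optional config for the provenance line.
#' @return The path, invisibly.
#' @export
write_standard_pop <- function(std, path, config = NULL) {
  stopifnot(inherits(std, "standard_population"))
  df <- data.frame(age_stratum = names(std$rates), rate = unname(std$rates),
                   crude_rate = std$crude_rate, stringsAsFactors = FALSE)
  invisible(.write_csv_prov(df, path, config))
}

#' Write a region's area-unit table to CSV
#'
#' Inverse of [read_areas()] (CSV flavor): centroids, `pop_<stratum>`
#' columns and the 17 census variables.
#'
#' @param region A [study_region()].
#' @param path Output CSV path.
#' @param config Optional config for the provenance line.
#' @return The path, invisibly.
#' @export
write_areas <- function(region, path, config = NULL) {
  stopifnot(inherits(region, "study_region"))
  df <- data.frame(unit_id = region$unit_id, stringsAsFactors = FALSE)
  if (region$coords == "lonlat") {
    df$centroid_lon <- region$centroid[, 1]
    df$centroid_lat <- region$centroid[, 2]
  } else {
    df$centroid_x <- region$centroid[, 1]
    df$centroid_y <- region$centroid[, 2]
  }
  for (s in colnames(region$pop)) df[[paste0("pop_", s)]] <- region$pop[, s]
  df <- cbind(df, as.data.frame(region$profile))
  invisible(.write_csv_prov(df, path, config))
}

#' Export a region with ADI attributes as GeoJSON
#'
#' A FeatureCollection of Point features (the unit centroids) whose
#' properties carry the unit id, the raw composite score and, per
#' calibration scale, the percentile and flag (`pctile_regional` /
#' `flag_regional`, `pctile_local_<r>km` / `flag_local_<r>km`) — ready for
#' choropleth-style rendering in any GIS. Projected centroids are exported
#' as-is with the coordinate note in the collection's `provenance` member
#' (RFC 7946 GeoJSON proper expects WGS84 lon/lat).
#'
#' @param region A [study_region()].
#' @param calibrations Named list of calibration result data frames, as
#'   returned by [adi_by_scale()].
#' @param path Output `.geojson` path.
#' @param config Optional config for the provenance member.
#' @return The path, invisibly.
#' @export
export_geojson <- function(region, calibrations, path, config = NULL) {
  stopifnot(inherits(region, "study_region"))
  prop_name <- function(scale, what) {
    if (scale == "regional") return(paste0(what, "_regional"))
    r <- sub("^local\\((.*)km\\)$", "\\1", scale)
    sprintf("%s_local_%skm", what, r)
  }
  features <- lapply(seq_along(region$unit_id), function(i) {
    props <- list(unit_id = region$unit_id[i])
    props$adi_raw <- calibrations[[1]]$raw_score[i]
    for (scale in names(calibrations)) {
      cal <- calibrations[[scale]]
      props[[prop_name(scale, "pctile")]] <- cal$percentile[i]
      props[[prop_name(scale, "flag")]] <- cal$flag[i]
    }
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = unname(region$centroid[i, ])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection",
             provenance = list(generator = .provenance_line(config),
                               coords = region$coords,
                               crs_note = region$crs_note),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Write the scale-comparison odds-ratio table
#'
#' One row per (scale, category) with the Mantel-Haenszel estimate and CI,
#' plus a human-readable `"OR (low-high)"` column mirroring the layout of
#' published scale-comparison tables.
#'
#' @param or_table Data frame from [compare_scales()] (possibly row-bound
#'   over categories).
#' @param path Output CSV path.
#' @param config Optional config for the provenance line.
#' @return The path, invisibly.
#' @export
write_or_table <- function(or_table, path, config = NULL) {
  or_table$formatted <- sprintf("%.2f (%.2f-%.2f)", or_table$estimate,
                                or_table$ci_low, or_table$ci_high)
  invisible(.write_csv_prov(or_table, path, config))
}
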