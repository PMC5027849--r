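#' Construct a study region of area units
#'
#' A study region bundles the spatial units of a small-area analysis
#' (ZCTA-like units): a unique identifier, a centroid, an age-stratified
#' population, and the 17-variable census profile of each unit.
#'
#' @param areas Data frame with columns `unit_id`; either
#'   `centroid_lon`/`centroid_lat` (degrees, WGS84) or
#'   `centroid_x`/`centroid_y` (projected meters); one `pop_<stratum>`
#'   column per age stratum (person counts); and the 17 census variable
#'   columns of [adi_variables()].
#' @param coords `"lonlat"` or `"projected"`. Inferred from the column
#'   names when exactly one convention is present; supplying both
#'   conventions without naming one is an error.
#' @param crs_note Free-text note on the coordinate convention.
#' @return An object of class `study_region` with elements `unit_id`,
#'   `centroid` (n x 2 matrix), `coords`, `pop` (n x strata matrix),
#'   `profile` (n x 17 matrix), `crs_note`.
#' @export
study_region <- function(areas, coords = NULL, crs_note = NULL) {
  if (!is.data.frame(areas)) stop("`areas` must be a data frame", call. = FALSE)
  if (!"unit_id" %in% names(areas)) stop("`areas` needs a unit_id column", call. = FALSE)
  unit_id <- as.character(areas$unit_id)
  if (anyDuplicated(unit_id)) {
    stop("duplicate unit_id: ",
         paste(unique(unit_id[duplicated(unit_id)]), collapse = ", "), call. = FALSE)
  }

  has_ll <- all(c("centroid_lon", "centroid_lat") %in% names(areas))
  has_xy <- all(c("centroid_x", "centroid_y") %in% names(areas))
  if (is.null(coords)) {
    if (has_ll && has_xy) {
      stop("both lon/lat and projected centroid columns present; ",
           "pass coords = \"lonlat\" or \"projected\"", call. = FALSE)
    }
    coords <- if (has_ll) "lonlat" else if (has_xy) "projected" else
      stop("no centroid columns found (centroid_lon/centroid_lat or centroid_x/centroid_y)",
           call. = FALSE)
  }
  coords <- match.arg(coords, c("lonlat", "projected"))
  centroid <- if (coords == "lonlat") {
    if (!has_ll) stop("coords = \"lonlat\" but centroid_lon/centroid_lat missing", call. = FALSE)
    cbind(lon = areas$centroid_lon, lat = areas$centroid_lat)
  } else {
    if (!has_xy) stop("coords = \"projected\" but centroid_x/centroid_y missing", call. = FALSE)
    cbind(x = areas$centroid_x, y = areas$centroid_y)
  }
  if (anyNA(centroid) || any(!is.finite(centroid))) {
    stop("all centroids must be present and finite", call. = FALSE)
  }
  rownames(centroid) <- unit_id

  pop_cols <- grep("^pop_", names(areas), value = TRUE)
  if (length(pop_cols) == 0) stop("no pop_<stratum> columns found", call. = FALSE)
  pop <- as.matrix(areas[pop_cols])
  colnames(pop) <- sub("^pop_", "", pop_cols)
  rownames(pop) <- unit_id
  storage.mode(pop) <- "double"
  if (anyNA(pop) || any(pop < 0)) {
    stop("age-stratum populations must be non-negative and non-missing", call. = FALSE)
  }

  profile <- .as_profile_matrix(areas)
  .validate_profile_ranges(profile)
  rownames(profile) <- unit_id

  structure(list(unit_id = unit_id, centroid = centroid, coords = coords,
                 pop = pop, profile = profile,
                 crs_note = crs_note %||%
                   if (coords == "lonlat") "WGS84 lon/lat degrees" else "projected meters"),
            class = "study_region")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_region <- function(x, ...) {
  cat("<study_region> ", length(x$unit_id), " units, ",
      ncol(x$pop), " age strata, coords: ", x$coords,
      " (", x$crs_note, ")\n", sep = "")
  cat("  total population: ", format(sum(x$pop), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Number of units in a study region
#' @param region A `study_region`.
#' @return Integer count of area units.
#' @export
n_units <- function(region) length(region$unit_id)

#' Age stratum labels of a study region
#' @param region A `study_region`.
#' @return Character vector of stratum labels (the `pop_` column suffixes).
#' @export
strata_labels <- function(region) colnames(region$pop)

# Named raw-score vector aligned to the region's units; accepts unnamed
# vectors in region order.
.align_scores <- function(region, raw_scores) {
  n <- n_units(region)
  if (is.null(names(raw_scores))) {
    if (length(raw_scores) != n) {
      stop("raw_scores must cover all ", n, " units", call. = FALSE)
    }
    names(raw_scores) <- region$unit_id
    return(raw_scores)
  }
  missing_ids <- setdiff(region$unit_id, names(raw_scores))
  if (length(missing_ids) > 0) {
    stop("raw_scores missing unit(s): ",
         paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  raw_scores[region$unit_id]
}
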