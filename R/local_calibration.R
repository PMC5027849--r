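#' Pairwise centroid distances between area units, in km
#'
#' Great-circle (haversine) distance on a sphere of authalic radius
#' 6371.0088 km for lon/lat regions; Euclidean distance for projected
#' (meter) regions.
#'
#' @param region A [study_region()].
#' @return Symmetric n x n matrix of distances in kilometers, zero
#'   diagonal, dimnames = unit ids.
#' @export
pairwise_distance <- function(region) {
  stopifnot(inherits(region, "study_region"))
  xy <- region$centroid
  n <- nrow(xy)
  if (region$coords == "lonlat") {
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      d[i, ] <- geosphere::distHaversine(xy[i, , drop = FALSE], xy, r = 6371.0088)
    }
    d <- (d + t(d)) / 2 # enforce exact symmetry against rounding
  } else {
    dx <- outer(xy[, 1], xy[, 1], "-")
    dy <- outer(xy[, 2], xy[, 2], "-")
    d <- sqrt(dx^2 + dy^2) / 1000
  }
  diag(d) <- 0
  dimnames(d) <- list(region$unit_id, region$unit_id)
  d
}

#' Units within a radius of a central unit
#'
#' The moving window of the local calibration: all units (the central unit
#' included) whose centroid lies within `radius_km` of the central unit's
#' centroid.
#'
#' @param region A [study_region()].
#' @param unit_id Identifier of the central unit.
#' @param radius_km Window radius in km, `>= 0` (radius 0 returns the unit
#'   itself).
#' @param dist Optional precomputed [pairwise_distance()] matrix.
#' @return Character vector of unit ids in the window.
#' @export
neighborhood <- function(region, unit_id, radius_km, dist = NULL) {
  stopifnot(inherits(region, "study_region"))
  if (!is.numeric(radius_km) || length(radius_km) != 1 || is.na(radius_km) ||
      radius_km < 0) {
    stop("`radius_km` must be a single non-negative number", call. = FALSE)
  }
  if (!unit_id %in% region$unit_id) {
    stop("unknown unit_id: ", unit_id, call. = FALSE)
  }
  if (is.null(dist)) dist <- pairwise_distance(region)
  region$unit_id[dist[unit_id, ] <= radius_km]
}

.adi_result <- function(region, raw_scores, percentile, flag, scale,
                        threshold_pct, window_size) {
  data.frame(unit_id = region$unit_id,
             raw_score = unname(raw_scores),
             percentile = unname(percentile),
             flag = unname(flag),
             scale = scale,
             threshold_pct = threshold_pct,
             window_size = unname(window_size),
             stringsAsFactors = FALSE)
}

#' Regional ADI calibration
#'
#' Percentile-ranks the raw ADI scores over the whole study region and
#' flags the top `threshold_pct` percent ([dichotomize()]).
#'
#' @param region A [study_region()] with at least 2 units.
#' @param raw_scores Per-unit raw ADI scores (named by unit id, or in
#'   region order), e.g. from [compute_raw_adi()].
#' @param threshold_pct Top-percent cut, default 15.
#' @return Data frame with columns `unit_id`, `raw_score`, `percentile`,
#'   `flag`, `scale` (`"regional"`), `threshold_pct`, `window_size` (the
#'   region size).
#' @export
regional_adi <- function(region, raw_scores, threshold_pct = 15) {
  stopifnot(inherits(region, "study_region"))
  if (n_units(region) < 2) stop("regional calibration needs >= 2 units", call. = FALSE)
  s <- .align_scores(region, raw_scores)
  pct <- percentile_rank(s)
  .adi_result(region, s, pct, dichotomize(pct, threshold_pct),
              "regional", threshold_pct, n_units(region))
}

#' Local (moving-window) ADI calibration
#'
#' Each unit's ADI percentile is computed relative only to the units whose
#' centroids lie within `radius_km` of its own centroid (the central unit
#' included, so the radius-to-infinity limit reproduces the regional
#' calibration exactly). A unit in the top `threshold_pct` percent of its
#' own window is flagged as highly deprived in its local context. Windows
#' smaller than `min_window` units keep their percentile but get an
#' indeterminate flag (`NA`): a top-percent cut among a handful of
#' neighbors is not meaningful.
#'
#' @inheritParams regional_adi
#' @param radius_km Window radius in km, `> 0` (the study's scales were 10,
#'   20 and 30 km).
#' @param min_window Minimum window size for a determinate flag; default
#'   10 units.
#' @param include_self Keep the central unit in its own comparison set
#'   (default `TRUE`). When `FALSE` the percentile is computed among the
#'   neighbors only and may be 0 for a locally minimal unit.
#' @param dist Optional precomputed [pairwise_distance()] matrix.
#' @return Data frame as in [regional_adi()] with `scale =
#'   "local(<r>km)"` and `window_size` = the number of units in each
#'   window; `flag` is `NA` for windows below `min_window`.
#' @export
local_adi <- function(region, raw_scores, radius_km, threshold_pct = 15,
                      min_window = 10, include_self = TRUE, dist = NULL) {
  stopifnot(inherits(region, "study_region"))
  if (n_units(region) < 2) stop("local calibration needs >= 2 units", call. = FALSE)
  if (!is.numeric(radius_km) || length(radius_km) != 1 || is.na(radius_km) ||
      radius_km <= 0) {
    stop("`radius_km` must be a single positive number", call. = FALSE)
  }
  s <- .align_scores(region, raw_scores)
  if (anyNA(s) || any(!is.finite(s))) {
    stop("raw_scores must be finite and non-missing", call. = FALSE)
  }
  if (is.null(dist)) dist <- pairwise_distance(region)

  w <- dist <= radius_km # includes self: diagonal is 0
  if (!include_self) diag(w) <- FALSE
  # leq[i, j]: does unit j's score count as <= unit i's score
  leq <- outer(s, s, FUN = ">=")
  size <- rowSums(w)
  cnt <- rowSums(w & leq)
  pct <- ifelse(size > 0, 100 * cnt / size, NA_real_)
  flag <- rep(NA, length(s))
  ok <- size >= min_window
  if (any(ok)) flag[ok] <- dichotomize(pmax(pct[ok], .Machine$double.xmin),
                                       threshold_pct)
  # include_self = FALSE can yield percentile 0; it is never flagged
  if (!include_self) flag[ok & pct[ok] == 0] <- FALSE
  .adi_result(region, s, pct, flag, sprintf("local(%gkm)", radius_km),
              threshold_pct, if (include_self) size else size + 1L)
}

#' Compute ADI flags across local and regional scales
#'
#' Convenience wrapper running [local_adi()] for each radius and
#' [regional_adi()] once, from a single shared distance matrix.
#'
#' @inheritParams local_adi
#' @param radii Vector of positive window radii in km; default
#'   `c(10, 20, 30)`.
#' @return Named list of calibration result data frames: one
#'   `"local(<r>km)"` entry per radius, plus `"regional"`.
#' @export
adi_by_scale <- function(region, raw_scores, radii = c(10, 20, 30),
                         threshold_pct = 15, min_window = 10,
                         include_self = TRUE, dist = NULL) {
  if (is.null(dist)) dist <- pairwise_distance(region)
  out <- lapply(radii, function(r) {
    local_adi(region, raw_scores, r, threshold_pct, min_window,
              include_self, dist)
  })
  names(out) <- sprintf("local(%gkm)", radii)
  out$regional <- regional_adi(region, raw_scores, threshold_pct)
  out
}
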