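#' Diagnostic categories and their ICD-9 code ranges
#'
#' The major diagnostic categories used for hospitalization outcomes:
#' respiratory system (ICD-9 codes 460-519), circulatory system (390-459),
#' mental disorders (290-319), and total (all codes).
#'
#' @return Named list of inclusive integer code ranges; `total` is `"all"`.
#' @export
icd9_categories <- function() {
  list(total = "all",
       respiratory = c(460L, 519L),
       circulatory = c(390L, 459L),
       mental = c(290L, 319L))
}

#' Classify ICD-9 codes into major diagnostic categories
#'
#' A code is ranged by its 3-digit numeric root; suffixes after the root
#' (e.g. `"493.20"` -> 493) are ignored. V- and E-codes and unparseable
#' strings map to no named category, and by default are excluded from
#' `total` as well (set `include_ve_in_total = TRUE` to count them there).
#'
#' @param codes Character vector of ICD-9 codes.
#' @return Character vector: `"respiratory"`, `"circulatory"`, `"mental"`,
#'   or `NA` for codes in none of the named ranges. Use [icd9_in_total()]
#'   for membership in the `total` category.
#' @export
classify_icd9 <- function(codes) {
  root <- .icd9_root(codes)
  out <- rep(NA_character_, length(codes))
  out[!is.na(root) & root >= 460 & root <= 519] <- "respiratory"
  out[!is.na(root) & root >= 390 & root <= 459] <- "circulatory"
  out[!is.na(root) & root >= 290 & root <= 319] <- "mental"
  out
}

#' @rdname classify_icd9
#' @param include_ve_in_total Count V/E-codes toward `total`?
#' @export
icd9_in_total <- function(codes, include_ve_in_total = FALSE) {
  root <- .icd9_root(codes)
  if (include_ve_in_total) !is.na(.icd9_root(codes, allow_ve = TRUE)) else !is.na(root)
}

.icd9_root <- function(codes, allow_ve = FALSE) {
  codes <- trimws(as.character(codes))
  # 3-digit numeric root; V-codes carry 2 digits, E-codes 3
  pat <- if (allow_ve) "^([0-9]{3}|[Vv][0-9]{2}|[Ee][0-9]{3})" else "^[0-9]{3}"
  m <- regmatches(codes, regexpr(pat, codes))
  root <- rep(NA_integer_, length(codes))
  hit <- grepl(pat, codes)
  if (allow_ve) {
    root[hit] <- suppressWarnings(as.integer(gsub("[VvEe]", "", m)))
  } else {
    root[hit] <- as.integer(substr(codes[hit], 1, 3))
  }
  root
}

#' Validate an event table
#'
#' An event table has one row per (unit, age stratum, category, year) with
#' a non-negative count. Fractional counts are allowed only in averaged
#' tables (the output of [average_years()]).
#'
#' @param events Data frame with columns `unit_id`, `age_stratum`,
#'   `category`, `year`, `count`.
#' @return The validated data frame (invisibly usable in pipelines).
#' @export
validate_events <- function(events) {
  need <- c("unit_id", "age_stratum", "category", "year", "count")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols) > 0) {
    stop("event table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(events$count) || any(events$count < 0)) {
    stop("event counts must be non-negative and non-missing", call. = FALSE)
  }
  events
}

#' Average an event table over years
#'
#' Collapses multi-year counts to a single period by the arithmetic mean
#' over the listed years: count per (unit, stratum, category) = sum over
#' listed years / number of listed years, so a year with no row for a unit
#' contributes 0 (warned about). Fractional means are preserved.
#'
#' @param events An event table ([validate_events()]).
#' @param years Years to average over; default all years present.
#' @return Event table with a single period (`year = NA`) and fractional
#'   counts.
#' @export
average_years <- function(events, years = sort(unique(events$year))) {
  events <- validate_events(events)
  if (length(years) == 0) stop("`years` must name at least one year", call. = FALSE)
  ev <- events[events$year %in% years, , drop = FALSE]
  present <- unique(ev[c("unit_id", "year")])
  n_pairs <- length(unique(ev$unit_id)) * length(years)
  if (nrow(present) < n_pairs) {
    warning(n_pairs - nrow(present),
            " unit-year combination(s) absent from the event table; treated as 0 events",
            call. = FALSE)
  }
  agg <- stats::aggregate(count ~ unit_id + age_stratum + category, data = ev, FUN = sum)
  agg$count <- agg$count / length(years)
  agg$year <- NA_integer_
  agg[c("unit_id", "age_stratum", "category", "year", "count")]
}

#' Standard population stratum rates
#'
#' The reference rates for indirect age standardization: an event rate per
#' person-period for each age stratum of the standard population, plus the
#' standard population's crude rate.
#'
#' @param rates Named numeric vector of per-stratum event rates (names =
#'   age stratum labels, matching the region's `pop_<stratum>` suffixes).
#' @param crude_rate The standard population's crude event rate.
#' @return Object of class `standard_population`.
#' @export
standard_population <- function(rates, crude_rate) {
  if (is.null(names(rates)) || anyNA(rates) || any(rates < 0)) {
    stop("`rates` must be a named vector of non-negative stratum rates", call. = FALSE)
  }
  if (!is.numeric(crude_rate) || length(crude_rate) != 1 || crude_rate < 0) {
    stop("`crude_rate` must be a single non-negative number", call. = FALSE)
  }
  structure(list(rates = rates, crude_rate = crude_rate),
            class = "standard_population")
}

#' @export
print.standard_population <- function(x, ...) {
  cat("<standard_population> ", length(x$rates), " age strata, crude rate ",
      signif(x$crude_rate, 4), "\n", sep = "")
  invisible(x)
}

# Dense units x strata count matrix for one category, aligned to the
# region's population matrix (absent combinations are 0 events).
.event_matrix <- function(region, events, category) {
  ev <- events[events$category == category, , drop = FALSE]
  E <- matrix(0, n_units(region), ncol(region$pop),
              dimnames = dimnames(region$pop))
  if (nrow(ev) > 0) {
    unknown <- setdiff(unique(ev$unit_id), region$unit_id)
    if (length(unknown) > 0) {
      stop("event table names unknown unit(s): ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
    bad_strata <- setdiff(unique(ev$age_stratum), colnames(region$pop))
    if (length(bad_strata) > 0) {
      stop("event table names unknown age stratum(s): ",
           paste(utils::head(bad_strata, 3), collapse = ", "), call. = FALSE)
    }
    agg <- stats::aggregate(count ~ unit_id + age_stratum, data = ev, FUN = sum)
    E[cbind(as.character(agg$unit_id), as.character(agg$age_stratum))] <- agg$count
  }
  E
}

#' Indirect age standardization of area event rates
#'
#' For each unit, the expected event count is the sum over age strata of
#' the standard population's stratum rate times the unit's stratum
#' population. The standardized morbidity ratio (SMR) is observed /
#' expected, and the indirectly age-adjusted rate is SMR times the
#' standard crude rate.
#'
#' @param region A [study_region()].
#' @param events A single-period event table (pass multi-year tables
#'   through [average_years()] first).
#' @param std A [standard_population()] whose stratum labels match the
#'   region's.
#' @param category Diagnostic category to adjust; default `"total"`.
#' @return Data frame with columns `unit_id`, `category`, `observed`,
#'   `expected`, `smr`, `adjusted_rate`. `smr` is `NA` where expected and
#'   observed are both 0; expected 0 with observed > 0 is an error.
#' @export
indirect_adjust <- function(region, events, std, category = "total") {
  stopifnot(inherits(region, "study_region"), inherits(std, "standard_population"))
  events <- validate_events(events)
  if (length(unique(events$year)) > 1) {
    stop("event table spans multiple years; average with average_years() first",
         call. = FALSE)
  }
  missing_strata <- setdiff(colnames(region$pop), names(std$rates))
  if (length(missing_strata) > 0) {
    stop("standard population is missing stratum rate(s): ",
         paste(missing_strata, collapse = ", "), call. = FALSE)
  }
  E <- .event_matrix(region, events, category)
  observed <- rowSums(E)
  expected <- drop(region$pop %*% std$rates[colnames(region$pop)])
  bad <- expected == 0 & observed > 0
  if (any(bad)) {
    stop("expected events are 0 but observed > 0 for unit(s): ",
         paste(utils::head(region$unit_id[bad], 3), collapse = ", "), call. = FALSE)
  }
  smr <- ifelse(expected > 0, observed / expected, NA_real_)
  data.frame(unit_id = region$unit_id, category = category,
             observed = unname(observed), expected = unname(expected),
             smr = unname(smr), adjusted_rate = unname(smr * std$crude_rate),
             stringsAsFactors = FALSE)
}
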