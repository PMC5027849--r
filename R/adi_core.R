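#' The 17 census variables of the area deprivation index
#'
#' Canonical snake_case names for the 17 socioeconomic census variables
#' entering the ADI composite, grouped in four domains: education
#' (`pct_edu_lt9y`, `pct_edu_hs_plus`, `pct_white_collar`),
#' income/employment (`median_family_income`, `income_disparity`,
#' `pct_families_poverty`, `pct_below_150_poverty`, `pct_unemployed`),
#' housing (`median_home_value`, `median_gross_rent`, `median_mortgage`,
#' `pct_owner_occupied`, `pct_no_plumbing`) and household characteristics
#' (`pct_single_parent`, `pct_no_vehicle`, `pct_no_telephone`,
#' `pct_crowding`).
#'
#' @return Character vector of length 17.
#' @export
adi_variables <- function() names(.adi_directions)

# +1: larger value = more deprivation; -1: larger value = less deprivation.
.adi_directions <- c(
  pct_edu_lt9y          = 1,
  pct_edu_hs_plus       = -1,
  pct_white_collar      = -1,
  median_family_income  = -1,
  income_disparity      = 1,
  pct_families_poverty  = 1,
  pct_below_150_poverty = 1,
  pct_unemployed        = 1,
  median_home_value     = -1,
  median_gross_rent     = -1,
  median_mortgage       = -1,
  pct_owner_occupied    = -1,
  pct_no_plumbing       = 1,
  pct_single_parent     = 1,
  pct_no_vehicle        = 1,
  pct_no_telephone      = 1,
  pct_crowding          = 1
)

.adi_percent_vars <- c(
  "pct_edu_lt9y", "pct_edu_hs_plus", "pct_white_collar",
  "pct_families_poverty", "pct_below_150_poverty", "pct_unemployed",
  "pct_owner_occupied", "pct_no_plumbing", "pct_single_parent",
  "pct_no_vehicle", "pct_no_telephone", "pct_crowding"
)

.adi_currency_vars <- c(
  "median_family_income", "median_home_value", "median_gross_rent",
  "median_mortgage"
)

#' Deprivation direction of each ADI variable
#'
#' @return Named numeric vector over [adi_variables()]: `+1` where larger
#'   values indicate more deprivation, `-1` where larger values indicate
#'   less (income, education attainment, white-collar share, home value,
#'   rent, mortgage, owner occupancy).
#' @export
adi_directions <- function() .adi_directions

#' Construct and validate a weight vector for the ADI composite
#'
#' The composite is a weighted sum of direction-adjusted standardized
#' variables. The default is equal weights `1/17`: the published factor
#' loadings behind operational ADIs are not part of this package, and an
#' equal-weight composite on direction-adjusted z-scores is a reproducible
#' baseline. Supply published loadings here to change that.
#'
#' @param weights Named numeric vector covering exactly the 17 variables of
#'   [adi_variables()] (any order), or `NULL` for equal weights.
#' @return Named numeric vector in canonical variable order, class
#'   `adi_weights`.
#' @export
adi_weights <- function(weights = NULL) {
  vars <- adi_variables()
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(vars), length(vars)), vars)
  }
  if (is.null(names(weights)) || !setequal(names(weights), vars) ||
      length(weights) != length(vars)) {
    stop("`weights` must be a named vector covering exactly the 17 ADI variables; ",
         "see adi_variables()", call. = FALSE)
  }
  weights <- weights[vars]
  if (!is.numeric(weights) || anyNA(weights) || any(!is.finite(weights))) {
    stop("`weights` must be finite numeric values", call. = FALSE)
  }
  if (all(weights == 0)) stop("at least one weight must be nonzero", call. = FALSE)
  structure(weights, class = "adi_weights")
}

# Coerce a profile input (data.frame or matrix) to an n x 17 numeric matrix
# in canonical column order, with rownames from unit_id when available.
.as_profile_matrix <- function(profiles) {
  vars <- adi_variables()
  if (is.data.frame(profiles)) {
    missing_vars <- setdiff(vars, names(profiles))
    if (length(missing_vars) > 0) {
      stop("profile input is missing census variable column(s): ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(profiles[vars])
    if ("unit_id" %in% names(profiles)) rownames(m) <- as.character(profiles$unit_id)
  } else {
    m <- as.matrix(profiles)
    missing_vars <- setdiff(vars, colnames(m))
    if (length(missing_vars) > 0) {
      stop("profile input is missing census variable column(s): ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    m <- m[, vars, drop = FALSE]
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m
}

.validate_profile_ranges <- function(m) {
  for (v in intersect(colnames(m), .adi_percent_vars)) {
    bad <- which(m[, v] < 0 | m[, v] > 100)
    if (length(bad) > 0) {
      stop("percent variable '", v, "' outside [0, 100] for unit(s) ",
           paste(utils::head(rownames(m)[bad], 3), collapse = ", "), call. = FALSE)
    }
  }
  for (v in c(intersect(colnames(m), .adi_currency_vars), "income_disparity")) {
    bad <- which(m[, v] < 0)
    if (length(bad) > 0) {
      stop("variable '", v, "' negative for unit(s) ",
           paste(utils::head(rownames(m)[bad], 3), collapse = ", "), call. = FALSE)
    }
  }
  invisible(m)
}

#' Standardize the 17 census variables across a reference set of units
#'
#' Each variable is centered and scaled to mean 0, standard deviation 1
#' across units (population standard deviation, dividing by `n`, so the
#' result is a deterministic function of the input set), then multiplied by
#' its deprivation direction so that larger standardized values always mean
#' more deprivation. A zero-variance variable contributes 0 for every unit
#' (with a warning); a missing value is an error naming the unit and
#' variable.
#'
#' @param profiles Data frame or matrix with the 17 columns of
#'   [adi_variables()] (a `unit_id` column, if present, names the rows).
#' @return Numeric matrix, units x 17 variables, direction-adjusted
#'   z-scores.
#' @export
standardize_variables <- function(profiles) {
  m <- .as_profile_matrix(profiles)
  if (nrow(m) < 2) stop("standardization needs at least 2 units", call. = FALSE)
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx) > 0) {
    stop("missing value in variable '", colnames(m)[na_idx[1, 2]],
         "' for unit '", rownames(m)[na_idx[1, 1]], "'", call. = FALSE)
  }
  .validate_profile_ranges(m)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  zero_var <- sd_pop == 0
  if (any(zero_var)) {
    warning("zero-variance variable(s) contribute 0 to all scores: ",
            paste(colnames(m)[zero_var], collapse = ", "), call. = FALSE)
    sd_pop[zero_var] <- 1 # centered values are 0, so any divisor works
  }
  z <- sweep(sweep(m, 2, mu), 2, sd_pop, "/")
  sweep(z, 2, .adi_directions[colnames(z)], "*")
}

#' Compute raw ADI composite scores
#'
#' The raw score of a unit is the weighted sum of its direction-adjusted
#' standardized census variables; higher scores mean more deprivation. The
#' score is relative to the reference set supplied (the units over which
#' standardization is performed).
#'
#' @param profiles As in [standardize_variables()].
#' @param weights An [adi_weights()] vector (default: equal weights).
#' @return Named numeric vector of raw scores, one per unit.
#' @export
compute_raw_adi <- function(profiles, weights = adi_weights()) {
  weights <- adi_weights(unclass(weights))
  z <- standardize_variables(profiles)
  drop(z %*% as.numeric(weights[colnames(z)]))
}

#' Percentile rank of scores within a reference set
#'
#' `percentile(u) = 100 * #\{v : score(v) <= score(u)\} / n` (weak
#' inequality). Tied scores share the highest applicable percentile, and the
#' maximum score always has percentile 100; a region of all-equal scores
#' therefore puts every unit at percentile 100.
#'
#' @param scores Numeric vector, at least one finite value.
#' @return Numeric vector of percentiles in (0, 100], names preserved.
#' @export
percentile_rank <- function(scores) {
  if (length(scores) == 0) stop("cannot rank an empty score vector", call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite and non-missing", call. = FALSE)
  }
  100 * rank(scores, ties.method = "max") / length(scores)
}

#' Dichotomize an ADI percentile at a top-percentile threshold
#'
#' A unit is flagged as highly deprived when it lies strictly inside the top
#' `threshold_pct` percent of its reference set: `percentile > 100 -
#' threshold_pct` under the weak-inequality percentile of
#' [percentile_rank()]. With `n` unique scores this flags exactly
#' `floor(n * threshold_pct / 100)` units (15 of 100 at the default
#' threshold); all-equal scores all sit at percentile 100 and are all
#' flagged.
#'
#' @param percentile Numeric vector of percentiles in (0, 100].
#' @param threshold_pct Top-percent cut in (0, 100); default 15.
#' @return Logical vector: `TRUE` = high deprivation.
#' @export
dichotomize <- function(percentile, threshold_pct = 15) {
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1 ||
      is.na(threshold_pct) || threshold_pct <= 0 || threshold_pct >= 100) {
    stop("`threshold_pct` must be a single value in (0, 100)", call. = FALSE)
  }
  if (anyNA(percentile) || any(percentile <= 0 | percentile > 100)) {
    stop("`percentile` values must lie in (0, 100]", call. = FALSE)
  }
  percentile > 100 - threshold_pct
}
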