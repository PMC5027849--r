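.z_alpha <- function(alpha) stats::qnorm(1 - alpha / 2)

.or_result <- function(estimate, ci_low, ci_high, alpha, method,
                       n_strata, n_informative) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 alpha = alpha, method = method, n_strata = n_strata,
                 n_informative_strata = n_informative),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR = %.4g (%g%% CI %.4g-%.4g), method = %s, strata = %d (%d informative)\n",
              x$estimate, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
              x$method, x$n_strata, x$n_informative_strata))
  invisible(x)
}

#' Crude odds ratio of a single 2x2 table
#'
#' Estimate `ad / bc` with a Haldane-Anscombe correction (0.5 added to
#' every cell) applied if and only if some cell is zero; Wald confidence
#' interval on the log scale from the possibly-corrected cells.
#'
#' @param table 2x2 matrix `rbind(c(a, b), c(c, d))` or length-4 vector
#'   `c(a, b, c, d)`: a = exposed events, b = exposed non-events, c =
#'   unexposed events, d = unexposed non-events.
#' @param alpha Two-sided error rate; default 0.05 (95% CI).
#' @return An `or_result`: `estimate`, `ci_low`, `ci_high`, `alpha`,
#'   `method = "crude"`, stratum counts.
#' @export
crude_or <- function(table, alpha = 0.05) {
  cells <- as.numeric(table)
  if (length(cells) != 4 || anyNA(cells) || any(cells < 0)) {
    stop("`table` must be 4 non-negative cells (a, b, c, d)", call. = FALSE)
  }
  if (any(cells == 0)) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  est <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- .z_alpha(alpha)
  .or_result(est, est * exp(-z * se), est * exp(z * se), alpha, "crude", 1L, 1L)
}

#' Mantel-Haenszel odds ratio over age strata
#'
#' The age-adjusted (stratified) odds ratio: `OR_MH = sum(a_i d_i / n_i) /
#' sum(b_i c_i / n_i)` over informative strata, with the
#' Robins-Breslow-Greenland variance of `log(OR_MH)` for the confidence
#' interval. A stratum is informative when it contributes to either sum
#' (`a_i d_i + b_i c_i > 0`); non-informative strata are skipped and
#' counted. A zero denominator with a positive numerator yields an
#' infinite estimate with `ci_high = Inf`.
#'
#' @param strata Data frame (or matrix) with columns `a`, `b`, `c`, `d` —
#'   one row per age stratum, cells as in [crude_or()]. The output of
#'   [build_strata()].
#' @param alpha Two-sided error rate; default 0.05.
#' @return An `or_result` with `method = "mantel_haenszel"`.
#' @export
mh_or <- function(strata, alpha = 0.05) {
  strata <- as.data.frame(strata)
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(strata))) {
    stop("`strata` needs columns a, b, c, d", call. = FALSE)
  }
  a <- as.numeric(strata$a); b <- as.numeric(strata$b)
  cc <- as.numeric(strata$c); d <- as.numeric(strata$d)
  if (anyNA(c(a, b, cc, d)) || any(c(a, b, cc, d) < 0)) {
    stop("all stratum cells must be non-negative and non-missing", call. = FALSE)
  }
  n <- a + b + cc + d
  Ri <- ifelse(n > 0, a * d / n, 0)
  Si <- ifelse(n > 0, b * cc / n, 0)
  informative <- Ri + Si > 0
  k_inf <- sum(informative)
  if (k_inf == 0) stop("no informative stratum (every a*d + b*c is 0)", call. = FALSE)
  R <- sum(Ri[informative]); S <- sum(Si[informative])
  z <- .z_alpha(alpha)
  if (S == 0) {
    return(.or_result(Inf, NA_real_, Inf, alpha, "mantel_haenszel",
                      nrow(strata), k_inf))
  }
  if (R == 0) {
    return(.or_result(0, 0, NA_real_, alpha, "mantel_haenszel",
                      nrow(strata), k_inf))
  }
  est <- R / S
  Pi <- ((a + d) / n)[informative]
  Qi <- ((b + cc) / n)[informative]
  ri <- Ri[informative]; si <- Si[informative]
  v <- sum(Pi * ri) / (2 * R^2) + sum(Pi * si + Qi * ri) / (2 * R * S) +
    sum(Qi * si) / (2 * S^2)
  se <- sqrt(v)
  .or_result(est, est * exp(-z * se), est * exp(z * se), alpha,
             "mantel_haenszel", nrow(strata), k_inf)
}

#' Assemble age-stratified 2x2 tables from unit flags and events
#'
#' The ecological exposure is the unit-level deprivation flag; the outcome
#' is whether a person was hospitalized within the (single, averaged)
#' period. For each age stratum the exposed events `a` sum the events of
#' flagged units, exposed non-events `b` their remaining population, and
#' `c`, `d` likewise over unflagged units. Averaged fractional event
#' counts are rounded half-up to integers first; a count exceeding its
#' stratum population is capped with a warning. Units with an
#' indeterminate (`NA`) flag contribute to neither arm; their number is
#' recorded in the `n_excluded_units` attribute.
#'
#' @param region A [study_region()].
#' @param flags Per-unit logical exposure flags (named by unit id, or in
#'   region order; `NA` = indeterminate), e.g. the `flag` column of
#'   [local_adi()] / [regional_adi()].
#' @param events A single-period event table (see [average_years()]).
#' @param category Diagnostic category; default `"total"`.
#' @return Data frame with columns `stratum`, `a`, `b`, `c`, `d`,
#'   attribute `n_excluded_units`.
#' @export
build_strata <- function(region, flags, events, category = "total") {
  stopifnot(inherits(region, "study_region"))
  events <- validate_events(events)
  if (length(unique(events$year)) > 1) {
    stop("event table spans multiple years; average with average_years() first",
         call. = FALSE)
  }
  flags <- .align_flags(region, flags)
  E <- round_half_up(.event_matrix(region, events, category))
  over <- E > region$pop
  if (any(over)) {
    warning(sum(over), " (unit, stratum) event count(s) exceed population; capped",
            call. = FALSE)
    E[over] <- region$pop[over]
  }
  keep <- !is.na(flags)
  n_excluded <- sum(!keep)
  exp_idx <- keep & flags
  une_idx <- keep & !flags
  a <- colSums(E[exp_idx, , drop = FALSE])
  b <- colSums(region$pop[exp_idx, , drop = FALSE]) - a
  cc <- colSums(E[une_idx, , drop = FALSE])
  d <- colSums(region$pop[une_idx, , drop = FALSE]) - cc
  out <- data.frame(stratum = colnames(region$pop), a = unname(a),
                    b = unname(b), c = unname(cc), d = unname(d),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded_units") <- n_excluded
  out
}

.align_flags <- function(region, flags) {
  n <- n_units(region)
  if (is.null(names(flags))) {
    if (length(flags) != n) stop("flags must cover all ", n, " units", call. = FALSE)
    names(flags) <- region$unit_id
    return(flags)
  }
  missing_ids <- setdiff(region$unit_id, names(flags))
  if (length(missing_ids) > 0) {
    stop("flags missing unit(s): ",
         paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  flags[region$unit_id]
}

#' Logistic-regression odds ratio over strata (cross-check utility)
#'
#' Maximum-likelihood odds ratio for the exposure from a grouped binomial
#' logistic fit with stratum indicators — an independent cross-check on
#' [mh_or()]; both estimate the common odds ratio under homogeneity.
#'
#' @inheritParams mh_or
#' @return An `or_result` with `method = "logistic"` (Wald CI from the
#'   fit's standard error).
#' @export
logistic_or <- function(strata, alpha = 0.05) {
  strata <- as.data.frame(strata)
  keep <- with(strata, (a + b) > 0 & (c + d) > 0)
  s <- strata[keep, , drop = FALSE]
  if (nrow(s) == 0) stop("no stratum with both arms populated", call. = FALSE)
  dat <- data.frame(
    events = c(s$a, s$c), nonevents = c(s$b, s$d),
    exposed = rep(c(1, 0), each = nrow(s)),
    stratum = factor(rep(seq_len(nrow(s)), 2)))
  fit <- stats::glm(cbind(events, nonevents) ~ exposed + stratum,
                    family = stats::binomial(), data = dat)
  beta <- stats::coef(fit)["exposed"]
  se <- sqrt(stats::vcov(fit)["exposed", "exposed"])
  z <- .z_alpha(alpha)
  .or_result(unname(exp(beta)), unname(exp(beta - z * se)),
             unname(exp(beta + z * se)), alpha, "logistic",
             nrow(strata), nrow(s))
}

#' Odds ratios of one outcome across calibration scales
#'
#' Runs the full validation comparison for one diagnostic category:
#' deprivation flags at each local radius and at the regional scale
#' (identical events and outcome definition throughout), each related to
#' the hospitalization outcome by a Mantel-Haenszel age-stratified odds
#' ratio.
#'
#' @inheritParams adi_by_scale
#' @param events A single-period event table.
#' @param category Diagnostic category; default `"total"`.
#' @param alpha Two-sided error rate for the CIs; default 0.05.
#' @return Data frame, one row per scale: `scale`, `category`, `estimate`,
#'   `ci_low`, `ci_high`, `n_strata`, `n_informative_strata`,
#'   `n_excluded_units`.
#' @export
compare_scales <- function(region, raw_scores, events, category = "total",
                           radii = c(10, 20, 30), threshold_pct = 15,
                           min_window = 10, alpha = 0.05, dist = NULL) {
  calib <- adi_by_scale(region, raw_scores, radii, threshold_pct,
                        min_window, dist = dist)
  rows <- lapply(names(calib), function(scale) {
    flags <- stats::setNames(calib[[scale]]$flag, calib[[scale]]$unit_id)
    strata <- build_strata(region, flags, events, category)
    or <- mh_or(strata, alpha)
    data.frame(scale = scale, category = category, estimate = or$estimate,
               ci_low = or$ci_low, ci_high = or$ci_high,
               n_strata = or$n_strata,
               n_informative_strata = or$n_informative_strata,
               n_excluded_units = attr(strata, "n_excluded_units"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
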