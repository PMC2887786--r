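## Indirect standardization: stratum-specific reference rates, expected
## counts E_i as the dot product of each area's stratified population
## with those rates, standardized incidence ratios SIR_i = Y_i / E_i,
## and exact Poisson (gamma-quantile) confidence intervals.  Exact
## intervals are used because counts at small-area scale are far too
## small for normal approximations.

#' Estimate reference rates from a pooled stratum table
#'
#' Pools persons and cases over areas per stratum key and returns
#' rate = total cases / total persons.  When the rates are re-estimated
#' from the study's own pooled data ("internal standardization"), the
#' expected counts later satisfy sum(E) == sum(Y) exactly.
#'
#' @param ref_table a stratum table (`area_id, age_band, sex,
#'   [income_quintile,] population, cases`).
#' @param by stratum key columns; defaults to `age_band`, `sex`, plus
#'   `income_quintile` if present.
#' @return A rate-vector data.frame (`by` columns plus `rate`).
#' @export
estimate_reference_rates <- function(ref_table, by = NULL) {
  if (is.null(by)) {
    by <- intersect(c("age_band", "sex", "income_quintile"),
                    names(ref_table))
    by <- by[vapply(by, function(cl) !all(is.na(ref_table[[cl]])), TRUE)]
  }
  if (nrow(ref_table) == 0L) {
    out <- ref_table[, by, drop = FALSE]
    out$rate <- numeric(0)
    return(out)
  }
  agg <- aggregate(ref_table[, c("population", "cases")],
                   ref_table[, by, drop = FALSE], sum)
  bad <- agg$population == 0 & agg$cases > 0
  if (any(bad)) stop("stratum with cases but zero population")
  zero <- agg$population == 0
  agg$rate <- ifelse(zero, 0, agg$cases / ifelse(zero, 1, agg$population))
  if (any(zero))
    warning(sum(zero), " stratum/strata with zero population given rate 0")
  agg[, c(by, "rate")]
}

#' Expected counts per area
#'
#' E_i = sum over strata of persons x reference rate.  When the rate
#' vector is income-stratified, the expectation adjusts for income as
#' well as age and sex, so spatial patterns driven by the income
#' gradient are absorbed into E rather than showing up in the SIRs.
#'
#' @param pop_table stratum table with `population` (a `cases` column,
#'   if present, is ignored here).
#' @param rates rate-vector data.frame.
#' @param strict if `TRUE` (default) a stratum key missing from `rates`
#'   is an error; otherwise it is imputed rate 0 with a warning.
#' @return Named numeric vector of E_i, names = area IDs (in first
#'   appearance order).
#' @export
expected_counts <- function(pop_table, rates, strict = TRUE) {
  r <- match_stratum_rates(pop_table, rates, strict = strict)
  e <- tapply(pop_table$population * r, pop_table$area_id, sum)
  ids <- unique(pop_table$area_id)
  out <- as.numeric(e[ids])
  names(out) <- ids
  out
}

#' Observed counts per area
#' @param tab stratum table with `cases`.
#' @return Named integer vector of Y_i.
#' @export
observed_counts <- function(tab) {
  y <- tapply(tab$cases, tab$area_id, sum)
  ids <- unique(tab$area_id)
  out <- as.integer(y[ids])
  names(out) <- ids
  out
}

#' Standardized incidence ratios
#'
#' SIR_i = Y_i / E_i.  Areas with E = 0 and Y = 0 (unpopulated areas)
#' are retained but flagged `excluded` with an undefined (NA) SIR; E = 0
#' with Y > 0 is impossible under the model and raises an error.
#'
#' @param Y named integer vector of observed counts.
#' @param E numeric vector of expected counts (same order/names).
#' @param level confidence level for the exact intervals.
#' @return An `area_risk` data.frame: `area_id, observed, expected, sir,
#'   ci_low, ci_high, excluded`.
#' @export
compute_sir <- function(Y, E, level = 0.95) {
  if (length(Y) != length(E)) stop("Y and E lengths differ")
  if (any(Y < 0) || any(Y != floor(Y))) stop("Y must be integers >= 0")
  if (any(E < 0)) stop("E must be >= 0")
  if (any(E == 0 & Y > 0)) stop("observed cases in an area with E = 0")
  ids <- names(Y)
  if (is.null(ids)) ids <- as.character(seq_along(Y))
  excluded <- E == 0
  sir <- ifelse(excluded, NA_real_, Y / ifelse(excluded, 1, E))
  lo <- hi <- rep(NA_real_, length(Y))
  ok <- !excluded
  if (any(ok)) {
    ci <- sir_confidence_interval(Y[ok], E[ok], level)
    lo[ok] <- ci[, 1]
    hi[ok] <- ci[, 2]
  }
  structure(data.frame(area_id = ids, observed = as.integer(Y),
                       expected = as.numeric(E), sir = sir, ci_low = lo,
                       ci_high = hi, excluded = excluded,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("area_risk", "data.frame"))
}

#' Exact Poisson interval for an SIR
#'
#' The exact (gamma-quantile) interval for a Poisson mean, divided by E:
#' `low = qgamma(a/2, Y)/E` (0 when Y = 0) and
#' `high = qgamma(1 - a/2, Y + 1)/E`.
#'
#' @param Y observed counts (vectorized).
#' @param E expected counts, all > 0.
#' @param level confidence level in (0, 1).
#' @return Two-column matrix (low, high).
#' @export
sir_confidence_interval <- function(Y, E, level = 0.95) {
  if (any(E <= 0)) stop("E must be > 0 for an interval")
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  a <- 1 - level
  lo <- ifelse(Y == 0, 0, qgamma(a / 2, pmax(Y, 1)) / E)
  hi <- qgamma(1 - a / 2, Y + 1) / E
  cbind(low = as.numeric(lo), high = as.numeric(hi))
}

#' Combined SIR over a subset of areas
#'
#' Sums Y and E over the subset and recomputes the SIR and exact
#' interval.  With `reference = "complement"` the expected counts are
#' rescaled by the complement's own Y/E, giving the "relative to the
#' remainder of the study region" reading used when reporting clusters.
#'
#' @param risk an `area_risk` table.
#' @param subset character IDs (or logical/integer index) of the areas
#'   to combine.
#' @param level confidence level.
#' @param reference `"external"` (rates as given) or `"complement"`.
#' @return One-row data.frame `observed, expected, sir, ci_low, ci_high`.
#' @export
aggregate_sir <- function(risk, subset, level = 0.95,
                          reference = c("external", "complement")) {
  reference <- match.arg(reference)
  if (is.character(subset)) subset <- risk$area_id %in% subset
  if (is.numeric(subset)) subset <- seq_len(nrow(risk)) %in% subset
  if (!any(subset)) stop("empty area subset")
  Yz <- sum(risk$observed[subset])
  Ez <- sum(risk$expected[subset])
  if (reference == "complement") {
    Yc <- sum(risk$observed[!subset])
    Ec <- sum(risk$expected[!subset])
    if (Ec <= 0 || Yc <= 0)
      stop("complement has no cases/expectation to serve as reference")
    Ez <- Ez * (Yc / Ec)
  }
  if (Ez <= 0) stop("subset has zero expected count")
  ci <- sir_confidence_interval(Yz, Ez, level)
  data.frame(observed = Yz, expected = Ez, sir = Yz / Ez,
             ci_low = ci[1, 1], ci_high = ci[1, 2])
}

#' Standardize a study end to end
#'
#' Convenience wrapper: expected counts from the given (or internally
#' re-estimated) rates, observed counts, SIRs and intervals.
#'
#' @param strata stratum table with `population` and `cases`.
#' @param rates reference rate vector; `NULL` re-estimates internally
#'   from the pooled table.
#' @param level confidence level.
#' @return An `area_risk` table.
#' @export
standardize_study <- function(strata, rates = NULL, level = 0.95) {
  if (is.null(rates)) rates <- estimate_reference_rates(strata)
  E <- expected_counts(strata, rates)
  Y <- observed_counts(strata)
  compute_sir(Y, E[names(Y)], level)
}

#' Write an area risk table as CSV
#' @param risk an `area_risk` table.
#' @param path file path.
#' @return The input, invisibly.
#' @export
write_area_risk <- function(risk, path) {
  write.csv(risk, path, row.names = FALSE)
  invisible(risk)
}
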