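#' Residual life expectancy at an exact age
#'
#' Linear interpolation of an abridged residual-life-expectancy table,
#' constant beyond its ends.
#'
#' @param life_table data frame with `age` and `residual_le` columns.
#' @param age exact age(s) in years.
#' @return residual life expectancy in years.
#' @export
life_expectancy_at <- function(life_table, age) {
  approx(life_table$age, life_table$residual_le, xout = age, rule = 2)$y
}

# Midpoint age of a band; an open-ended band is closed at 85 for the
# purpose of residual-life-expectancy lookup.
.stratum_midpoint <- function(age_lo, age_hi, open_end_cap = 85) {
  hi <- ifelse(is.na(age_hi), open_end_cap - 1, age_hi)
  (age_lo + hi + 1) / 2
}

#' Total (all-cause-of-exposure) burden of one condition in one stratum
#'
#' Converts per-100,000 rates into stratum counts and burden:
#' * incident cases = incidence rate x population / 1e5 (deaths likewise
#'   from the mortality rate, prevalent cases from the prevalence rate);
#' * `events` reports incident or prevalent cases according to the
#'   condition's `events_basis`;
#' * YLD = prevalent cases x disability weight;
#' * YLL = deaths x residual life expectancy at the stratum midpoint age;
#' * DALYs = YLD + YLL;
#' * cost = incident cases x first-year cost + prevalent cases x annual
#'   cost (local currency units as supplied).
#'
#' @param epi one row of the disease-epidemiology table.
#' @param stratum one row of the population table (`sex`, `age_lo`,
#'   `age_hi`, `population`).
#' @param life_table residual life expectancy table (see
#'   [life_expectancy_at()]).
#' @return one-row tibble with `incident_cases`, `prevalent_cases`,
#'   `events`, `deaths`, `ylds`, `ylls`, `dalys`, `cost`.
#' @export
total_burden <- function(epi, stratum, life_table) {
  mid <- .stratum_midpoint(stratum$age_lo, stratum$age_hi)
  le <- life_expectancy_at(life_table, mid)
  if (is.na(le)) .validation_error("life table does not cover age ", mid)
  scale <- stratum$population / 1e5
  incident <- epi$incidence_rate * scale
  prevalent <- epi$prevalence_rate * scale
  deaths <- epi$mortality_rate * scale
  ylds <- prevalent * epi$disability_weight
  ylls <- deaths * le
  tibble::tibble(
    incident_cases = incident,
    prevalent_cases = prevalent,
    events = if (identical(epi$events_basis, "prevalent")) prevalent else incident,
    deaths = deaths,
    ylds = ylds,
    ylls = ylls,
    dalys = ylds + ylls,
    cost = incident * epi$cost_incident + prevalent * epi$cost_prevalent
  )
}

#' Apply attributable fractions to burden totals
#'
#' Attribution is linear: each attributable quantity is its PAF times the
#' corresponding total.  Case-driven quantities (events, YLDs, costs) use
#' the events PAF; death-driven quantities (deaths, YLLs) use the deaths
#' PAF.  DALYs are rebuilt as attributable YLD + attributable YLL.
#'
#' @param totals a row produced by [total_burden()].
#' @param paf_events attributable fraction for cases (proportion).
#' @param paf_deaths attributable fraction for deaths; defaults to
#'   `paf_events` (the single-RR assumption used for diabetes).
#' @return one-row tibble of attributable `events`, `deaths`, `ylds`,
#'   `ylls`, `dalys`, `cost`.
#' @export
attribute_burden <- function(totals, paf_events, paf_deaths = paf_events) {
  tibble::tibble(
    events = paf_events * totals$events,
    deaths = paf_deaths * totals$deaths,
    ylds = paf_events * totals$ylds,
    ylls = paf_deaths * totals$ylls,
    dalys = paf_events * totals$ylds + paf_deaths * totals$ylls,
    cost = paf_events * totals$cost
  )
}

#' Convert local-currency amounts to US dollars
#'
#' @param amount local currency units; passed through unchanged when the
#'   economics table flags costs as already being in USD.
#' @param economics one-row economics table with `exchange_rate` (local
#'   currency per USD) and `cost_unit`.
#' @return amount in USD.
#' @export
convert_currency <- function(amount, economics) {
  if (economics$exchange_rate <= 0) .validation_error("exchange_rate must be > 0")
  unit <- economics$cost_unit
  if (is.null(unit)) unit <- "local"
  if (identical(unit, "USD")) amount else amount / economics$exchange_rate
}
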