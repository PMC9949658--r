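#' Exposure distributions
#'
#' The attributable-fraction machinery works on a discrete exposure
#' distribution over SSB intake (240 ml servings/day): either a point mass
#' at a stratum mean, or a weighted sample of individual-level intakes.
#'
#' @param x servings/day for the point mass.
#' @return an `ssb_exposure` object.
#' @export
exposure_point <- function(x) {
  exposure_sample(values = x, weights = 1, representation = "point_mass")
}

#' @rdname exposure_point
#' @param values servings/day values (all `>= 0`).
#' @param weights probability weights; must be non-negative and sum to 1
#'   (normalized counts are accepted and renormalized).
#' @param representation label, `"point_mass"` or `"sample"`.
#' @export
exposure_sample <- function(values, weights = NULL,
                            representation = c("sample", "point_mass")) {
  representation <- match.arg(representation)
  if (length(values) == 0) stop("exposure must contain at least one value")
  if (any(values < 0)) stop("exposure values must be >= 0")
  if (is.null(weights)) weights <- rep(1 / length(values), length(values))
  if (length(weights) != length(values) || any(weights < 0)) {
    stop("weights must be non-negative and match values")
  }
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) weights <- weights / s
  structure(list(representation = representation, values = values, weights = weights),
            class = "ssb_exposure")
}

#' Relative risk at a given dose
#'
#' Scales a per-serving relative risk to an arbitrary daily intake.  The
#' default dose-response is log-linear, `theta^x`, consistent with
#' meta-analytic RRs reported "per one serving/day"; a linear alternative
#' `1 + (theta - 1) * x` is available for sensitivity analysis.
#'
#' @param theta relative risk per serving/day (`> 0`).
#' @param x intake, servings/day (`>= 0`).
#' @param dose_response `"exponential"` (default) or `"linear"`.
#' @return dimensionless relative risk at dose `x`.
#' @examples
#' rr_at_dose(1.37, 1)   # 1.37
#' rr_at_dose(1.08, 2)   # 1.1664
#' @export
rr_at_dose <- function(theta, x, dose_response = c("exponential", "linear")) {
  dose_response <- match.arg(dose_response)
  if (any(theta <= 0)) stop("theta must be > 0")
  if (any(x < 0)) stop("dose must be >= 0")
  switch(dose_response,
         exponential = theta^x,
         linear = 1 + (theta - 1) * x)
}

#' Population attributable fraction for a distributed exposure
#'
#' `PAF = 1 - 1 / E[RR(X)]`, where the expectation of the dose-specific
#' relative risk runs over the exposure distribution.  This is the standard
#' continuous-exposure attributable fraction against a counterfactual of
#' zero intake: with all mass at `x = 0` the mean RR is 1 and the PAF is 0.
#'
#' Point estimates with `theta >= 1` always lie in `[0, 1)`.  A `theta < 1`
#' (which can arise when sampling the RR inside a Monte Carlo run) yields a
#' negative PAF; with `truncate = TRUE` (the default, intended for point
#' estimates) the value is capped at 0 with a warning, while Monte Carlo
#' propagation keeps the negative draw to avoid biasing intervals.
#'
#' @inheritParams rr_at_dose
#' @param exposure an `ssb_exposure` object (see [exposure_point()]).
#' @param truncate cap negative values at zero (point-estimate behaviour)?
#' @return attributable fraction (proportion).
#' @examples
#' paf(exposure_point(1), 1.37)  # 1 - 1/1.37 = 0.27007
#' @export
paf <- function(exposure, theta, dose_response = c("exponential", "linear"),
                truncate = TRUE) {
  stopifnot(inherits(exposure, "ssb_exposure"))
  dose_response <- match.arg(dose_response)
  mean_rr <- sum(exposure$weights *
                   rr_at_dose(theta, exposure$values, dose_response))
  out <- 1 - 1 / mean_rr
  if (out < 0 && truncate) {
    warning("theta < 1 produced a negative PAF; capped at 0")
    out <- 0
  }
  out
}

#' Direct-pathway PAF table
#'
#' Computes one attributable fraction per (disease, adult stratum, outcome)
#' for every direct risk function.  Diabetes carries a single per-serving RR
#' assumed to act identically on incident cases, prevalent cases and
#' deaths; cardiovascular conditions carry separate RRs for
#' incidence/prevalence and for mortality.  Rows with `outcome = "all"`
#' expand to both the `events` and `deaths` outcomes.
#'
#' @param inputs an `ssb_inputs` object.
#' @param consumption_override optional named vector (stratum id ->
#'   servings/day) replacing the stratum means, used by the Monte Carlo
#'   engine.
#' @param rr_override optional named vector (`disease.outcome` ->
#'   sampled RR) replacing the point RRs.
#' @param dose_response see [rr_at_dose()].
#' @param truncate see [paf()].
#' @return a tibble (`disease`, `sex`, `age_lo`, `age_hi`, `outcome`,
#'   `paf`) with `outcome` in `events`/`deaths`; exportable as a delimited
#'   table.
#' @export
paf_table_direct <- function(inputs, consumption_override = NULL,
                             rr_override = NULL,
                             dose_response = c("exponential", "linear"),
                             truncate = TRUE) {
  dose_response <- match.arg(dose_response)
  rf <- inputs$risk_functions[inputs$risk_functions$pathway == "direct", ]
  cons <- inputs$consumption[inputs$consumption$age_lo >= 18, ]
  if (nrow(cons) == 0) .validation_error("no adult consumption strata available")
  ids <- stratum_id(cons$sex, cons$age_lo, cons$age_hi)
  x <- cons$mean_servings
  if (!is.null(consumption_override)) x <- unname(consumption_override[ids])
  if (anyNA(x)) .validation_error("missing consumption for a stratum")

  rows <- lapply(seq_len(nrow(rf)), function(i) {
    outcomes <- switch(rf$outcome[i],
                       all = c("events", "deaths"),
                       incidence = "events",
                       mortality = "deaths")
    theta <- rf$rr_per_unit[i]
    key <- paste(rf$disease[i], rf$outcome[i], sep = ".")
    if (!is.null(rr_override) && key %in% names(rr_override)) {
      theta <- unname(rr_override[key])
    }
    pafs <- vapply(x, function(xi) {
      paf(exposure_point(xi), theta, dose_response, truncate = truncate)
    }, numeric(1))
    tidyr::expand_grid(
      tibble::tibble(disease = rf$disease[i]),
      outcome = outcomes
    ) |>
      dplyr::cross_join(
        tibble::tibble(sex = cons$sex, age_lo = cons$age_lo,
                       age_hi = cons$age_hi, paf = pafs)
      )
  })
  out <- dplyr::bind_rows(rows)
  out[, c("disease", "sex", "age_lo", "age_hi", "outcome", "paf")]
}
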