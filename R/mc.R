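#' Monte Carlo configuration
#'
#' @param n_iter iterations (published analysis uses 1000).
#' @param seed RNG seed; a fixed seed makes the run bitwise-reproducible.
#' @param rr_sampling sampling law for relative risks: `"normal"` (the
#'   published choice, standard deviation `(ci_hi - ci_lo)/3.92`) or
#'   `"lognormal"` (the epidemiologically conventional alternative, same
#'   construction on the log scale).
#' @param sample_bmi_deltas also sample the per-serving BMI shift
#'   coefficients from their confidence bounds? Default off.
#' @param dose_response see [rr_at_dose()].
#' @param n_points BMI support points per stratum.
#' @return an `ssb_mc_config` list.
#' @export
mc_config <- function(n_iter = 1000, seed = 1L,
                      rr_sampling = c("normal", "lognormal"),
                      sample_bmi_deltas = FALSE,
                      dose_response = c("exponential", "linear"),
                      n_points = 2000) {
  stopifnot(n_iter >= 1)
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 rr_sampling = match.arg(rr_sampling),
                 sample_bmi_deltas = isTRUE(sample_bmi_deltas),
                 dose_response = match.arg(dose_response),
                 n_points = n_points),
            class = "ssb_mc_config")
}

# one draw per delta from its 95% bounds, floored at 0
.draw_effect <- function(effect) {
  draw1 <- function(mean, ci) max(0, rnorm(1, mean, (ci[2] - ci[1]) / 3.92))
  bmi_effect_model(
    delta_low = draw1(effect$delta_low, effect$ci_low),
    delta_high = draw1(effect$delta_high, effect$ci_high),
    delta_child = draw1(effect$delta_child, effect$ci_child)
  )
}

#' Monte Carlo uncertainty propagation
#'
#' Repeats the deterministic pipeline `n_iter` times with sampled inputs
#' and summarizes each reporting cell by its iteration mean and percentile
#' 2.5/97.5 interval.  Per iteration:
#'
#' * each relative risk is drawn once and shared across all strata (the RR
#'   is a global parameter), normal with `sd = (ci_hi - ci_lo)/3.92` by
#'   default, floored at `1e-6`;
#' * stratum consumption means are drawn independently,
#'   `N(mean, se)` truncated below at 0;
#' * optionally the BMI-shift coefficients are drawn from their bounds.
#'
#' Negative attributable fractions arising from RR draws below 1 are
#' retained (not truncated) so the intervals are not biased upward.
#'
#' @param inputs an `ssb_inputs` object; every sampled parameter must carry
#'   its uncertainty (`se_servings`; `ci_lo`/`ci_hi`), otherwise a
#'   validation error is raised.
#' @param config an [mc_config()].
#' @return an `ssb_mc_result`: tibble with `condition_group`, `sex`,
#'   `measure`, the deterministic point `estimate`, the iteration
#'   `mc_mean`, percentile bounds `ci_lo`/`ci_hi`, and the all-cause
#'   `total`; both-sex and all-condition rows are summed within each
#'   iteration before taking percentiles.  Attributes: `config`, and
#'   `draws` (the per-iteration aggregated matrix) for audit/trace export.
#' @export
run_mc <- function(inputs, config = mc_config()) {
  rf <- inputs$risk_functions
  if (anyNA(rf$ci_lo) || anyNA(rf$ci_hi)) {
    .validation_error("risk_functions: every sampled RR needs ci_lo/ci_hi")
  }
  if (anyNA(inputs$consumption$se_servings)) {
    .validation_error("consumption: every stratum needs se_servings")
  }
  model <- prepare_model(inputs, n_points = config$n_points,
                         dose_response = config$dose_response)

  point_eval <- evaluate_model(model)
  base_point <- aggregate_results(point_eval, model$economics)
  key <- paste(base_point$condition_group, base_point$sex, base_point$measure,
               sep = "|")
  model$.agg <- .agg_bookkeeping(model)
  usd_scale <- convert_currency(1, model$economics) / 1e6

  rr_mean <- model$risk_functions$rr_per_unit
  rr_sd <- (model$risk_functions$ci_hi - model$risk_functions$ci_lo) / 3.92
  rr_keys <- model$risk_functions$key
  serv_mean <- model$strata$mean_servings
  serv_se <- model$strata$se_servings
  ids <- model$strata$id

  set.seed(config$seed)
  draws_mat <- matrix(NA_real_, nrow = length(key), ncol = config$n_iter,
                      dimnames = list(key, NULL))
  for (it in seq_len(config$n_iter)) {
    rr_draw <- switch(config$rr_sampling,
      normal = rnorm(length(rr_mean), rr_mean, rr_sd),
      lognormal = rlnorm(length(rr_mean), log(rr_mean),
                         (log(model$risk_functions$ci_hi) -
                            log(model$risk_functions$ci_lo)) / 3.92)
    )
    rr_draw <- pmax(rr_draw, 1e-6)
    serv_draw <- pmax(rnorm(length(serv_mean), serv_mean, serv_se), 0)
    effect <- if (config$sample_bmi_deltas) .draw_effect(model$effect) else model$effect
    core <- .evaluate_core(model, servings = serv_draw,
                           rr = setNames(rr_draw, rr_keys),
                           effect = effect, truncate = FALSE)
    vals <- .fast_aggregate(core, model, usd_scale)
    draws_mat[, it] <- vals[key]
  }

  completed_point <- aggregate_attributable(base_point)
  # per-iteration completion (both-sex and total rows summed within
  # iteration) so interval bounds respect cross-cell correlation
  comp_key <- paste(completed_point$condition_group, completed_point$sex,
                    completed_point$measure, sep = "|")
  member <- .completion_members(base_point, completed_point)
  comp_draws <- do.call(rbind, lapply(member, function(idx) {
    colSums(draws_mat[idx, , drop = FALSE])
  }))
  out <- tibble::tibble(
    condition_group = completed_point$condition_group,
    sex = completed_point$sex,
    measure = completed_point$measure,
    estimate = completed_point$attributable,
    mc_mean = rowMeans(comp_draws),
    ci_lo = apply(comp_draws, 1, quantile, probs = 0.025, names = FALSE),
    ci_hi = apply(comp_draws, 1, quantile, probs = 0.975, names = FALSE),
    total = completed_point$total
  )
  structure(out, class = c("ssb_mc_result", class(out)),
            config = config, draws = comp_draws)
}

# which base rows feed each completed row
.completion_members <- function(base, completed) {
  lapply(seq_len(nrow(completed)), function(i) {
    g <- completed$condition_group[i]; s <- completed$sex[i]
    m <- completed$measure[i]
    sel <- base$measure == m &
      (base$condition_group == g | g == "total") &
      (base$sex == s | s == "both")
    which(sel)
  })
}

#' Export the per-iteration trace of a Monte Carlo run
#'
#' @param result an `ssb_mc_result`.
#' @param path CSV file to write (long format: cell keys x iteration).
#' @return `path`, invisibly.
#' @export
write_mc_trace <- function(result, path) {
  draws <- attr(result, "draws")
  long <- tibble::tibble(
    condition_group = rep(result$condition_group, ncol(draws)),
    sex = rep(result$sex, ncol(draws)),
    measure = rep(result$measure, ncol(draws)),
    iteration = rep(seq_len(ncol(draws)), each = nrow(draws)),
    attributable = as.vector(draws)
  )
  readr::write_csv(long, path)
  invisible(path)
}
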