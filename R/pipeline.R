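#' Prepare a burden model from validated inputs
#'
#' Precomputes everything that does not change across Monte Carlo
#' iterations: the stratum table, all-cause burden totals per disease and
#' stratum, the baseline BMI point set per stratum, and the risk-function
#' bookkeeping.  Disease burden (events, deaths, DALYs, disease costs) is
#' modelled for adult strata; child strata contribute only
#' overweight/obesity cases and their costs — the long-term effects of
#' child exposure are deliberately not extrapolated.
#'
#' @param inputs an `ssb_inputs` object (see [read_inputs()]).
#' @param n_points BMI support points per stratum (see
#'   [fit_bmi_distribution()]).
#' @param effect per-serving BMI effect coefficients
#'   ([bmi_effect_model()]).
#' @param dose_response dose-response form for direct RRs
#'   ([rr_at_dose()]).
#' @return an `ssb_model` list consumed by [evaluate_model()].
#' @export
prepare_model <- function(inputs, n_points = 2000, effect = bmi_effect_model(),
                          dose_response = c("exponential", "linear")) {
  dose_response <- match.arg(dose_response)
  validate_inputs(inputs)
  strata <- dplyr::inner_join(inputs$population, inputs$consumption,
                              by = c("sex", "age_lo", "age_hi"))
  strata$id <- stratum_id(strata$sex, strata$age_lo, strata$age_hi)
  strata$is_adult <- strata$age_lo >= 18

  rf <- inputs$risk_functions
  rf$key <- paste(rf$disease, rf$outcome, sep = ".")
  epi <- inputs$disease_epi

  # all-cause totals per disease x adult stratum (sex-specific conditions
  # only enter matching strata)
  adult <- strata[strata$is_adult, ]
  grid <- tidyr::expand_grid(disease = epi$disease, stratum = adult$id)
  grid <- dplyr::left_join(grid, epi, by = "disease")
  grid <- dplyr::left_join(grid,
                           adult[, c("id", "sex", "age_lo", "age_hi", "population")],
                           by = c(stratum = "id"), suffix = c("_epi", ""))
  grid <- grid[grid$sex_epi == "all" | grid$sex_epi == grid$sex, ]
  totals <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    total_burden(grid[i, ], grid[i, ], inputs$life_table)
  }))
  grid <- dplyr::bind_cols(
    grid[, c("disease", "group", "stratum", "sex", "age_lo", "age_hi")],
    totals
  )

  # baseline BMI distribution per stratum (needed when the indirect pathway
  # or overweight/obesity costing is configured)
  needs_bmi <- any(rf$pathway == "bmi_mediated") || nrow(inputs$weight_costs) > 0
  bmi_dists <- NULL
  excess_base <- NULL
  indirect <- rf[rf$pathway == "bmi_mediated", ]
  if (needs_bmi) {
    bmi <- inputs$bmi
    bmi_ids <- stratum_id(bmi$sex, bmi$age_lo, bmi$age_hi)
    bmi_dists <- lapply(strata$id, function(id) {
      fit_bmi_distribution(bmi[match(id, bmi_ids), ], n_points = n_points)
    })
    names(bmi_dists) <- strata$id
    # baseline BMI excess over each reference level, per stratum
    refs <- unique(indirect$reference_bmi)
    excess_base <- lapply(refs, function(r) {
      lapply(bmi_dists, function(d) pmax(0, d$points - r))
    })
    names(excess_base) <- as.character(refs)
  }

  # annual overweight/obesity cost per category, adults and children
  wc <- inputs$weight_costs
  weight_cost <- list(
    adult = setNames(wc$cost_annual[wc$population == "adult"],
                     wc$category[wc$population == "adult"]),
    child = setNames(wc$cost_annual[wc$population == "child"],
                     wc$category[wc$population == "child"])
  )
  # fixed layout for overweight/obesity outputs: one row per stratum x
  # category, with baseline masses (counterfactual-independent)
  weight_layout <- NULL
  if (needs_bmi) {
    weight_layout <- dplyr::bind_rows(lapply(seq_len(nrow(strata)), function(i) {
      d <- bmi_dists[[i]]
      masses <- bmi_category_masses(d)[-1]
      cost_per <- weight_cost[[if (strata$is_adult[i]) "adult" else "child"]]
      tibble::tibble(
        stratum_idx = i, stratum = strata$id[i], sex = strata$sex[i],
        age_lo = strata$age_lo[i], age_hi = strata$age_hi[i],
        is_adult = strata$is_adult[i], category = names(masses),
        baseline_mass = unname(masses),
        population = strata$population[i],
        cost_per_case = unname(cost_per[names(masses)])
      )
    }))
  }

  structure(list(
    strata = strata,
    grid = grid,
    risk_functions = rf,
    direct = rf[rf$pathway == "direct", ],
    indirect = indirect,
    bmi_dists = bmi_dists,
    excess_base = excess_base,
    weight_cost = weight_cost,
    weight_layout = weight_layout,
    effect = effect,
    dose_response = dose_response,
    economics = inputs$economics,
    life_table = inputs$life_table
  ), class = "ssb_model")
}

# point-value parameter draws (the deterministic run)
.point_draws <- function(model) {
  list(
    servings = setNames(model$strata$mean_servings, model$strata$id),
    rr = setNames(model$risk_functions$rr_per_unit, model$risk_functions$key),
    effect = model$effect
  )
}

# Numeric core of one pipeline evaluation.  Returns bare vectors aligned to
# model$grid (disease burden) and model$weight_layout (overweight/obesity);
# the exported evaluate_model() dresses them up.
.evaluate_core <- function(model, servings, rr, effect, truncate = TRUE) {
  strata <- model$strata
  n_str <- nrow(strata)

  # counterfactual BMI points per stratum
  cf_points <- NULL
  if (!is.null(model$bmi_dists)) {
    cf_points <- vector("list", n_str)
    for (i in seq_len(n_str)) {
      d <- model$bmi_dists[[i]]
      delta <- if (strata$is_adult[i]) {
        ifelse(d$points < 25, effect$delta_low, effect$delta_high)
      } else effect$delta_child
      shifted <- d$points - servings[i] * delta
      cf_points[[i]] <- ifelse(d$points <= .bmi_floor, d$points,
                               pmax(shifted, .bmi_floor))
    }
  }

  # direct PAFs
  grid <- model$grid
  paf_events <- numeric(nrow(grid))
  paf_deaths <- numeric(nrow(grid))
  x_of <- setNames(servings, strata$id)
  exp_dr <- identical(model$dose_response, "exponential")
  direct <- model$direct
  for (d in unique(direct$disease)) {
    rows <- direct[direct$disease == d, ]
    theta_e <- rr[[rows$key[rows$outcome %in% c("all", "incidence")][1]]]
    theta_d <- rr[[rows$key[rows$outcome %in% c("all", "mortality")][1]]]
    sel <- which(grid$disease == d)
    x <- x_of[grid$stratum[sel]]
    mean_rr_e <- if (exp_dr) theta_e^x else 1 + (theta_e - 1) * x
    mean_rr_d <- if (exp_dr) theta_d^x else 1 + (theta_d - 1) * x
    pe <- 1 - 1 / mean_rr_e
    pd <- 1 - 1 / mean_rr_d
    if (truncate) {
      if (any(pe < 0) || any(pd < 0)) {
        warning("theta < 1 produced a negative PAF; capped at 0")
      }
      pe <- pmax(pe, 0); pd <- pmax(pd, 0)
    }
    paf_events[sel] <- pe
    paf_deaths[sel] <- pd
  }

  # BMI-mediated PAFs
  indirect <- model$indirect
  if (nrow(indirect) > 0 && !is.null(cf_points)) {
    str_index <- setNames(seq_len(n_str), strata$id)
    for (i in seq_len(nrow(indirect))) {
      rr_i <- max(rr[[indirect$key[i]]], 1e-6)
      lrr <- log(rr_i)
      ref <- as.character(indirect$reference_bmi[i])
      sel <- which(grid$disease == indirect$disease[i])
      p <- vapply(grid$stratum[sel], function(id) {
        k <- str_index[[id]]
        w <- model$bmi_dists[[k]]$weights
        e_base <- sum(w * exp(lrr * model$excess_base[[ref]][[k]]))
        e_cf <- sum(w * exp(lrr * pmax(0, cf_points[[k]] -
                                         indirect$reference_bmi[i])))
        1 - e_cf / e_base
      }, numeric(1))
      paf_events[sel] <- p
      paf_deaths[sel] <- p
    }
  }

  out <- list(
    paf_events = paf_events,
    paf_deaths = paf_deaths,
    attr_events = paf_events * grid$events,
    attr_deaths = paf_deaths * grid$deaths,
    attr_ylds = paf_events * grid$ylds,
    attr_ylls = paf_deaths * grid$ylls,
    attr_cost = paf_events * grid$cost
  )
  out$attr_dalys <- out$attr_ylds + out$attr_ylls

  # overweight/obesity cases per stratum x category
  if (!is.null(model$weight_layout)) {
    wl <- model$weight_layout
    cf_mass <- numeric(nrow(wl))
    for (i in seq_len(n_str)) {
      d <- model$bmi_dists[[i]]
      idx <- findInterval(cf_points[[i]], d$cutoffs) + 1L
      m <- vapply(seq_len(length(d$cutoffs) + 1L),
                  function(k) sum(d$weights[idx == k]), numeric(1))[-1]
      cf_mass[wl$stratum_idx == i] <- m
    }
    out$weight_cf_mass <- cf_mass
    out$weight_attr_cases <- (wl$baseline_mass - cf_mass) * wl$population
    out$weight_attr_cost <- out$weight_attr_cases * wl$cost_per_case
  }
  out
}

#' Evaluate the deterministic pipeline for one parameter set
#'
#' Runs the full causal chain for a single set of parameter values (point
#' values by default; sampled values inside [run_mc()]): direct PAFs from
#' per-serving RRs, the counterfactual BMI shift with BMI-mediated PAFs and
#' attributable overweight/obesity cases, and PAF-weighted attribution of
#' every burden total.
#'
#' @param model an `ssb_model` from [prepare_model()].
#' @param draws list with `servings` (named by stratum id), `rr` (named by
#'   `disease.outcome`) and `effect`; defaults to the point values.
#' @param truncate cap negative direct PAFs at zero (see [paf()]); the
#'   Monte Carlo engine disables this to keep intervals unbiased.
#' @return list with `burden` (per disease x stratum attributable and
#'   total quantities) and `weight` (per stratum x BMI category cases and
#'   costs; `NULL` when no BMI pathway is configured).
#' @export
evaluate_model <- function(model, draws = .point_draws(model), truncate = TRUE) {
  servings <- draws$servings[model$strata$id]
  if (anyNA(servings)) .validation_error("missing consumption for a stratum")
  core <- .evaluate_core(model, servings, draws$rr, draws$effect, truncate)
  grid <- model$grid
  burden <- dplyr::bind_cols(
    grid[, c("disease", "group", "stratum", "sex", "age_lo", "age_hi")],
    tibble::tibble(
      paf_events = core$paf_events, paf_deaths = core$paf_deaths,
      attr_events = core$attr_events, attr_deaths = core$attr_deaths,
      attr_ylds = core$attr_ylds, attr_ylls = core$attr_ylls,
      attr_dalys = core$attr_dalys, attr_cost = core$attr_cost
    ),
    grid[, c("events", "deaths", "ylds", "ylls", "dalys", "cost")]
  )
  weight <- NULL
  if (!is.null(model$weight_layout)) {
    wl <- model$weight_layout
    weight <- dplyr::bind_cols(
      wl[, c("stratum", "sex", "age_lo", "age_hi", "is_adult", "category")],
      tibble::tibble(
        baseline_cases = wl$baseline_mass * wl$population,
        counterfactual_cases = core$weight_cf_mass * wl$population,
        attributable_cases = core$weight_attr_cases,
        cost_attr = core$weight_attr_cost,
        cost_total = wl$baseline_mass * wl$population * wl$cost_per_case
      )
    )
  }
  list(burden = burden, weight = weight)
}

#' Aggregate an evaluation into condition groups by sex
#'
#' Collapses the per-disease, per-stratum output of [evaluate_model()] to
#' the reporting shape: one row per condition group x sex x measure, with
#' the attributable quantity and its all-cause total.  Overweight/obesity
#' appears as two groups (`ow_ob_adult`, `ow_ob_child`) carrying only
#' events and costs; costs are converted to USD millions.
#'
#' @param evaluation output of [evaluate_model()].
#' @param economics one-row economics table (currency conversion).
#' @return tibble with `condition_group`, `sex`, `measure`, `attributable`,
#'   `total`.
#' @export
aggregate_results <- function(evaluation, economics) {
  b <- evaluation$burden
  if (any(is.na(b$group))) {
    .validation_error("diseases without a condition-group mapping")
  }
  disease_rows <- dplyr::bind_rows(lapply(c("events", "deaths", "dalys"), function(m) {
    dplyr::summarise(dplyr::group_by(b, condition_group = .data$group, .data$sex),
                     measure = m,
                     attributable = sum(.data[[paste0("attr_", m)]]),
                     total = sum(.data[[m]]), .groups = "drop")
  }))
  cost_rows <- dplyr::summarise(
    dplyr::group_by(b, condition_group = .data$group, .data$sex),
    measure = "cost_musd",
    attributable = convert_currency(sum(.data$attr_cost), economics) / 1e6,
    total = convert_currency(sum(.data$cost), economics) / 1e6,
    .groups = "drop"
  )
  out <- dplyr::bind_rows(disease_rows, cost_rows)

  w <- evaluation$weight
  if (!is.null(w)) {
    w$condition_group <- ifelse(w$is_adult, "ow_ob_adult", "ow_ob_child")
    weight_rows <- dplyr::bind_rows(
      dplyr::summarise(dplyr::group_by(w, .data$condition_group, .data$sex),
                       measure = "events",
                       attributable = sum(.data$attributable_cases),
                       total = sum(.data$baseline_cases), .groups = "drop"),
      dplyr::summarise(dplyr::group_by(w, .data$condition_group, .data$sex),
                       measure = "cost_musd",
                       attributable = convert_currency(sum(.data$cost_attr), economics) / 1e6,
                       total = convert_currency(sum(.data$cost_total), economics) / 1e6,
                       .groups = "drop")
    )
    out <- dplyr::bind_rows(weight_rows, out)
  }
  out <- out[order(out$condition_group, out$measure, out$sex), ]
  tibble::as_tibble(out)
}

# Fast path used inside the Monte Carlo loop: same cell values as
# aggregate_results()$attributable, computed with rowsum() on the raw core
# output.  Returns a named vector keyed "group|sex|measure".
.fast_aggregate <- function(core, model, usd_scale) {
  g <- model$.agg
  vals <- c(
    setNames(as.vector(rowsum(core$attr_events, g$burden_key)),
             paste(g$burden_levels, "events", sep = "|")),
    setNames(as.vector(rowsum(core$attr_deaths, g$burden_key)),
             paste(g$burden_levels, "deaths", sep = "|")),
    setNames(as.vector(rowsum(core$attr_dalys, g$burden_key)),
             paste(g$burden_levels, "dalys", sep = "|")),
    setNames(as.vector(rowsum(core$attr_cost, g$burden_key)) * usd_scale,
             paste(g$burden_levels, "cost_musd", sep = "|"))
  )
  if (!is.null(core$weight_attr_cases)) {
    vals <- c(vals,
      setNames(as.vector(rowsum(core$weight_attr_cases, g$weight_key)),
               paste(g$weight_levels, "events", sep = "|")),
      setNames(as.vector(rowsum(core$weight_attr_cost, g$weight_key)) * usd_scale,
               paste(g$weight_levels, "cost_musd", sep = "|"))
    )
  }
  vals
}

.agg_bookkeeping <- function(model) {
  burden_key <- factor(paste(model$grid$group, model$grid$sex, sep = "|"))
  out <- list(burden_key = burden_key, burden_levels = levels(burden_key))
  if (!is.null(model$weight_layout)) {
    wl <- model$weight_layout
    weight_key <- factor(paste(ifelse(wl$is_adult, "ow_ob_adult", "ow_ob_child"),
                               wl$sex, sep = "|"))
    out$weight_key <- weight_key
    out$weight_levels <- levels(weight_key)
  }
  out
}

#' Deterministic point-estimate pipeline
#'
#' Convenience wrapper: prepare the model, evaluate it at the point
#' parameter values, and aggregate to the reporting shape (including
#' both-sex and all-condition totals with attributable percentages).
#'
#' @inheritParams prepare_model
#' @param n_points BMI support points per stratum.
#' @return list with `report` (completed aggregate, see
#'   [aggregate_attributable()]), `evaluation` (per-disease detail) and
#'   `model`.
#' @export
compute_burden <- function(inputs, n_points = 2000,
                           effect = bmi_effect_model(),
                           dose_response = c("exponential", "linear")) {
  model <- prepare_model(inputs, n_points = n_points, effect = effect,
                         dose_response = dose_response)
  evaluation <- evaluate_model(model)
  base <- aggregate_results(evaluation, model$economics)
  list(report = aggregate_attributable(base), evaluation = evaluation,
       model = model)
}
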