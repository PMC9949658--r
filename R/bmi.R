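#' Per-serving BMI effect coefficients
#'
#' Daily SSB intake shifts attained BMI.  Adults gain 0.10 kg/m2 per
#' serving/day when their baseline BMI is below 25 and 0.23 kg/m2 per
#' serving/day at 25 or above; children and adolescents gain 0.57/1.7 ~
#' 0.335 kg/m2 per serving/day (a single published contrast — a 0.57 kg/m2
#' reduction for a 1.7 serving reduction — assumed linear in servings).
#' Confidence bounds for the adult deltas are the published ones; the child
#' bounds are synthetic (+/-50%) since none are published.
#'
#' @param delta_low,delta_high,delta_child kg/m2 per serving/day.
#' @param ci_low,ci_high,ci_child length-2 95% bounds for each delta.
#' @return an `ssb_bmi_effect` list.
#' @export
bmi_effect_model <- function(delta_low = 0.10, delta_high = 0.23,
                             delta_child = 0.57 / 1.7,
                             ci_low = c(0.05, 0.15),
                             ci_high = c(0.14, 0.32),
                             ci_child = 0.57 / 1.7 * c(0.5, 1.5)) {
  deltas <- c(delta_low, delta_high, delta_child)
  if (any(deltas < 0)) stop("BMI effect deltas must be >= 0")
  structure(list(delta_low = delta_low, delta_high = delta_high,
                 delta_child = delta_child, ci_low = ci_low,
                 ci_high = ci_high, ci_child = ci_child),
            class = "ssb_bmi_effect")
}

# BMI support bounds for generated point sets (kg/m2).
.bmi_min <- 10.1
.bmi_max <- 79.9
# Counterfactual floor: shifted BMI never goes below this (unless the
# baseline already is).
.bmi_floor <- 13

# Mean of a log-normal restricted to (a, b], with values outside the
# generated BMI support clamped to its bounds (mirroring the point set).
.lnorm_cat_mean <- function(mu, sigma, a, b) {
  z <- function(x) {
    if (x <= 0) return(-Inf)
    if (is.infinite(x)) return(Inf)
    (log(x) - mu) / sigma
  }
  za <- z(a); zb <- z(b)
  mass <- stats::pnorm(zb) - stats::pnorm(za)
  zl <- max(za, z(.bmi_min)); zu <- min(zb, z(.bmi_max))
  core <- if (zu > zl) {
    exp(mu + sigma^2 / 2) * (stats::pnorm(zu - sigma) - stats::pnorm(zl - sigma))
  } else 0
  below <- .bmi_min * max(0, stats::pnorm(min(zb, z(.bmi_min))) - stats::pnorm(za))
  above <- .bmi_max * max(0, stats::pnorm(zb) - stats::pnorm(max(za, z(.bmi_max))))
  (core + below + above) / mass
}

# Absorb a residual between the target mean and the generated point-set
# mean by shifting points within their categories, proportionally to each
# point's headroom to the category bound.  Category masses are untouched.
.match_mean <- function(pts, cuts, target) {
  r <- target - sum(pts$weights * pts$points)
  if (abs(r) < 1e-9) return(pts)
  lo <- pmax(cuts[pts$category], .bmi_min)
  hi <- pmin(cuts[pts$category + 1L], .bmi_max)
  head_room <- if (r > 0) hi - 1e-6 - pts$points else pts$points - (lo + 1e-6)
  head_room <- pmax(head_room, 0)
  cap <- sum(pts$weights * head_room)
  lambda <- if (cap > 0) min(1, abs(r) / cap) else 0
  pts$points <- pts$points + sign(r) * lambda * head_room
  pts
}

# Quantile-midpoint point set for a log-normal, stratified so that each
# category's probability mass is matched exactly by its point weights.
.stratified_points <- function(mu, sigma, p, cuts, n_points) {
  points <- numeric(0); weights <- numeric(0); category <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] <= 0) next
    n_k <- max(1L, as.integer(round(p[k] * n_points)))
    fa <- stats::plnorm(cuts[k], mu, sigma)
    fb <- stats::plnorm(cuts[k + 1], mu, sigma)
    u <- (seq_len(n_k) - 0.5) / n_k
    q <- stats::qlnorm(fa + u * (fb - fa), mu, sigma)
    points <- c(points, pmin(pmax(q, .bmi_min), .bmi_max))
    weights <- c(weights, rep(p[k] / n_k, n_k))
    category <- c(category, rep(k, n_k))
  }
  list(points = points, weights = weights, category = category)
}

#' Fit a BMI distribution to a stratum profile
#'
#' Reconstructs an individual-level BMI point set from the published
#' summaries: a mean BMI plus category prevalences.  A log-normal is the
#' working shape (positive support, right skew, like empirical BMI); its
#' scale is pinned so that the mass at or above 25 kg/m2 equals the total
#' overweight-plus-obesity prevalence, and its spread is solved so that the
#' post-stratified mean — category masses re-weighted to the published
#' cells, with within-category shapes from the log-normal — matches the
#' published mean.  Points are quantile midpoints within each category, so
#' category masses are matched exactly by construction and the point set is
#' deterministic.  Any residual between the point-set mean and the target
#' (discretization, or profiles at the edge of the log-normal family) is
#' absorbed by shifting points within their categories in proportion to
#' their headroom to the category bounds, leaving category masses intact.
#'
#' Adult categories use the WHO cutoffs 25/30/35/40 kg/m2.  Child strata
#' (two categories, overweight and obesity) have no published absolute
#' cutoffs; their thresholds are taken as the baseline quantiles matching
#' the published prevalences under a fixed-shape log-normal
#' (`sdlog = 0.12`).
#'
#' @param profile one-row data frame / list with `mean_bmi`,
#'   `prev_overweight`, `prev_ob1`, `prev_ob2`, `prev_ob3` (child strata:
#'   `prev_ob1` = obesity prevalence, `prev_ob2 = prev_ob3 = 0`) and
#'   stratum keys `sex`, `age_lo`, `age_hi`.
#' @param n_points number of support points (`>= 1000`).
#' @param seed retained for interface stability; the default quantile-
#'   midpoint construction is deterministic regardless of its value.
#' @return an `ssb_bmi_dist`: list with `points`, `weights`, `category`,
#'   `cutoffs` (named), `is_adult`, `stratum`, and the fitted `mu`/`sigma`.
#' @export
fit_bmi_distribution <- function(profile, n_points = 2000, seed = 1L) {
  if (n_points < 1000) stop("n_points must be >= 1000")
  prev <- c(profile$prev_overweight, profile$prev_ob1,
            profile$prev_ob2, profile$prev_ob3)
  if (any(prev < 0 | prev > 1) || sum(prev) > 1 + 1e-9) {
    .validation_error("infeasible BMI profile: prevalences outside [0,1] or summing > 1")
  }
  is_adult <- profile$age_lo >= 18
  mean_bmi <- profile$mean_bmi
  if (is_adult) {
    p <- c(1 - sum(prev), prev)
    cuts <- c(0, 25, 30, 35, 40, Inf)
    pow <- sum(prev)                     # total mass at or above 25
    if (pow > 0 && pow < 1) {
      mu_of <- function(sigma) log(25) - sigma * qnorm(1 - pow)
      f <- function(sigma) {
        mu <- mu_of(sigma)
        m <- sum(vapply(seq_along(p), function(k) {
          if (p[k] <= 0) return(0)
          p[k] * .lnorm_cat_mean(mu, sigma, cuts[k], cuts[k + 1])
        }, numeric(1)))
        m - mean_bmi
      }
      sigma <- tryCatch(
        uniroot(f, c(0.02, 0.8), tol = 1e-10)$root,
        error = function(e) optimize(function(s) abs(f(s)), c(0.02, 0.8))$minimum
      )
      mu <- mu_of(sigma)
    } else {
      # degenerate profile: all mass on one side of 25; fix the shape and
      # solve the location so the truncated mean matches.
      sigma <- 0.15
      side <- if (pow == 0) c(0, 25) else c(25, Inf)
      g <- function(mu) .lnorm_cat_mean(mu, sigma, side[1], side[2]) - mean_bmi
      mu <- uniroot(g, log(c(12, 60)), tol = 1e-10, extendInt = "yes")$root
    }
    cutoffs <- c(overweight = 25, obesity1 = 30, obesity2 = 35, obesity3 = 40)
  } else {
    p_ow <- prev[1]; p_ob <- prev[2]
    sigma <- 0.12
    mu <- log(mean_bmi) - sigma^2 / 2
    t_ob <- qlnorm(1 - p_ob, mu, sigma)
    t_ow <- qlnorm(1 - p_ow - p_ob, mu, sigma)
    p <- c(1 - p_ow - p_ob, p_ow, p_ob)
    cuts <- c(0, t_ow, t_ob, Inf)
    cutoffs <- c(overweight = t_ow, obesity = t_ob)
  }
  pts <- .stratified_points(mu, sigma, p, cuts, n_points)
  pts <- .match_mean(pts, cuts, mean_bmi)
  structure(list(points = pts$points, weights = pts$weights,
                 category = pts$category, cutoffs = cutoffs,
                 is_adult = is_adult,
                 stratum = list(sex = profile$sex, age_lo = profile$age_lo,
                                age_hi = profile$age_hi),
                 mu = mu, sigma = sigma),
            class = "ssb_bmi_dist")
}

#' Category masses of a BMI distribution
#'
#' @param dist an `ssb_bmi_dist`, or a numeric vector of BMI points (then
#'   `weights` and `cutoffs` must be given).
#' @param weights,cutoffs used when `dist` is a bare numeric vector.
#' @return named vector of probability masses: `normal` plus one entry per
#'   cutoff category.
#' @export
bmi_category_masses <- function(dist, weights = NULL, cutoffs = NULL) {
  if (inherits(dist, "ssb_bmi_dist")) {
    points <- dist$points; weights <- dist$weights; cutoffs <- dist$cutoffs
  } else {
    points <- dist
  }
  idx <- findInterval(points, cutoffs) + 1L  # 1 = below first cutoff
  out <- vapply(seq_len(length(cutoffs) + 1L),
                function(k) sum(weights[idx == k]), numeric(1))
  names(out) <- c("normal", names(cutoffs))
  out
}

#' Shift a BMI distribution to its zero-SSB counterfactual
#'
#' Each individual's counterfactual BMI is `baseline - servings * delta`,
#' where `delta` is chosen once from the baseline BMI (below/at-or-above 25
#' for adults; the child coefficient for under-18 strata) and the result is
#' floored at 13 kg/m2.  Zero consumption returns the baseline unchanged.
#'
#' @param dist baseline `ssb_bmi_dist`.
#' @param consumption an `ssb_exposure` for the same stratum (its mean is
#'   the per-person daily serving count removed in the counterfactual).
#' @param effect an [bmi_effect_model()].
#' @param is_adult override for the adult/child coefficient choice;
#'   defaults to the distribution's own flag.
#' @return a new `ssb_bmi_dist` with shifted points (weights, categories
#'   and cutoffs unchanged).
#' @export
counterfactual_bmi <- function(dist, consumption, effect = bmi_effect_model(),
                               is_adult = dist$is_adult) {
  stopifnot(inherits(dist, "ssb_bmi_dist"), inherits(consumption, "ssb_exposure"))
  servings <- sum(consumption$weights * consumption$values)
  delta <- if (is_adult) {
    ifelse(dist$points < 25, effect$delta_low, effect$delta_high)
  } else {
    effect$delta_child
  }
  shifted <- dist$points - servings * delta
  out <- dist
  out$points <- ifelse(dist$points <= .bmi_floor, dist$points,
                       pmax(shifted, .bmi_floor))
  out
}

#' Attributable overweight/obesity cases from a counterfactual shift
#'
#' For each BMI category, attributable cases are the baseline category mass
#' minus the counterfactual category mass, times the stratum population.
#' Counts are additive across strata and linear in population.
#'
#' @param baseline,counterfactual `ssb_bmi_dist` objects sharing a point
#'   set (as produced by [counterfactual_bmi()]).
#' @param population stratum population (persons).
#' @return tibble with one row per category (`category`, `baseline_cases`,
#'   `counterfactual_cases`, `attributable_cases`).
#' @export
attributable_weight_cases <- function(baseline, counterfactual, population) {
  if (length(baseline$points) != length(counterfactual$points) ||
      !identical(baseline$cutoffs, counterfactual$cutoffs)) {
    .validation_error("baseline and counterfactual distributions do not match")
  }
  mb <- bmi_category_masses(baseline)[-1]        # drop "normal"
  mc <- bmi_category_masses(counterfactual)[-1]
  tibble::tibble(
    category = names(mb),
    baseline_cases = unname(mb) * population,
    counterfactual_cases = unname(mc) * population,
    attributable_cases = unname(mb - mc) * population
  )
}

#' BMI-mediated PAF from a counterfactual shift
#'
#' For a BMI-mediated risk function, the relative risk at BMI `b` is
#' `rr_per_unit ^ max(0, b - reference_bmi)` — log-linear above the
#' reference BMI and flat below it.  The attributable fraction compares the
#' population mean relative risk under the baseline and counterfactual
#' distributions: `PAF = 1 - E[RR(cf)] / E[RR(base)]`.
#'
#' @param baseline,counterfactual `ssb_bmi_dist` objects.
#' @param risk one row of the risk-function table (`pathway` must be
#'   `"bmi_mediated"`); a sampled `rr_per_unit` may be supplied via
#'   `rr_override`.
#' @param rr_override optional sampled relative risk replacing
#'   `risk$rr_per_unit`.
#' @return attributable fraction (proportion, `< 1`; non-negative whenever
#'   `rr_per_unit >= 1`).
#' @export
paf_indirect <- function(baseline, counterfactual, risk, rr_override = NULL) {
  if (!identical(risk$pathway, "bmi_mediated")) {
    .validation_error("paf_indirect requires a bmi_mediated risk function (got ",
                      risk$pathway, ")")
  }
  rr <- if (is.null(rr_override)) risk$rr_per_unit else rr_override
  ref <- risk$reference_bmi
  e_base <- sum(baseline$weights * rr^pmax(0, baseline$points - ref))
  e_cf <- sum(counterfactual$weights * rr^pmax(0, counterfactual$points - ref))
  1 - e_cf / e_base
}
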