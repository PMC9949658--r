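test_that("fitted BMI distributions reproduce the published moments", {
  fx <- ssb_fixture()
  for (i in seq_len(nrow(fx$bmi))) {
    pr <- fx$bmi[i, ]
    d <- fit_bmi_distribution(pr, n_points = 2000)
    expect_equal(sum(d$weights * d$points), pr$mean_bmi, tolerance = 0.05 / 30)
    masses <- bmi_category_masses(d)
    tgt <- if (pr$age_lo >= 18) {
      c(pr$prev_overweight, pr$prev_ob1, pr$prev_ob2, pr$prev_ob3)
    } else {
      c(pr$prev_overweight, pr$prev_ob1)
    }
    expect_equal(unname(masses[-1]), tgt, tolerance = 0.005)
    expect_true(all(d$points > 10 & d$points < 80))
    # counted masses equal the brute-force per-point classification exactly
    expect_equal(masses, oracle_category_masses(d$points, d$weights, d$cutoffs))
  }
})

test_that("an all-normal-weight profile fits entirely below 25", {
  pr <- list(sex = "female", age_lo = 18, age_hi = 44, mean_bmi = 22,
             prev_overweight = 0, prev_ob1 = 0, prev_ob2 = 0, prev_ob3 = 0)
  d <- fit_bmi_distribution(pr, n_points = 1000)
  expect_true(all(d$points < 25))
  expect_equal(sum(d$weights * d$points), 22, tolerance = 1e-6)
})

test_that("infeasible profiles are rejected", {
  pr <- list(sex = "male", age_lo = 18, age_hi = 44, mean_bmi = 28,
             prev_overweight = 0.6, prev_ob1 = 0.5, prev_ob2 = 0, prev_ob3 = 0)
  expect_error(fit_bmi_distribution(pr), class = "ssb_validation_error")
  expect_error(fit_bmi_distribution(list(sex = "male", age_lo = 18, age_hi = 44,
                                         mean_bmi = 28, prev_overweight = 0.3,
                                         prev_ob1 = 0.1, prev_ob2 = 0,
                                         prev_ob3 = 0), n_points = 10),
               "n_points")
})

test_that("counterfactual shift applies the published per-serving deltas", {
  eff <- bmi_effect_model()
  # adult at baseline 26, two servings/day: shift by 2 x 0.23
  d <- structure(list(points = c(22, 26), weights = c(0.5, 0.5),
                      category = c(1L, 2L),
                      cutoffs = c(overweight = 25, obesity1 = 30,
                                  obesity2 = 35, obesity3 = 40),
                      is_adult = TRUE,
                      stratum = list(sex = "male", age_lo = 18, age_hi = 44)),
                 class = "ssb_bmi_dist")
  cf <- counterfactual_bmi(d, exposure_point(2), eff)
  expect_equal(cf$points[2], 26 - 2 * 0.23)
  expect_equal(cf$points[1], 22 - 2 * 0.10)  # below-25 coefficient
  # zero consumption leaves the distribution untouched
  expect_equal(counterfactual_bmi(d, exposure_point(0), eff)$points, d$points)
  # child at 1.7 servings/day loses 0.57 kg/m2
  dc <- d; dc$is_adult <- FALSE
  cfc <- counterfactual_bmi(dc, exposure_point(1.7), eff)
  expect_equal(dc$points - cfc$points, rep(0.57, 2), tolerance = 1e-12)
  # the shift is floored so BMI never drops below 13
  dl <- d; dl$points <- c(13.05, 26)
  cfl <- counterfactual_bmi(dl, exposure_point(3), eff)
  expect_equal(cfl$points[1], 13)
  expect_true(all(cfl$points <= dl$points))
})

test_that("attributable case counts equal brute-force re-classification", {
  fx <- ssb_fixture()
  eff <- bmi_effect_model()
  for (i in c(1, 5, 7)) {  # adult female, adult male, child
    pr <- fx$bmi[i, ]
    base <- fit_bmi_distribution(pr, n_points = 2000)
    cf <- counterfactual_bmi(base, exposure_point(1.2), eff)
    pop <- 250000
    got <- attributable_weight_cases(base, cf, pop)
    mb <- oracle_category_masses(base$points, base$weights, base$cutoffs)[-1]
    mc <- oracle_category_masses(cf$points, cf$weights, cf$cutoffs)[-1]
    expect_equal(got$attributable_cases, unname(mb - mc) * pop)
    expect_true(all(got$attributable_cases >= 0))
    # identical distributions produce zeros
    none <- attributable_weight_cases(base, base, pop)
    expect_true(all(none$attributable_cases == 0))
    # linear in population, additive across strata
    twice <- attributable_weight_cases(base, cf, 2 * pop)
    expect_equal(twice$attributable_cases, 2 * got$attributable_cases)
  }
})

test_that("BMI-mediated PAF matches a hand-computed toy and its invariants", {
  risk <- list(disease = "asthma", pathway = "bmi_mediated", outcome = "all",
               rr_per_unit = 1.10, ci_lo = 1.05, ci_hi = 1.15,
               reference_bmi = 22)
  mk <- function(points) {
    structure(list(points = points, weights = rep(0.5, 2), category = c(1L, 2L),
                   cutoffs = c(overweight = 25, obesity1 = 30, obesity2 = 35,
                               obesity3 = 40),
                   is_adult = TRUE,
                   stratum = list(sex = "male", age_lo = 18, age_hi = 44)),
              class = "ssb_bmi_dist")
  }
  base <- mk(c(24, 28)); cf <- mk(c(23.8, 27.54))
  hand <- 1 - mean(c(1.1^max(0, 23.8 - 22), 1.1^max(0, 27.54 - 22))) /
    mean(c(1.1^max(0, 24 - 22), 1.1^max(0, 28 - 22)))
  expect_equal(paf_indirect(base, cf, risk), hand, tolerance = 1e-12)
  # no shift -> 0; all mass in the flat region -> 0
  expect_equal(paf_indirect(base, base, risk), 0)
  low <- mk(c(18, 20)); low_cf <- mk(c(17.8, 19.8))
  expect_equal(paf_indirect(low, low_cf, risk), 0)
  # direct risk functions are rejected
  expect_error(paf_indirect(base, cf, list(pathway = "direct")),
               class = "ssb_validation_error")
  # bounded and monotone in the size of the shift
  p1 <- paf_indirect(base, mk(c(23.9, 27.8)), risk)
  p2 <- paf_indirect(base, mk(c(23.8, 27.5)), risk)
  expect_true(p1 >= 0 && p2 < 1 && p2 > p1)
})

test_that("counterfactual never raises BMI and never raises excess-weight mass", {
  fx <- ssb_fixture()
  eff <- bmi_effect_model()
  set.seed(11)
  for (i in seq_len(nrow(fx$bmi))) {
    base <- fit_bmi_distribution(fx$bmi[i, ], n_points = 1000)
    cf <- counterfactual_bmi(base, exposure_point(runif(1, 0, 3)), eff)
    expect_true(all(cf$points <= base$points + 1e-12))
    mb <- bmi_category_masses(base); mc <- bmi_category_masses(cf)
    expect_true(all(mc[-1] <= mb[-1] + 1e-12))
  }
})
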