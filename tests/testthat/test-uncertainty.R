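test_that("zero input variance collapses the interval onto the point estimate", {
  inputs <- toy_inputs(theta = 1.37, servings = 1, se = 0)
  mc <- run_mc(inputs, mc_config(n_iter = 100, seed = 5))
  expect_equal(mc$ci_lo, mc$estimate, tolerance = 1e-12)
  expect_equal(mc$ci_hi, mc$estimate, tolerance = 1e-12)
  expect_equal(mc$mc_mean, mc$estimate, tolerance = 1e-12)
})

test_that("interval width shrinks as input variances shrink", {
  width_at <- function(se, half_ci) {
    inputs <- toy_inputs(theta = 1.37, servings = 1, se = se)
    inputs$risk_functions$ci_lo <- 1.37 - half_ci
    inputs$risk_functions$ci_hi <- 1.37 + half_ci
    mc <- run_mc(inputs, mc_config(n_iter = 300, seed = 9))
    row <- mc[mc$condition_group == "total" & mc$sex == "both" &
                mc$measure == "deaths", ]
    row$ci_hi - row$ci_lo
  }
  w <- c(width_at(0.2, 0.2), width_at(0.05, 0.05), width_at(0.01, 0.01))
  expect_true(all(diff(w) < 0))
  expect_lt(w[3], w[1] / 5)
})

test_that("a fixed seed reproduces the run exactly; seeds differ otherwise", {
  inputs <- toy_inputs(theta = 1.37, servings = 1, se = 0.1)
  inputs$risk_functions$ci_lo <- 1.16
  inputs$risk_functions$ci_hi <- 1.58
  a <- run_mc(inputs, mc_config(n_iter = 200, seed = 123))
  b <- run_mc(inputs, mc_config(n_iter = 200, seed = 123))
  expect_identical(attr(a, "draws"), attr(b, "draws"))
  c <- run_mc(inputs, mc_config(n_iter = 200, seed = 321))
  expect_false(identical(attr(a, "draws"), attr(c, "draws")))
})

test_that("independent seeds agree on the mean within Monte Carlo error", {
  inputs <- toy_inputs(theta = 1.37, servings = 1, se = 0.1)
  inputs$risk_functions$ci_lo <- 1.16
  inputs$risk_functions$ci_hi <- 1.58
  pick <- function(mc) {
    mc[mc$condition_group == "diabetes" & mc$sex == "both" &
         mc$measure == "deaths", ]
  }
  a <- pick(run_mc(inputs, mc_config(n_iter = 5000, seed = 1)))
  b <- pick(run_mc(inputs, mc_config(n_iter = 5000, seed = 2)))
  # se of the iteration mean from the draw spread itself
  sd_draw <- (a$ci_hi - a$ci_lo) / 3.92
  se_mean <- sd_draw / sqrt(5000)
  expect_lt(abs(a$mc_mean - b$mc_mean), 3 * sqrt(2) * se_mean)
})

test_that("the Monte Carlo mean converges to the analytic expectation", {
  # one stratum, one direct disease: attributable deaths per iteration are
  # deaths x (1 - theta^-x) with theta ~ N(1.37, 0.05), x ~ N(1, 0.08)
  # truncated at machine-positive/zero respectively; the analytic value is
  # a 2-d normal integral computed by quadrature, independent of run_mc().
  sd_rr <- 0.05; se_x <- 0.08
  inputs <- toy_inputs(theta = 1.37, servings = 1, se = se_x)
  inputs$risk_functions$ci_lo <- 1.37 - 1.96 * sd_rr
  inputs$risk_functions$ci_hi <- 1.37 + 1.96 * sd_rr
  n_iter <- 20000
  mc <- run_mc(inputs, mc_config(n_iter = n_iter, seed = 31))
  row <- mc[mc$condition_group == "diabetes" & mc$sex == "both" &
              mc$measure == "deaths", ]

  integrand <- function(th, x) {
    (1 - pmax(th, 1e-6)^(-pmax(x, 0))) *
      dnorm(th, 1.37, sd_rr) * dnorm(x, 1, se_x)
  }
  inner <- function(th) {
    vapply(th, function(t) {
      integrate(function(x) integrand(t, x), -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  analytic <- 100 * integrate(inner, 1.37 - 8 * sd_rr, 1.37 + 8 * sd_rr,
                              rel.tol = 1e-9)$value
  idx <- which(mc$condition_group == "diabetes" & mc$sex == "both" &
                 mc$measure == "deaths")
  sd_draw <- sd(attr(mc, "draws")[idx, ])
  expect_lt(abs(row$mc_mean - analytic), 4 * sd_draw / sqrt(n_iter))
})

test_that("missing uncertainty specifications are rejected", {
  inputs <- toy_inputs(theta = 1.37, servings = 1, se = 0.1)
  inputs$risk_functions$ci_lo <- NA_real_
  expect_error(run_mc(inputs, mc_config(n_iter = 10)),
               class = "ssb_validation_error")
  inputs2 <- toy_inputs()
  inputs2$consumption$se_servings <- NA_real_
  expect_error(run_mc(inputs2, mc_config(n_iter = 10)),
               class = "ssb_validation_error")
})

test_that("fixture-scale Monte Carlo reports intervals around the point estimate", {
  fx <- ssb_fixture()
  mc <- run_mc(fx, mc_config(n_iter = 100, seed = 17, n_points = 1000))
  expect_true(all(mc$ci_lo <= mc$ci_hi))
  on_point <- mc$measure != "cost_musd" | mc$estimate > 0
  expect_true(all(mc$ci_lo[on_point] <= mc$estimate[on_point] + 1e-9))
  expect_true(all(mc$estimate[on_point] <= mc$ci_hi[on_point] + 1e-9))
  # attributable quantities never exceed their all-cause totals
  expect_true(all(mc$estimate <= mc$total + 1e-9))
})
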