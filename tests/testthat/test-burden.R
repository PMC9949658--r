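fx <- ssb_fixture()

test_that("total_burden converts rates to counts, YLDs, YLLs and costs", {
  stratum <- list(sex = "male", age_lo = 18, age_hi = 44, population = 1e5)
  epi <- fx$disease_epi[fx$disease_epi$disease == "diabetes_t2", ]
  tot <- total_burden(epi, stratum, fx$life_table)
  expect_equal(tot$prevalent_cases, 12363)
  expect_equal(tot$ylds, 12363 * 0.07)  # 865.41
  expect_equal(tot$events, tot$prevalent_cases)  # prevalent events basis
  expect_equal(tot$deaths, 71.91)
  le <- life_expectancy_at(fx$life_table, (18 + 44 + 1) / 2)
  expect_equal(tot$ylls, 71.91 * le)
  expect_equal(tot$dalys, tot$ylds + tot$ylls)
  expect_equal(tot$cost, 12363 * 1414)

  # zero population zeroes everything
  tot0 <- total_burden(epi, modifyList(stratum, list(population = 0)),
                       fx$life_table)
  expect_true(all(unlist(tot0) == 0))

  # zero disability weight -> zero YLD (gallbladder/biliary diseases)
  gall <- fx$disease_epi[fx$disease_epi$disease == "gallbladder_biliary_disease", ]
  expect_equal(total_burden(gall, stratum, fx$life_table)$ylds, 0)
})

test_that("attribution is linear and never exceeds totals", {
  stratum <- list(sex = "male", age_lo = 18, age_hi = 44, population = 1e5)
  epi <- fx$disease_epi[fx$disease_epi$disease == "diabetes_t2", ]
  epi$mortality_rate <- 100
  tot <- total_burden(epi, stratum, fx$life_table)
  p <- 1 - 1 / 1.37
  attr <- attribute_burden(tot, p)
  expect_equal(attr$deaths, 100 * p)  # 27.007 deaths
  expect_equal(attr$events, tot$events * p)
  expect_equal(attr$dalys, attr$ylds + attr$ylls, tolerance = 1e-12)
  expect_true(all(unlist(attr) <= unlist(tot[names(attr)])))
  expect_true(all(unlist(attribute_burden(tot, 0)) == 0))
  # doubling costs doubles attributable cost
  tot2 <- tot; tot2$cost <- 2 * tot$cost
  expect_equal(attribute_burden(tot2, p)$cost, 2 * attr$cost)
})

test_that("attribution commutes with aggregation across strata", {
  strata <- list(
    list(sex = "male", age_lo = 18, age_hi = 44, population = 2e5),
    list(sex = "male", age_lo = 45, age_hi = 64, population = 5e4)
  )
  epi <- fx$disease_epi[fx$disease_epi$disease == "asthma", ]
  p <- c(0.12, 0.07)
  per <- mapply(function(s, pi) {
    attribute_burden(total_burden(epi, s, fx$life_table), pi)$events
  }, strata, p)
  tots <- vapply(strata, function(s) {
    total_burden(epi, s, fx$life_table)$events
  }, numeric(1))
  expect_equal(sum(per), sum(p * tots), tolerance = 1e-12)
})

test_that("currency conversion follows the published exchange rate", {
  ars <- list(exchange_rate = 48.14, cost_unit = "local")
  expect_equal(convert_currency(48.14, ars), 1)
  expect_equal(convert_currency(0, ars), 0)
  expect_equal(convert_currency(4814, ars), 100)
  # fixture costs are already USD and pass through unchanged
  expect_equal(convert_currency(10, fx$economics), 10)
  expect_error(convert_currency(1, list(exchange_rate = 0, cost_unit = "local")),
               class = "ssb_validation_error")
})

test_that("a one-stratum closed form matches the full pipeline", {
  inputs <- toy_inputs(theta = 1.37, servings = 1)
  res <- compute_burden(inputs)
  rep <- res$report
  p <- 1 - 1 / 1.37
  deaths <- rep[rep$condition_group == "diabetes" & rep$sex == "both" &
                  rep$measure == "deaths", ]
  expect_equal(deaths$attributable, p * 100, tolerance = 1e-12)
  expect_equal(deaths$total, 100)
  events <- rep[rep$condition_group == "total" & rep$sex == "both" &
                  rep$measure == "events", ]
  expect_equal(events$attributable, p * 500, tolerance = 1e-12)
})
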