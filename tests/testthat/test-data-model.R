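test_that("packaged fixture loads with the published population structure", {
  fx <- ssb_fixture()
  expect_s3_class(fx, "ssb_inputs")
  s <- summarize_inputs(fx)
  expect_equal(s$population[s$segment == "adult"], 30.2e6)
  # band populations for children sum to 12.9M (the printed 13.0M overall is
  # not the sum of its printed bands)
  expect_equal(s$population[s$segment == "child"], 12.9e6)
  # band-weighted adult consumption; the printed overall value (1.0) is not
  # reproducible from the printed bands
  expect_equal(s$mean_servings[s$segment == "adult"], 34.87e6 / 30.2e6,
               tolerance = 1e-9)
})

test_that("fixture carries the published cost and epidemiology values", {
  fx <- ssb_fixture()
  epi <- fx$disease_epi
  expect_equal(epi$cost_prevalent[epi$disease == "diabetes_t2"], 1414)
  expect_equal(epi$prevalence_rate[epi$disease == "diabetes_t2"], 12363)
  wc <- fx$weight_costs
  expect_equal(wc$cost_annual[wc$population == "child" & wc$category == "obesity"], 24)
  expect_equal(wc$cost_annual[wc$population == "adult" & wc$category == "overweight"], 0)
  expect_equal(fx$economics$exchange_rate, 48.14)
  rf <- fx$risk_functions
  expect_equal(rf$rr_per_unit[rf$disease == "diabetes_t2"], 1.37)
  expect_equal(rf$ci_hi[rf$disease == "stroke" & rf$outcome == "mortality"], 1.14)
})

test_that("write_fixture/read_inputs round-trips field-for-field", {
  dir <- withr::local_tempdir()
  fx <- ssb_fixture()
  write_fixture(dir, fx)
  back <- read_inputs(dir)
  for (nm in names(fx)) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(fx[[nm]]),
                 info = nm)
  }
})

test_that("reading an empty or incomplete directory fails with a clear error", {
  dir <- withr::local_tempdir()
  expect_error(read_inputs(dir), class = "ssb_validation_error")
  expect_error(read_inputs(file.path(dir, "nope")), class = "ssb_validation_error")
  expect_error(read_inputs(ssb_fixture_dir(), schema_version = "2"),
               class = "ssb_validation_error")
})

test_that("validation rejects coverage gaps and out-of-range values", {
  fx <- ssb_fixture()
  broken <- fx
  broken$consumption <- broken$consumption[-1, ]
  expect_error(validate_inputs(broken), "consumption missing",
               class = "ssb_validation_error")

  broken <- fx
  broken$disease_epi$incidence_rate[3] <- -1
  expect_error(validate_inputs(broken), "negative rates",
               class = "ssb_validation_error")

  broken <- fx
  broken$population$population[1] <- -5
  expect_error(validate_inputs(broken), class = "ssb_validation_error")

  broken <- fx
  broken$bmi$prev_overweight[2] <- 0.9  # with ob1 0.273 the sum exceeds 1
  expect_error(validate_inputs(broken), "sum > 1", class = "ssb_validation_error")
})

test_that("double-counting exclusion is enforced in both directions", {
  fx <- ssb_fixture()
  # a direct per-serving RR for asthma is not allowed
  bad <- fx
  bad$risk_functions$pathway[bad$risk_functions$disease == "asthma"] <- "direct"
  expect_error(validate_inputs(bad), "double-counting",
               class = "ssb_validation_error")
  # a BMI-mediated RR for diabetes or a cardiovascular condition is not allowed
  bad <- fx
  extra <- bad$risk_functions[bad$risk_functions$disease == "asthma", ]
  extra$disease <- "diabetes_t2"
  bad$risk_functions <- rbind(bad$risk_functions, extra)
  expect_error(validate_inputs(bad), "double-counting",
               class = "ssb_validation_error")
})
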