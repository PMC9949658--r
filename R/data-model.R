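#' Input schema
#'
#' A model input set is a directory of UTF-8 CSV tables, one per entity,
#' mirroring the published input tables so that swapping countries means
#' swapping files:
#'
#' * `population.csv` — `sex` (`female`/`male`), `age_lo`, `age_hi` (years;
#'   `NA` = open-ended band), `population` (persons).  Age bands within one
#'   sex must not overlap.  Adults are strata with `age_lo >= 18`.
#' * `consumption.csv` — same stratum keys plus `mean_servings` and
#'   `se_servings` (240 ml servings/day).  The packaged fixture's standard
#'   errors are synthetic (set to 10% of the mean): the source publication
#'   prints only means in its main text.
#' * `bmi.csv` — stratum keys plus `mean_bmi` (kg/m2) and category
#'   prevalences `prev_overweight`, `prev_ob1`, `prev_ob2`, `prev_ob3`
#'   (proportions; WHO adult cutoffs 25/30/35/40 kg/m2).  For child strata
#'   `prev_ob1` holds the single obesity prevalence and `prev_ob2`/`prev_ob3`
#'   are 0; the fixture's child mean BMI values are synthetic placeholders
#'   (the published model does not use them).
#' * `disease_epi.csv` — `disease`, `group` (reporting group), `sex`
#'   (`all`/`female`/`male`), `incidence_rate`, `prevalence_rate`,
#'   `mortality_rate` (per 100,000), `disability_weight` (0–1),
#'   `cost_incident`, `cost_prevalent` (currency per case), `events_basis`
#'   (`incident` or `prevalent` — which count the "events" row reports).
#' * `risk_functions.csv` — `disease`, `pathway` (`direct`/`bmi_mediated`),
#'   `outcome` (`incidence`, `mortality` or `all`), `rr_per_unit`, `ci_lo`,
#'   `ci_hi`, `reference_bmi` (kg/m2, BMI-mediated rows only).  Direct RRs
#'   are per serving/day; BMI-mediated RRs are per kg/m2 above the
#'   reference.  The fixture's BMI-mediated values and the diabetes CI are
#'   plausible synthetic placeholders, not published numbers.
#' * `weight_costs.csv` — `population` (`adult`/`child`), `category`,
#'   `cost_annual` (currency per case per year).
#' * `economics.csv` — one row: `exchange_rate` (local currency per USD),
#'   `gdp_per_capita` (USD), `health_expenditure_share`, `cost_unit`
#'   (`USD` or `local`; costs in `local` units are divided by the exchange
#'   rate at reporting).
#' * `life_table_synthetic.csv` (or `life_table.csv`) — `age`,
#'   `residual_le`: abridged residual life expectancy used for years of
#'   life lost.  The packaged table is a synthetic stand-in for a national
#'   life table.
#' * `table3_attributable.csv` (optional) — published per-condition-group,
#'   per-sex attributable and total burden used by the reporting stage:
#'   `condition_group`, `sex`, `measure` (`events`, `deaths`, `dalys`,
#'   `cost_musd`), `attributable`, `total`, `ci_lo`, `ci_hi`.
#'
#' @name input-schema
#' @aliases ssb_inputs
NULL

.required_tables <- c("population", "consumption", "bmi", "disease_epi",
                      "risk_functions", "economics")
.optional_tables <- c("weight_costs", "life_table", "table3_attributable")

.read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and validate a model input directory
#'
#' Reads the delimited input tables documented in [input-schema], checks
#' them for internal consistency, and returns a cross-referenced input set.
#'
#' @param path directory containing the input tables.
#' @param schema_version schema identifier; only `"1"` is defined.
#' @return an object of class `ssb_inputs`: a named list of tibbles
#'   (`population`, `consumption`, `bmi`, `disease_epi`, `risk_functions`,
#'   `weight_costs`, `economics`, `life_table`, and optionally
#'   `table3_attributable`).
#' @seealso [ssb_fixture()] for the packaged Argentina 2020 input set,
#'   [write_fixture()] for the inverse operation.
#' @export
read_inputs <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    .validation_error("unknown schema_version: ", schema_version)
  }
  if (!dir.exists(path)) .validation_error("input directory does not exist: ", path)
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  names(files) <- sub("\\.csv$", "", basename(files))
  names(files)[names(files) == "life_table_synthetic"] <- "life_table"
  missing <- setdiff(.required_tables, names(files))
  if (length(missing)) {
    .validation_error("missing input tables: ", paste(missing, collapse = ", "))
  }
  inputs <- lapply(files, .read_table)
  inputs <- inputs[intersect(c(.required_tables, .optional_tables), names(inputs))]
  if (is.null(inputs$weight_costs)) {
    inputs$weight_costs <- tibble::tibble(population = character(),
                                          category = character(),
                                          cost_annual = numeric())
  }
  if (is.null(inputs$life_table)) {
    .validation_error("missing input tables: life_table")
  }
  inputs <- structure(inputs, class = "ssb_inputs")
  validate_inputs(inputs)
  inputs
}

#' Validate a model input set
#'
#' Checks stratum coverage, value ranges, and the double-counting exclusion
#' (no BMI-mediated relative risk may target a disease that already carries
#' a direct per-serving relative risk, i.e. diabetes or cardiovascular
#' disease).  Called by [read_inputs()]; exposed so that programmatically
#' built inputs (e.g. from [generate_population()]) can be checked too.
#'
#' @param inputs an `ssb_inputs` list.
#' @return `inputs`, invisibly, if valid; otherwise an error of class
#'   `ssb_validation_error`.
#' @export
validate_inputs <- function(inputs) {
  pop <- inputs$population
  if (nrow(pop) == 0) .validation_error("population table is empty")
  if (any(!pop$sex %in% .sexes)) .validation_error("population: sex must be female/male")
  if (any(pop$population < 0)) .validation_error("population: negative population")
  # age bands within a sex must not overlap
  for (s in unique(pop$sex)) {
    b <- pop[pop$sex == s, ]
    b <- b[order(b$age_lo), ]
    hi <- ifelse(is.na(b$age_hi), Inf, b$age_hi)
    if (any(b$age_lo[-1] <= hi[-nrow(b)])) {
      .validation_error("population: overlapping age bands for sex ", s)
    }
  }
  pop_ids <- stratum_id(pop$sex, pop$age_lo, pop$age_hi)
  if (anyDuplicated(pop_ids)) .validation_error("population: duplicated strata")

  cons <- inputs$consumption
  cons_ids <- stratum_id(cons$sex, cons$age_lo, cons$age_hi)
  gap <- setdiff(pop_ids, cons_ids)
  if (length(gap)) {
    .validation_error("consumption missing for strata: ", paste(gap, collapse = ", "))
  }
  if (any(cons$mean_servings < 0, na.rm = TRUE) ||
      any(cons$se_servings < 0, na.rm = TRUE)) {
    .validation_error("consumption: negative mean or se")
  }

  epi <- inputs$disease_epi
  rates <- as.matrix(epi[, c("incidence_rate", "prevalence_rate", "mortality_rate")])
  if (any(rates < 0, na.rm = TRUE)) .validation_error("disease_epi: negative rates")
  if (any(epi$disability_weight < 0 | epi$disability_weight > 1)) {
    .validation_error("disease_epi: disability_weight outside [0,1]")
  }
  if (any(c(epi$cost_incident, epi$cost_prevalent) < 0, na.rm = TRUE)) {
    .validation_error("disease_epi: negative costs")
  }
  if (any(!epi$events_basis %in% c("incident", "prevalent"))) {
    .validation_error("disease_epi: events_basis must be incident/prevalent")
  }

  rf <- inputs$risk_functions
  if (any(rf$rr_per_unit <= 0 | rf$ci_lo <= 0, na.rm = TRUE)) {
    .validation_error("risk_functions: relative risks must be positive")
  }
  if (any(rf$ci_lo > rf$rr_per_unit | rf$rr_per_unit > rf$ci_hi, na.rm = TRUE)) {
    .validation_error("risk_functions: need ci_lo <= rr_per_unit <= ci_hi")
  }
  unknown <- setdiff(rf$disease, epi$disease)
  if (length(unknown)) {
    .validation_error("risk_functions reference diseases without epidemiology: ",
                      paste(unknown, collapse = ", "))
  }
  grp <- setNames(epi$group, epi$disease)
  direct_bad <- rf$pathway == "direct" & !grp[rf$disease] %in% .direct_groups
  if (any(direct_bad)) {
    .validation_error("double-counting violation: direct RR supplied for ",
                      paste(unique(rf$disease[direct_bad]), collapse = ", "),
                      " (direct pathway is reserved for diabetes and cardiovascular disease)")
  }
  indirect_bad <- rf$pathway == "bmi_mediated" & grp[rf$disease] %in% .direct_groups
  if (any(indirect_bad)) {
    .validation_error("double-counting violation: BMI-mediated RR supplied for ",
                      paste(unique(rf$disease[indirect_bad]), collapse = ", "),
                      " which already carries the direct pathway")
  }
  if (any(rf$pathway == "bmi_mediated" & is.na(rf$reference_bmi))) {
    .validation_error("risk_functions: BMI-mediated rows need reference_bmi")
  }

  # BMI profiles are needed for every stratum whenever the BMI pathway or
  # overweight/obesity costing is configured.
  needs_bmi <- any(rf$pathway == "bmi_mediated") || nrow(inputs$weight_costs) > 0
  if (needs_bmi) {
    bmi <- inputs$bmi
    bmi_ids <- stratum_id(bmi$sex, bmi$age_lo, bmi$age_hi)
    gap <- setdiff(pop_ids, bmi_ids)
    if (length(gap)) {
      .validation_error("bmi profile missing for strata: ", paste(gap, collapse = ", "))
    }
    pr <- as.matrix(bmi[, c("prev_overweight", "prev_ob1", "prev_ob2", "prev_ob3")])
    if (any(pr < 0 | pr > 1)) .validation_error("bmi: prevalences outside [0,1]")
    if (any(rowSums(pr) > 1 + 1e-9)) .validation_error("bmi: category prevalences sum > 1")
  }

  eco <- inputs$economics
  if (nrow(eco) != 1 || eco$exchange_rate <= 0) {
    .validation_error("economics: need one row with exchange_rate > 0")
  }
  lt <- inputs$life_table
  if (any(diff(lt$age) <= 0) || any(lt$residual_le < 0)) {
    .validation_error("life_table: ages must increase and residual_le be >= 0")
  }
  invisible(inputs)
}

#' Path to the packaged Argentina 2020 fixture directory
#' @return directory path inside the installed package.
#' @export
ssb_fixture_dir <- function() {
  system.file("extdata", "argentina2020", package = "ssbcra", mustWork = TRUE)
}

#' Packaged Argentina 2020 input set
#'
#' The published key input tables (population, SSB consumption, BMI
#' profiles, disease epidemiology and costs, risk functions, economics)
#' together with the published attributable-burden table consumed by the
#' reporting stage.  Values that the main publication does not print
#' (consumption standard errors, child mean BMI, BMI-mediated relative
#' risks, the diabetes RR confidence interval, the life table) are clearly
#' documented synthetic placeholders — see [input-schema].
#'
#' @return an `ssb_inputs` object.
#' @export
ssb_fixture <- function() read_inputs(ssb_fixture_dir())

#' Write an input set to a directory of CSV tables
#'
#' Inverse of [read_inputs()]: emits one CSV per table so that
#' `read_inputs(write_fixture(dir))` round-trips field-for-field.
#'
#' @param target directory to create/write into.
#' @param inputs input set to write; defaults to the packaged fixture.
#' @return `target`, invisibly.
#' @export
write_fixture <- function(target, inputs = ssb_fixture()) {
  ok <- dir.exists(target) || dir.create(target, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(target, 2) != 0) {
    stop("cannot write to target directory: ", target)
  }
  for (nm in names(inputs)) {
    file_nm <- if (nm == "life_table") "life_table_synthetic" else nm
    readr::write_csv(inputs[[nm]], file.path(target, paste0(file_nm, ".csv")), na = "NA")
  }
  invisible(target)
}

#' @export
print.ssb_inputs <- function(x, ...) {
  pop <- x$population
  adult <- pop$age_lo >= 18
  cat("<ssb_inputs>\n")
  cat(sprintf("  strata: %d (%d adult, %d child)\n", nrow(pop), sum(adult), sum(!adult)))
  cat(sprintf("  population: %.1fM adults, %.1fM children\n",
              sum(pop$population[adult]) / 1e6, sum(pop$population[!adult]) / 1e6))
  cat(sprintf("  diseases: %d (%d direct-pathway RRs, %d BMI-mediated)\n",
              nrow(x$disease_epi), sum(x$risk_functions$pathway == "direct"),
              sum(x$risk_functions$pathway == "bmi_mediated")))
  invisible(x)
}

#' Population-weighted summary of an input set
#'
#' Convenience accessor: total population and weighted mean consumption for
#' adults and children, recomputed from the age-band strata.
#'
#' @param inputs an `ssb_inputs` object.
#' @return a tibble with one row per population segment.
#' @export
summarize_inputs <- function(inputs) {
  pop <- dplyr::inner_join(inputs$population, inputs$consumption,
                           by = c("sex", "age_lo", "age_hi"))
  pop$segment <- ifelse(pop$age_lo >= 18, "adult", "child")
  dplyr::summarise(
    dplyr::group_by(pop, .data$segment),
    mean_servings = sum(.data$mean_servings * .data$population) /
      sum(.data$population),
    population = sum(.data$population),
    .groups = "drop"
  )
}
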