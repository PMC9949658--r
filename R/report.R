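.group_order <- c("ow_ob_child", "ow_ob_adult", "diabetes", "cardiac",
                  "cerebrovascular", "ckd", "asthma", "musculoskeletal",
                  "other", "total")
.sex_order <- c("female", "male", "both")

#' Complete an attributable-burden table with both-sex rows, totals and
#' percentages
#'
#' Takes per-condition-group, per-sex rows of attributable and total burden
#' (the shape produced by [aggregate_results()], and the shape of the
#' published burden table) and adds: a `both` sex row per group and measure
#' (sum of female and male), an all-condition `total` group per sex and
#' measure (sum over groups), and the attributable percentage
#' `attributable / total`.  All derived rows are recomputed sums — where a
#' source publication's printed totals disagree with the sum of its own
#' cells, the recomputed value is reported.
#'
#' @param tbl tibble with `condition_group`, `sex` (`female`/`male`),
#'   `measure`, `attributable`, `total`.
#' @return tibble in the same shape plus `both`/`total` rows and a `pct`
#'   column, ordered for presentation.
#' @export
aggregate_attributable <- function(tbl) {
  cols <- c("condition_group", "sex", "measure", "attributable", "total")
  if (nrow(tbl) == 0) {
    tbl <- tidyr::expand_grid(condition_group = character(0), sex = .sexes,
                              measure = .measures, attributable = 0, total = 0)
  }
  missing_group <- is.na(tbl$condition_group)
  if (any(missing_group)) {
    .validation_error("rows with unmapped condition group in aggregate input")
  }
  base <- tbl[, cols]
  both <- dplyr::summarise(
    dplyr::group_by(base, .data$condition_group, .data$measure),
    sex = "both", attributable = sum(.data$attributable),
    total = sum(.data$total), .groups = "drop"
  )
  with_both <- dplyr::bind_rows(base, both[, cols])
  totals <- dplyr::summarise(
    dplyr::group_by(with_both, .data$sex, .data$measure),
    condition_group = "total", attributable = sum(.data$attributable),
    total = sum(.data$total), .groups = "drop"
  )
  out <- dplyr::bind_rows(with_both, totals[, cols])
  if (nrow(out) == 0) {
    out <- tidyr::expand_grid(condition_group = "total", sex = .sex_order,
                              measure = .measures) |>
      dplyr::mutate(attributable = 0, total = 0)
  }
  out$pct <- ifelse(out$total > 0, out$attributable / out$total, NA_real_)
  g <- match(out$condition_group, .group_order)
  g[is.na(g)] <- length(.group_order) + 1L
  out <- out[order(g, match(out$measure, .measures),
                   match(out$sex, .sex_order)), ]
  tibble::as_tibble(out)
}

# one decimal below 2%, whole percent above — mirrors the presentation of
# published burden tables
.fmt_pct <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p * 100 < 1.95, sprintf("(%.1f%%)", p * 100),
                sprintf("(%.0f%%)", p * 100)))
}

.markdown_report <- function(report) {
  fmt_n <- function(x, m) {
    ifelse(m == "cost_musd", sprintf("$ %.1f", x),
           formatC(round(x), format = "d", big.mark = ","))
  }
  lines <- c("| Condition | Sex | Measure | Attributable / Total |",
             "|---|---|---|---|")
  cells <- sprintf("| %s | %s | %s | %s / %s %s |",
                   report$condition_group, report$sex, report$measure,
                   fmt_n(report$attributable, report$measure),
                   fmt_n(report$total, report$measure),
                   .fmt_pct(report$pct))
  c(lines, cells)
}

#' Render a burden report to disk
#'
#' Writes the completed attributable-burden table ([aggregate_attributable()]
#' output, or [run_mc()] output) as CSV, JSON or a markdown table, plus a
#' JSON run manifest when one is supplied.
#'
#' @param report tibble to write.
#' @param format one of `"csv"`, `"json"`, `"markdown"`.
#' @param path output file path (without manifest); its directory must
#'   exist.
#' @param manifest optional manifest list from [run_manifest()]; written
#'   next to `path` as `manifest.json`.
#' @return invisible character vector of the files written.
#' @export
render_report <- function(report, format = c("csv", "json", "markdown"),
                          path, manifest = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown report format"))
  written <- path
  switch(format,
    csv = readr::write_csv(report, path, na = "NA"),
    json = jsonlite::write_json(report, path, dataframe = "rows",
                                digits = NA, na = "null", pretty = TRUE),
    markdown = writeLines(.markdown_report(report), path)
  )
  if (!is.null(manifest)) {
    mpath <- file.path(dirname(path), "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, mpath)
  }
  invisible(written)
}

#' Run manifest for reproducibility
#'
#' Captures the seed, a hash of the run configuration, and checksums of the
#' input files.  Deliberately excludes timestamps so that identical runs
#' produce identical manifests.
#'
#' @param seed integer seed used for the run (`NA` for deterministic runs).
#' @param config list of run parameters to hash.
#' @param input_dir optional input directory whose CSV files are
#'   checksummed.
#' @return a manifest list.
#' @export
run_manifest <- function(seed = NA_integer_, config = list(), input_dir = NULL) {
  checksums <- NULL
  if (!is.null(input_dir)) {
    files <- sort(list.files(input_dir, pattern = "\\.csv$", full.names = TRUE))
    checksums <- as.list(tools::md5sum(files))
    names(checksums) <- basename(files)
  }
  list(seed = seed, config_hash = rlang::hash(config),
       input_checksums = checksums)
}
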