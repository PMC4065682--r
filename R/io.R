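# CSV exchange formats, packaged reference tables, study configuration and
# the end-to-end pipeline driver.

#' Study-wide analysis configuration
#'
#' Collects every tunable choice of the pipeline in one validated object.
#' Units are fixed package-wide: hours, mg/L, mg, litres, and minutes for
#' dissolution times.
#'
#' @param dose Dose in mg.
#' @param dosing_interval Dosing interval in hours for the steady-state
#'   projection (default 24).
#' @param loq Lower limit of quantification, mg/L.
#' @param reference_brand Reference product label.
#' @param alpha Significance level for formulation comparisons.
#' @param seed Integer seed recorded in reports and used for any simulation.
#' @param trapezoid_rule `"linear"` or `"linear-log"`.
#' @param f2_truncation Truncate the dissolution plateau above 85\%?
#' @param model_variant Compartmental variant fitted in the pipeline.
#' @return A list of class `study_config`.
#' @export
study_config <- function(dose = 500, dosing_interval = 24, loq = 0.05,
                         reference_brand = "F", alpha = 0.05, seed = 1L,
                         trapezoid_rule = c("linear", "linear-log"),
                         f2_truncation = FALSE,
                         model_variant = FIT_VARIANTS) {
  trapezoid_rule <- match.arg(trapezoid_rule)
  model_variant <- match.arg(model_variant)
  check_numeric(dose, "dose", positive = TRUE)
  check_numeric(dosing_interval, "dosing_interval", positive = TRUE)
  check_numeric(loq, "loq", nonneg = TRUE)
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must be in (0, 1).")
  structure(
    list(
      dose = dose, dosing_interval = dosing_interval, loq = loq,
      reference_brand = reference_brand, alpha = alpha,
      seed = as.integer(seed), trapezoid_rule = trapezoid_rule,
      f2_truncation = isTRUE(f2_truncation), model_variant = model_variant
    ),
    class = "study_config"
  )
}

#' Read a plasma concentration study from CSV
#'
#' Expected columns: `subject_id`, `time_hr`, `conc_mg_L`, `censored_flag`
#' (0/1 or logical), and optionally `brand` and `dose_mg`. Profiles are
#' grouped by subject and sorted by time; duplicated (subject, time) rows and
#' non-monotone time grids are reported as parse errors with the offending
#' rows named.
#'
#' @param path Path to the CSV file.
#' @param dose Dose (mg) applied when the file has no `dose_mg` column.
#' @return A tibble in the package's study format (`censored` logical).
#' @export
read_pk_study <- function(path, dose = NULL) {
  if (!file.exists(path)) stop_input(sprintf("File '%s' does not exist.", path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(raw, c("subject_id", "time_hr", "conc_mg_L", "censored_flag"),
             "study CSV")
  keys <- intersect(c("brand", "subject_id"), names(raw))
  key <- do.call(paste, c(raw[keys], sep = "/"))
  dup <- duplicated(cbind(key, raw$time_hr))
  if (any(dup)) {
    stop_input(sprintf(
      "Duplicated (subject, time) rows at line(s): %s.",
      paste(which(dup) + 1L, collapse = ", ")
    ))
  }
  out <- raw |>
    dplyr::mutate(censored = as.logical(.data$censored_flag)) |>
    dplyr::select(-"censored_flag") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), .data$time_hr)
  if (!"dose_mg" %in% names(out)) {
    if (is.null(dose)) stop_input("Provide `dose` or a `dose_mg` column.")
    out$dose_mg <- dose
  }
  cols <- c(intersect("brand", names(out)), "subject_id", "time_hr",
            "conc_mg_L", "censored", "dose_mg")
  dplyr::relocate(out, dplyr::all_of(cols))
}

#' Write a plasma concentration study to CSV
#'
#' Inverse of [read_pk_study()]; writing then reading reproduces the input
#' table exactly.
#'
#' @param data Study tibble with a logical `censored` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pk_study <- function(data, path) {
  check_cols(data, c("subject_id", "time_hr", "conc_mg_L", "censored"))
  out <- data |>
    dplyr::mutate(censored_flag = as.integer(.data$censored)) |>
    dplyr::select(-"censored")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read dissolution profiles from CSV
#'
#' Expected columns: `product_id`, `time_min`, `pct_dissolved`.
#'
#' @param path Path to the CSV file.
#' @return A tibble in the package's dissolution format.
#' @export
read_dissolution <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("File '%s' does not exist.", path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(raw, c("product_id", "time_min", "pct_dissolved"),
             "dissolution CSV")
  dplyr::arrange(raw, .data$product_id, .data$time_min)
}

#' Write dissolution profiles to CSV
#'
#' @param data Dissolution tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dissolution <- function(data, path) {
  check_cols(data, c("product_id", "time_min", "pct_dissolved"))
  readr::write_csv(data, path)
  invisible(path)
}

#' Packaged summary tables from a published six-brand ciprofloxacin study
#'
#' Machine-readable transcriptions of the summary tables of a published
#' rabbit bioavailability comparison of five generic ciprofloxacin 500 mg
#' tablet brands (A--E) against the branded reference (F): the dissolution
#' difference/similarity factors, the noncompartmental and compartmental
#' parameter summaries (mean and SD per brand), and the reported relative
#' bioavailabilities. These are output-format references and desk-check
#' inputs; the underlying raw curves were never published in machine-readable
#' form, so the tables cannot be regenerated from data.
#'
#' @return A named list of tibbles: `dissolution_factors` (`product_id`,
#'   `f2`, `f1`), `nca_summary` and `compartmental_summary` (`parameter`,
#'   `brand`, `mean`, `sd`, `starred`), `relative_bioavailability`
#'   (`brand`, `fr_pct`).
#' @examples
#' load_cipro_tables()$relative_bioavailability
#' @export
load_cipro_tables <- function() {
  f <- function(name) {
    readr::read_csv(
      system.file("extdata", name, package = "pkbioeq", mustWork = TRUE),
      show_col_types = FALSE
    )
  }
  list(
    dissolution_factors = f("cipro_dissolution_factors.csv"),
    nca_summary = f("cipro_nca_summary.csv"),
    compartmental_summary = f("cipro_compartmental_summary.csv"),
    relative_bioavailability = f("cipro_relative_bioavailability.csv")
  )
}

#' Run the full comparison pipeline on tabulated inputs
#'
#' Executes, in order: dissolution comparison (f1/f2 and release
#' classification, skipped when `dissolution_path` is `NULL`),
#' noncompartmental analysis of every subject, compartmental fitting, and
#' the brand-level bioequivalence statistics. The returned report nests the
#' result of every stage together with the configuration (seed included);
#' when `out_dir` is given the report is also written as JSON plus one CSV
#' per tabular section.
#'
#' @param config A [study_config()].
#' @param study_path CSV of plasma profiles ([read_pk_study()] format).
#' @param dissolution_path Optional CSV of dissolution profiles.
#' @param out_dir Optional output directory for `report.json` and CSVs.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, study_path, dissolution_path = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }
  report <- list(config = unclass(config))
  if (!is.null(dissolution_path)) {
    report$dissolution <- stage("dissolution", {
      d <- read_dissolution(dissolution_path)
      list(
        comparison = compare_dissolution(
          d, reference = config$reference_brand,
          truncate_after_85 = config$f2_truncation
        ),
        classification = classify_release(d)
      )
    })
  }
  study <- stage("read_study", read_pk_study(study_path, dose = config$dose))
  nca_tbl <- stage("nca", nca(study, method = config$trapezoid_rule))
  fits <- stage("compartmental", fit_pk_study(
    study, variant = config$model_variant
  ))
  bioeq <- stage("bioeq_stats", run_bioeq_study(
    nca_tbl, reference = config$reference_brand, alpha = config$alpha
  ))
  report$nca <- nca_tbl
  report$nca_by_brand <- nca_summary(nca_tbl)
  report$fits <- dplyr::select(fits, -dplyr::any_of("fit"))
  report$bioeq <- list(
    fr = bioeq$fr, anova = bioeq$anova, tukey = bioeq$tukey
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    write_pipeline_report(report, out_dir)
  }
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- report
  class(json) <- NULL
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$nca, file.path(out_dir, "nca.csv"))
  readr::write_csv(report$nca_by_brand, file.path(out_dir, "nca_by_brand.csv"))
  readr::write_csv(report$fits, file.path(out_dir, "fits.csv"))
  readr::write_csv(report$bioeq$fr, file.path(out_dir, "bioavailability.csv"))
  if (!is.null(report$dissolution)) {
    readr::write_csv(report$dissolution$comparison,
                     file.path(out_dir, "dissolution_comparison.csv"))
  }
  invisible(out_dir)
}
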