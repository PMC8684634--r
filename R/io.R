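#' Read the five EHR tables from CSV
#'
#' Loads and validates the audit's input tables. Expected files (header
#' row, UTF-8, ISO-8601 dates):
#'
#' * `patients.csv`: `patient_id, sex, race, birth_date, region, site_id`
#' * `diagnoses.csv`: `patient_id, code, date`
#' * `labs.csv`: `patient_id, analyte, value, date`
#' * `vitals.csv`: `patient_id, weight_kg, height_cm, date`
#' * `dispenses.csv`: `patient_id, drug, dose_mg, frequency, days_supply,
#'   fill_date, site_id`
#'
#' Validation errors name the offending file and rows: missing columns,
#' unparseable dates, drugs outside the three DOACs, non-positive doses.
#'
#' @param dir Directory containing the five CSVs.
#' @return A `doacaudit_bundle` (list of tibbles).
#' @export
read_ehr_tables <- function(dir) {
  schemas <- list(
    patients = readr::cols(
      patient_id = readr::col_character(), sex = readr::col_character(),
      race = readr::col_character(), birth_date = readr::col_date(),
      region = readr::col_character(), site_id = readr::col_character()
    ),
    diagnoses = readr::cols(
      patient_id = readr::col_character(), code = readr::col_character(),
      date = readr::col_date()
    ),
    labs = readr::cols(
      patient_id = readr::col_character(), analyte = readr::col_character(),
      value = readr::col_double(), date = readr::col_date()
    ),
    vitals = readr::cols(
      patient_id = readr::col_character(), weight_kg = readr::col_double(),
      height_cm = readr::col_double(), date = readr::col_date()
    ),
    dispenses = readr::cols(
      patient_id = readr::col_character(), drug = readr::col_character(),
      dose_mg = readr::col_double(), frequency = readr::col_character(),
      days_supply = readr::col_integer(), fill_date = readr::col_date(),
      site_id = readr::col_character()
    )
  )
  tables <- list()
  for (name in names(schemas)) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      abort(paste0("missing input file: ", path), class = "doacaudit_config_error")
    }
    tbl <- readr::read_csv(path, col_types = schemas[[name]])
    missing <- setdiff(names(schemas[[name]]$cols), names(tbl))
    if (length(missing) > 0) {
      abort(paste0(name, ".csv: missing column(s): ", paste(missing, collapse = ", ")),
        class = "doacaudit_data_error"
      )
    }
    probs <- readr::problems(tbl)
    if (nrow(probs) > 0) {
      abort(paste0(
        name, ".csv: ", nrow(probs), " parsing problem(s), first at row ",
        probs$row[1], " (", probs$expected[1], ")"
      ), class = "doacaudit_data_error")
    }
    tables[[name]] <- tbl
  }
  bad_drug <- which(!tables$dispenses$drug %in% DOAC_DRUGS)
  if (length(bad_drug) > 0) {
    abort(paste0(
      "dispenses.csv: unknown drug '", tables$dispenses$drug[bad_drug[1]],
      "' at row ", bad_drug[1], " (", length(bad_drug), " row(s) affected)"
    ), class = "doacaudit_data_error")
  }
  bad_dose <- which(!is.na(tables$dispenses$dose_mg) & tables$dispenses$dose_mg <= 0)
  if (length(bad_dose) > 0) {
    abort(paste0("dispenses.csv: non-positive dose at row ", bad_dose[1]),
      class = "doacaudit_data_error"
    )
  }
  bundle(
    tables$patients, tables$diagnoses, tables$labs, tables$vitals,
    tables$dispenses
  )
}

#' Write an EHR bundle to CSV
#'
#' Writes the five tables (and, when present, the generator's truth table
#' and a provenance sidecar recording the seed) into a directory, one CSV
#' per table with stable column order — the inverse of
#' [read_ehr_tables()].
#'
#' @param bundle A `doacaudit_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in c("patients", "diagnoses", "labs", "vitals", "dispenses")) {
    readr::write_csv(bundle[[name]], file.path(dir, paste0(name, ".csv")))
  }
  if (!is.null(bundle$truth)) {
    readr::write_csv(bundle$truth, file.path(dir, "truth.csv"))
  }
  if (!is.null(bundle$provenance)) {
    jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
      auto_unbox = TRUE
    )
  }
  invisible(dir)
}

#' Run the full audit pipeline and write reports
#'
#' Orchestrates cohort construction, scoring, dose assessment, concordance
#' profiling, the predictor models, and the switch analysis, writing one
#' CSV per report plus a provenance file. Deterministic given the inputs
#' and seed.
#'
#' @param input Either a directory of CSVs (read via [read_ehr_tables()])
#'   or a `doacaudit_bundle`.
#' @param output_dir Directory for the report CSVs.
#' @param code_map Code map (default bundled synthetic map).
#' @param min_site_denominators Named vector with elements
#'   `inappropriate_low` (default 100) and `inappropriate_full` (default
#'   20).
#' @param fit_models Fit the logistic predictor models (default `TRUE`;
#'   they are the slowest stage).
#' @param mdrd_coefficient Passed to the eGFR calculation.
#' @param seed Recorded in provenance (the audit itself is deterministic).
#' @return Invisible list of all in-memory results.
#' @export
run_pipeline <- function(input, output_dir,
                         code_map = default_code_map(),
                         min_site_denominators = c(
                           inappropriate_low = 100, inappropriate_full = 20
                         ),
                         fit_models = TRUE, mdrd_coefficient = 175,
                         seed = NA_integer_) {
  bundle <- if (is.character(input)) read_ehr_tables(input) else input
  stopifnot(inherits(bundle, "doacaudit_bundle"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  audit <- audit_cohort(
    bundle$patients, bundle$diagnoses, bundle$labs, bundle$vitals,
    bundle$dispenses, code_map = code_map, mdrd_coefficient = mdrd_coefficient
  )
  rates <- summarize_rates(audit$assessments, by = "drug")
  overall <- summarize_rates(audit$assessments)
  trends <- trend_table(audit$assessments)
  sites_low <- profile_sites(audit$assessments, "inappropriate_low",
    min_site_denominators[["inappropriate_low"]])
  sites_full <- profile_sites(audit$assessments, "inappropriate_full",
    min_site_denominators[["inappropriate_full"]])

  switch_res <- NULL
  if (nrow(audit$switch_side) > 0) {
    part <- partition_excluded_rivaroxaban(audit$switch_side)
    switch_res <- list(
      partition = part,
      single_dose = assess_single_dose_switchers(
        part$membership, bundle$dispenses, bundle$patients, bundle$labs,
        mdrd_coefficient
      ),
      dose_order = assess_dose_order(
        part$membership, bundle$dispenses, bundle$patients, bundle$labs,
        mdrd_coefficient
      )
    )
  }

  models <- NULL
  if (fit_models && nrow(audit$assessments) > 0) {
    models <- run_all_models(audit$assessments, audit$panel)
  }

  out <- function(x, name) readr::write_csv(x, file.path(output_dir, name))
  out(audit$exclusion_log, "exclusion_log.csv")
  out(audit$assessments, "assessments.csv")
  out(bind_rows(overall, rates), "rates.csv")
  out(trends, "trends.csv")
  out(mutate(sites_low$profiles, direction = "inappropriate_low"),
    "sites_inappropriate_low.csv")
  out(mutate(sites_full$profiles, direction = "inappropriate_full"),
    "sites_inappropriate_full.csv")
  if (!is.null(switch_res)) {
    out(switch_res$partition$counts, "switch_partition.csv")
    out(switch_res$single_dose, "switch_single_dose.csv")
    out(switch_res$dose_order$order_counts, "switch_dose_order.csv")
  }
  if (!is.null(models)) {
    flat <- models %>%
      filter(.data$status == "fitted") %>%
      mutate(terms = purrr::map(.data$result, "terms")) %>%
      select("direction", "drug", "group", "n", "terms") %>%
      tidyr::unnest("terms")
    out(flat, "model_terms.csv")
    out(select(models, -"result"), "model_status.csv")
  }
  jsonlite::write_json(
    list(
      seed = seed,
      n_input_patients = nrow(bundle$patients),
      n_cohort = nrow(audit$cohort),
      package_version = as.character(utils::packageVersion("doacaudit")),
      timestamp = NULL
    ),
    file.path(output_dir, "provenance.json"),
    auto_unbox = TRUE, null = "null"
  )

  invisible(list(
    audit = audit, rates = bind_rows(overall, rates), trends = trends,
    sites = list(inappropriate_low = sites_low, inappropriate_full = sites_full),
    switch = switch_res, models = models
  ))
}
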