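#' Identify the non-valvular atrial fibrillation population
#'
#' Patients with at least one atrial-fibrillation code and no valvular
#' heart-disease code, per the supplied code map.
#'
#' @param diagnoses Tibble `patient_id`, `code`, `date`.
#' @param code_map Code map with `nvaf` and `valvular` classes.
#' @return Character vector of patient ids.
#' @export
identify_nvaf <- function(diagnoses, code_map = default_code_map()) {
  for (cls in c("nvaf", "valvular")) {
    if (length(condition_names(code_map, cls)) == 0) {
      abort(paste0("code map defines no '", cls, "' condition"),
        class = "doacaudit_config_error"
      )
    }
  }
  af <- match_conditions(diagnoses, code_map,
    conditions = condition_names(code_map, "nvaf")
  )
  valv <- match_conditions(diagnoses, code_map,
    conditions = condition_names(code_map, "valvular")
  )
  setdiff(unique(af$patient_id), unique(valv$patient_id))
}

#' Apply the cohort exclusion cascade
#'
#' Starting from NVAF patients with at least one DOAC fill, applies the
#' exclusion steps in a fixed order, attributing each patient to the first
#' step they fail:
#'
#' 1. `supply_lt_30`: total days supply summed over all DOAC fills < 30;
#' 2. `vte_code`: any venous-thromboembolism code (the indication for
#'    anticoagulation is then ambiguous);
#' 3. `multiple_drug_dose_site`: more than one DOAC, more than one dose
#'    category of one DOAC, or fills from more than one site — these
#'    patients are retained in a side table for the switch analysis;
#' 4. `other_dose_only`: every fill is an unclassifiable (`OTHER`) regimen,
#'    e.g. rivaroxaban 10 mg;
#' 5. `missing_demographics`: missing sex, race, birth date, or region;
#' 6. `missing_clinical`: no index creatinine on/before the first fill, or
#'    (apixaban only) no index weight.
#'
#' The final cohort has exactly one drug, one dose category, one site,
#' >= 30 days total supply, no VTE code, and complete required variables.
#' Per-step counts depend on this order; final membership does not.
#'
#' @param patients,diagnoses,labs,vitals,dispenses The five EHR tables (see
#'   [read_ehr_tables()] for schemas).
#' @param code_map Code map.
#' @param min_days_supply Minimum total days supply (default 30).
#' @return List with `cohort` (patient tibble), `index_dates`,
#'   `exclusion_log` (tibble `step`, `n_excluded`, `n_remaining`), and
#'   `switch_side` (dispense rows of patients excluded at step 3).
#' @export
apply_exclusions <- function(patients, diagnoses, labs, vitals, dispenses,
                             code_map = default_code_map(),
                             min_days_supply = 30) {
  doac_fills <- filter(dispenses, .data$drug %in% DOAC_DRUGS)
  nvaf_ids <- identify_nvaf(diagnoses, code_map)
  ids <- intersect(unique(doac_fills$patient_id), nvaf_ids)
  log <- tibble(step = "nvaf_doac_recipients", n_excluded = NA_integer_,
    n_remaining = length(ids))
  note <- function(step, keep, pool) {
    excluded <- setdiff(pool, keep)
    log <<- bind_rows(log, tibble(
      step = step, n_excluded = length(excluded), n_remaining = length(keep)
    ))
    keep
  }

  per_pat <- doac_fills %>%
    mutate(category = classify_dispense(.data$drug, .data$dose_mg, .data$frequency)) %>%
    group_by(.data$patient_id) %>%
    summarise(
      total_supply = sum(.data$days_supply),
      n_drugs = dplyr::n_distinct(.data$drug),
      n_categories = dplyr::n_distinct(paste(.data$drug, .data$category)),
      n_sites = dplyr::n_distinct(.data$site_id),
      all_other = all(.data$category == "OTHER"),
      .groups = "drop"
    ) %>%
    filter(.data$patient_id %in% ids)

  # 1. minimum total supply
  keep <- per_pat$patient_id[per_pat$total_supply >= min_days_supply]
  ids <- note("supply_lt_30", keep, ids)

  # 2. VTE code at any time
  vte <- match_conditions(diagnoses, code_map,
    conditions = condition_names(code_map, "vte")
  )
  ids <- note("vte_code", setdiff(ids, unique(vte$patient_id)), ids)

  # 3. multiple DOACs / dose categories / sites
  pp <- filter(per_pat, .data$patient_id %in% ids)
  multi <- pp$patient_id[
    pp$n_drugs > 1 |
      (pp$n_categories > pp$n_drugs) | # >1 dose category for some drug
      pp$n_sites > 1
  ]
  switch_side <- filter(doac_fills, .data$patient_id %in% multi)
  ids <- note("multiple_drug_dose_site", setdiff(ids, multi), ids)

  # 4. only unclassifiable regimens
  pp <- filter(per_pat, .data$patient_id %in% ids)
  ids <- note("other_dose_only", setdiff(ids, pp$patient_id[pp$all_other]), ids)

  # 5. missing demographics
  demo <- patients %>%
    filter(.data$patient_id %in% ids) %>%
    mutate(complete = !is.na(.data$sex) & !is.na(.data$race) &
      !is.na(.data$birth_date) & !is.na(.data$region))
  missing_demo <- union(
    demo$patient_id[!demo$complete],
    setdiff(ids, demo$patient_id) # no patient record at all
  )
  ids <- note("missing_demographics", setdiff(ids, missing_demo), ids)

  # 6. missing clinical data at index
  index_dates <- first_fill_dates(filter(doac_fills, .data$patient_id %in% ids))
  cr <- labs %>%
    filter(.data$analyte == "creatinine") %>%
    select("patient_id", "value", "date") %>%
    select_index_lab(index_dates)
  has_cr <- cr$patient_id
  apix_ids <- doac_fills %>%
    filter(.data$patient_id %in% ids, .data$drug == "apixaban") %>%
    pull(.data$patient_id) %>%
    unique()
  wt <- vitals %>%
    inner_join(index_dates, by = "patient_id") %>%
    filter(.data$date <= .data$index_date, !is.na(.data$weight_kg)) %>%
    pull(.data$patient_id) %>%
    unique()
  missing_clin <- union(setdiff(ids, has_cr), setdiff(apix_ids, wt))
  ids <- note("missing_clinical", setdiff(ids, missing_clin), ids)

  list(
    cohort = filter(patients, .data$patient_id %in% ids),
    index_dates = filter(index_dates, .data$patient_id %in% ids),
    exclusion_log = log,
    switch_side = switch_side
  )
}

# earliest fill per patient; safe on zero rows (dplyr would otherwise warn)
first_fill_dates <- function(fills) {
  if (nrow(fills) == 0) {
    return(tibble(patient_id = character(), index_date = as.Date(character())))
  }
  fills %>%
    group_by(.data$patient_id) %>%
    summarise(index_date = min(.data$fill_date), .groups = "drop")
}

#' Site assignment for cohort patients
#'
#' The audit attributes each patient to the single facility that dispensed
#' their DOAC. Multi-site patients must already have been excluded; finding
#' one here is an internal invariant violation, not a data error.
#'
#' @param dispenses Dispense rows for cohort patients.
#' @return Tibble `patient_id`, `site_id`.
#' @export
assign_site <- function(dispenses) {
  if (nrow(dispenses) == 0) {
    abort("assign_site: no fills supplied", class = "doacaudit_data_error")
  }
  sites <- dispenses %>%
    group_by(.data$patient_id) %>%
    summarise(n_sites = dplyr::n_distinct(.data$site_id),
      site_id = .data$site_id[1], .groups = "drop")
  if (any(sites$n_sites > 1)) {
    abort("assign_site: patient with fills at multiple sites reached site assignment",
      class = "doacaudit_internal_error"
    )
  }
  select(sites, "patient_id", "site_id")
}

#' Run the full dose audit on a table bundle
#'
#' Convenience wrapper: exclusion cascade, score panel, and dose assessment
#' in one call.
#'
#' @inheritParams apply_exclusions
#' @param mdrd_coefficient Passed to [build_score_panel()].
#' @return List `assessments`, `panel`, `cohort`, `exclusion_log`,
#'   `switch_side`, `index_dates`.
#' @export
audit_cohort <- function(patients, diagnoses, labs, vitals, dispenses,
                         code_map = default_code_map(),
                         min_days_supply = 30, mdrd_coefficient = 175) {
  excl <- apply_exclusions(patients, diagnoses, labs, vitals, dispenses,
    code_map = code_map, min_days_supply = min_days_supply
  )
  panel <- build_score_panel(
    excl$cohort, diagnoses, labs, vitals, excl$index_dates,
    code_map = code_map, mdrd_coefficient = mdrd_coefficient
  )
  cohort_fills <- semi_join(dispenses, excl$index_dates, by = "patient_id")
  assessments <- assess_cohort(cohort_fills, panel)
  list(
    assessments = assessments, panel = panel, cohort = excl$cohort,
    exclusion_log = excl$exclusion_log, switch_side = excl$switch_side,
    index_dates = excl$index_dates
  )
}
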