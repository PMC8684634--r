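#' Classify a dispensed dose as full, low, or other
#'
#' The audit recognises exactly one full and one low regimen per drug, taken
#' from the FDA labels for non-valvular atrial fibrillation:
#'
#' * dabigatran: 150 mg twice daily = FULL; 75 mg twice daily = LOW
#' * rivaroxaban: 20 mg once daily = FULL; 15 mg once daily = LOW
#' * apixaban: 5 mg twice daily = FULL; 2.5 mg twice daily = LOW
#'
#' Any other (drug, dose, frequency) combination — including dabigatran
#' 110 mg, which the VA pharmacy service did not recommend for NVAF — is
#' classified `OTHER` and never reaches the concordance assessment.
#'
#' @param drug One of `"dabigatran"`, `"rivaroxaban"`, `"apixaban"`.
#' @param dose_mg Tablet strength in mg.
#' @param frequency `"once daily"` or `"twice daily"` (`"QD"`/`"BID"`
#'   accepted).
#' @return Character vector in `c("FULL", "LOW", "OTHER")`.
#' @export
#' @examples
#' classify_dispense("dabigatran", 150, "twice daily") # FULL
#' classify_dispense("rivaroxaban", 10, "once daily") # OTHER
classify_dispense <- function(drug, dose_mg, frequency) {
  unknown <- setdiff(unique(drug), DOAC_DRUGS)
  if (length(unknown) > 0) {
    abort(paste0("unknown drug: ", paste(unknown, collapse = ", ")),
      class = "doacaudit_data_error"
    )
  }
  freq <- normalize_frequency(frequency)
  case_when(
    drug == "dabigatran" & dose_mg == 150 & freq == "twice daily" ~ "FULL",
    drug == "dabigatran" & dose_mg == 75 & freq == "twice daily" ~ "LOW",
    drug == "rivaroxaban" & dose_mg == 20 & freq == "once daily" ~ "FULL",
    drug == "rivaroxaban" & dose_mg == 15 & freq == "once daily" ~ "LOW",
    drug == "apixaban" & dose_mg == 5 & freq == "twice daily" ~ "FULL",
    drug == "apixaban" & dose_mg == 2.5 & freq == "twice daily" ~ "LOW",
    TRUE ~ "OTHER"
  )
}

normalize_frequency <- function(frequency) {
  f <- tolower(trimws(frequency))
  out <- case_when(
    f %in% c("once daily", "qd", "od", "daily") ~ "once daily",
    f %in% c("twice daily", "bid") ~ "twice daily",
    TRUE ~ NA_character_
  )
  if (any(is.na(out) & !is.na(frequency))) {
    bad <- unique(frequency[is.na(out) & !is.na(frequency)])
    abort(paste0("unrecognised frequency: ", paste(bad, collapse = ", ")),
      class = "doacaudit_data_error"
    )
  }
  out
}

#' Apixaban dose-reduction criteria and the eight-group lattice
#'
#' The apixaban label recommends the low dose for patients meeting at least
#' two of three criteria: age >= 80 years, body weight <= 60 kg, serum
#' creatinine >= 1.5 mg/dL. All three boundaries are inclusive, as printed
#' on the label. The three flags define eight mutually exclusive groups —
#' all three; each pair; each single criterion; none — used to stratify the
#' predictor models, because the criteria themselves cannot be entered into
#' one regression (they determine the recommendation deterministically).
#'
#' @param age Age in years.
#' @param weight_kg Body weight in kg.
#' @param creatinine Serum creatinine in mg/dL.
#' @return Tibble with logical columns `age_ge_80`, `weight_le_60`,
#'   `creatinine_ge_1_5`, integer `n_criteria`, and factor `group` with
#'   levels `all_three`, `age_weight`, `age_creatinine`,
#'   `weight_creatinine`, `age_only`, `weight_only`, `creatinine_only`,
#'   `none`.
#' @export
#' @examples
#' apixaban_criteria(85, 55, 1.8)$group # all_three
apixaban_criteria <- function(age, weight_kg, creatinine) {
  if (any(is.na(age)) || any(is.na(weight_kg)) || any(is.na(creatinine))) {
    missing <- c(
      if (any(is.na(age))) "age",
      if (any(is.na(weight_kg))) "weight_kg",
      if (any(is.na(creatinine))) "creatinine"
    )
    abort(paste0(
      "apixaban criteria require complete inputs; missing: ",
      paste(missing, collapse = ", ")
    ), class = "doacaudit_data_error")
  }
  a <- age >= 80
  w <- weight_kg <= 60
  cr <- creatinine >= 1.5
  group <- case_when(
    a & w & cr ~ "all_three",
    a & w ~ "age_weight",
    a & cr ~ "age_creatinine",
    w & cr ~ "weight_creatinine",
    a ~ "age_only",
    w ~ "weight_only",
    cr ~ "creatinine_only",
    TRUE ~ "none"
  )
  tibble(
    age_ge_80 = a, weight_le_60 = w, creatinine_ge_1_5 = cr,
    n_criteria = as.integer(a) + as.integer(w) + as.integer(cr),
    group = factor(group, levels = APIXABAN_GROUPS)
  )
}

#' Guideline-recommended dose
#'
#' Label-based recommendation per drug, evaluated once at the index date:
#'
#' * dabigatran: LOW iff eGFR < 30 mL/min/1.73 m^2, FULL otherwise;
#' * rivaroxaban: LOW iff eGFR < 50, FULL otherwise;
#' * apixaban: LOW iff at least two of \{age >= 80, weight <= 60 kg,
#'   creatinine >= 1.5 mg/dL\}, FULL otherwise.
#'
#' Thresholds are strict/inclusive exactly as printed on the labels (eGFR
#' 30.0 on dabigatran is FULL; apixaban age 80 / weight 60 / creatinine 1.5
#' all count as criteria met).
#'
#' @param drug Drug name(s).
#' @param egfr eGFR (required for dabigatran/rivaroxaban).
#' @param age,weight_kg,creatinine Required for apixaban.
#' @return Character vector, `"FULL"` or `"LOW"`.
#' @export
recommend_dose <- function(drug, egfr = NULL, age = NULL, weight_kg = NULL,
                           creatinine = NULL) {
  n <- length(drug)
  grab <- function(x) if (is.null(x)) rep(NA_real_, n) else rep_len(x, n)
  egfr <- grab(egfr)
  age <- grab(age)
  weight_kg <- grab(weight_kg)
  creatinine <- grab(creatinine)

  renal <- drug %in% c("dabigatran", "rivaroxaban")
  if (any(renal & is.na(egfr))) {
    abort("recommend_dose: missing required input 'egfr' for dabigatran/rivaroxaban",
      class = "doacaudit_data_error"
    )
  }
  apix <- drug == "apixaban"
  for (v in c("age", "weight_kg", "creatinine")) {
    if (any(apix & is.na(get(v)))) {
      abort(paste0("recommend_dose: missing required input '", v, "' for apixaban"),
        class = "doacaudit_data_error"
      )
    }
  }
  unknown <- setdiff(unique(drug), DOAC_DRUGS)
  if (length(unknown) > 0) {
    abort(paste0("unknown drug: ", paste(unknown, collapse = ", ")),
      class = "doacaudit_data_error"
    )
  }

  out <- rep("FULL", n)
  out[drug == "dabigatran" & egfr < 30] <- "LOW"
  out[drug == "rivaroxaban" & egfr < 50] <- "LOW"
  if (any(apix)) {
    crit <- apixaban_criteria(age[apix], weight_kg[apix], creatinine[apix])
    out[apix][crit$n_criteria >= 2] <- "LOW"
  }
  out
}

#' Assess received versus recommended dose for a cohort
#'
#' Joins the cohort's dispensing facts (one drug, one dose regimen per
#' patient — guaranteed by the exclusion cascade) with the score panel and
#' produces one assessment row per patient: received category, recommended
#' category, the concordance flag, the apixaban criteria group where
#' applicable, the calendar year of the first fill, and the site.
#'
#' @param cohort_dispenses Dispense tibble restricted to cohort patients.
#' @param panel Score panel from [build_score_panel()] for the same
#'   patients.
#' @return Tibble `patient_id`, `drug`, `received`, `recommended`,
#'   `concordant`, `apixaban_group`, `year`, `site_id`.
#' @export
assess_cohort <- function(cohort_dispenses, panel) {
  if (nrow(cohort_dispenses) == 0) {
    return(tibble(
      patient_id = character(), drug = character(), received = character(),
      recommended = character(), concordant = logical(),
      apixaban_group = factor(character(), levels = APIXABAN_GROUPS),
      year = integer(), site_id = character()
    ))
  }
  facts <- cohort_dispenses %>%
    mutate(received = classify_dispense(.data$drug, .data$dose_mg, .data$frequency)) %>%
    group_by(.data$patient_id) %>%
    summarise(
      drug = unique(.data$drug),
      received = unique(.data$received),
      year = as.integer(format(min(.data$fill_date), "%Y")),
      site_id = unique(.data$site_id),
      .groups = "drop"
    )
  if (any(facts$received == "OTHER")) {
    abort("assess_cohort: OTHER dose category present in cohort; exclusions incomplete",
      class = "doacaudit_internal_error"
    )
  }
  dat <- facts %>%
    inner_join(
      select(panel, "patient_id", "egfr", "age", "weight_kg", "creatinine"),
      by = "patient_id"
    )
  dat$recommended <- recommend_dose(
    dat$drug,
    egfr = dat$egfr, age = dat$age,
    weight_kg = dat$weight_kg, creatinine = dat$creatinine
  )
  apix_group <- factor(rep(NA_character_, nrow(dat)), levels = APIXABAN_GROUPS)
  is_apix <- dat$drug == "apixaban"
  if (any(is_apix)) {
    apix_group[is_apix] <- apixaban_criteria(
      dat$age[is_apix], dat$weight_kg[is_apix], dat$creatinine[is_apix]
    )$group
  }
  dat %>%
    mutate(
      concordant = .data$received == .data$recommended,
      apixaban_group = apix_group
    ) %>%
    select(
      "patient_id", "drug", "received", "recommended", "concordant",
      "apixaban_group", "year", "site_id"
    )
}
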