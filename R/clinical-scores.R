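#' Estimated glomerular filtration rate (MDRD)
#'
#' Computes eGFR with the 4-variable MDRD study equation. The default uses
#' the IDMS-traceable coefficient (175), the form behind the automatic eGFR
#' reported by most VA laboratories during the DOAC era; the original 186
#' coefficient is available via `coefficient` for sensitivity analyses.
#'
#' eGFR = coefficient * Scr^-1.154 * age^-0.203 * 0.742^female * 1.212^black
#'
#' @param creatinine Serum creatinine, mg/dL. Must be positive.
#' @param age Age in years. Must be positive.
#' @param female Logical, `TRUE` for female sex.
#' @param black Logical, `TRUE` for Black race.
#' @param coefficient 175 (IDMS-traceable, default) or 186 (original assay).
#' @return eGFR in mL/min/1.73 m^2, same length as the inputs.
#' @export
#' @examples
#' egfr_mdrd(1.0, 60, female = FALSE, black = FALSE) # ~76.2
egfr_mdrd <- function(creatinine, age, female, black, coefficient = 175) {
  if (any(!is.finite(creatinine) | creatinine <= 0)) {
    abort("creatinine must be positive and finite", class = "doacaudit_domain_error")
  }
  if (any(!is.finite(age) | age <= 0)) {
    abort("age must be positive and finite", class = "doacaudit_domain_error")
  }
  coefficient * creatinine^(-1.154) * age^(-0.203) *
    ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

# NA-tolerant wrapper used when assembling panels: missing inputs propagate
# to a missing eGFR instead of a domain error.
egfr_mdrd_na <- function(creatinine, age, female, black, coefficient = 175) {
  out <- rep(NA_real_, length(creatinine))
  ok <- !is.na(creatinine) & !is.na(age) & creatinine > 0 & age > 0 &
    !is.na(female) & !is.na(black)
  if (any(ok)) {
    out[ok] <- egfr_mdrd(creatinine[ok], age[ok], female[ok], black[ok],
      coefficient = coefficient
    )
  }
  out
}

#' Invert the MDRD equation for creatinine
#'
#' Returns the serum creatinine that yields a target eGFR at the given
#' covariates. Used by the synthetic generator so that sampled eGFR
#' categories are internally consistent with the emitted creatinine values.
#'
#' @inheritParams egfr_mdrd
#' @param egfr Target eGFR, mL/min/1.73 m^2.
#' @return Creatinine in mg/dL.
#' @export
creatinine_for_egfr <- function(egfr, age, female, black, coefficient = 175) {
  if (any(!is.finite(egfr) | egfr <= 0)) {
    abort("egfr must be positive and finite", class = "doacaudit_domain_error")
  }
  base <- coefficient * age^(-0.203) * ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
  (egfr / base)^(-1 / 1.154)
}

#' Clinical category bins
#'
#' Categorical bins used throughout the audit. All bins are left-closed and
#' right-open except the top bin, so each raw value maps to exactly one
#' category.
#'
#' @param egfr,bmi,age,count Raw values.
#' @return Factor with the audit's category labels.
#' @name categories
NULL

#' @rdname categories
#' @export
egfr_category <- function(egfr) {
  cut(egfr,
    breaks = c(0, 30, 45, 60, Inf), right = FALSE,
    labels = c("<30", "30-44", "45-59", ">=60")
  )
}

#' @rdname categories
#' @export
bmi_category <- function(bmi) {
  cut(bmi,
    breaks = c(0, 25, 30, 35, Inf), right = FALSE,
    labels = c("<25", "25-29.9", "30-34.9", ">=35")
  )
}

#' @rdname categories
#' @export
age_category <- function(age) {
  cut(age,
    breaks = c(0, 65, 75, 85, Inf), right = FALSE,
    labels = c("<65", "65-74", "75-84", ">=85")
  )
}

#' @rdname categories
#' @export
elixhauser_category <- function(count) {
  cut(count,
    breaks = c(0, 3, 5, Inf), right = FALSE,
    labels = c("0-2", "3-4", ">=5")
  )
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_cm Height in centimetres.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(80, 200) # 20
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.na(weight_kg) & weight_kg <= 0) ||
    any(!is.na(height_cm) & height_cm <= 0)) {
    abort("weight and height must be positive", class = "doacaudit_domain_error")
  }
  weight_kg / (height_cm / 100)^2
}

#' CHA2DS2-VASc stroke-risk score
#'
#' Published point values: congestive heart failure 1, hypertension 1,
#' age >= 75 2, diabetes 1, prior stroke/TIA 2, vascular disease 1,
#' age 65-74 1, female sex 1. The score ranges 0-9.
#'
#' @param age Age in years.
#' @param female Logical.
#' @param heart_failure,hypertension,diabetes,stroke,vascular_disease
#'   Logical condition flags resolved from diagnoses on/before the index
#'   date.
#' @return Integer score in 0..9.
#' @export
chads_vasc <- function(age, female, heart_failure, hypertension, diabetes,
                       stroke, vascular_disease) {
  age_pts <- ifelse(age >= 75, 2L, ifelse(age >= 65, 1L, 0L))
  as.integer(
    heart_failure + hypertension + diabetes + vascular_disease + female +
      2L * stroke + age_pts
  )
}

#' Index laboratory selection
#'
#' Picks, per patient, the most recent lab value dated on or before the
#' index date (the first qualifying DOAC fill). Same-day labs count as
#' prior: the dosing clinician sees same-day results. A tie on the most
#' recent date is broken by the larger value — conservative in the sense of
#' leaning toward a low-dose recommendation. Patients with no qualifying
#' lab are simply absent from the result, which feeds the missing-data
#' exclusion downstream.
#'
#' @param labs Tibble `patient_id`, `value`, `date` (optionally `analyte`;
#'   filter beforehand if several analytes are present).
#' @param index_dates Tibble `patient_id`, `index_date`.
#' @return Tibble `patient_id`, `value`, `date`, one row per patient with at
#'   least one lab on/before index.
#' @export
select_index_lab <- function(labs, index_dates) {
  labs %>%
    inner_join(index_dates, by = "patient_id") %>%
    filter(.data$date <= .data$index_date) %>%
    arrange(.data$patient_id, dplyr::desc(.data$date), dplyr::desc(.data$value)) %>%
    group_by(.data$patient_id) %>%
    slice(1) %>%
    ungroup() %>%
    select("patient_id", "value", "date")
}

#' Elixhauser comorbidity count
#'
#' Number of distinct Elixhauser-class conditions (per the code map) with at
#' least one matching diagnosis code on/before the patient's index date.
#' Duplicate codes for the same condition count once.
#'
#' @param diagnoses Tibble `patient_id`, `code`, `date`.
#' @param code_map Code map with `class == "elixhauser"` rows.
#' @param index_dates Tibble `patient_id`, `index_date`; rows are returned
#'   for every patient listed here.
#' @return Tibble `patient_id`, `elixhauser_count`, `elixhauser_category`.
#' @export
count_elixhauser <- function(diagnoses, code_map, index_dates) {
  elix <- condition_names(code_map, "elixhauser")
  long <- match_conditions(diagnoses, code_map,
    index_dates = index_dates, conditions = elix
  )
  counts <- long %>% count(.data$patient_id, name = "elixhauser_count")
  index_dates %>%
    select("patient_id") %>%
    left_join(counts, by = "patient_id") %>%
    mutate(
      elixhauser_count = dplyr::coalesce(.data$elixhauser_count, 0L),
      elixhauser_category = elixhauser_category(.data$elixhauser_count)
    )
}

#' Build the per-patient score panel
#'
#' Derives every patient-level variable the audit needs, anchored at each
#' patient's index date (the first DOAC fill): age, index creatinine, MDRD
#' eGFR and category, weight/height/BMI from the most recent vitals on or
#' before index, CHA2DS2-VASc, and the Elixhauser count. Missing labs or
#' vitals yield `NA` fields; the exclusion cascade decides what is fatal.
#'
#' @param patients Tibble `patient_id`, `sex`, `race`, `birth_date`,
#'   `region`, `site_id`.
#' @param diagnoses Tibble `patient_id`, `code`, `date`.
#' @param labs Tibble `patient_id`, `analyte`, `value`, `date`.
#' @param vitals Tibble `patient_id`, `weight_kg`, `height_cm`, `date`.
#' @param index_dates Tibble `patient_id`, `index_date`.
#' @param code_map Code map (default [default_code_map()]).
#' @param mdrd_coefficient Passed to [egfr_mdrd()].
#' @return Tibble with one row per patient in `index_dates` joining
#'   demographics with all derived scores.
#' @export
build_score_panel <- function(patients, diagnoses, labs, vitals, index_dates,
                              code_map = default_code_map(),
                              mdrd_coefficient = 175) {
  cr <- labs %>%
    filter(.data$analyte == "creatinine") %>%
    select("patient_id", "value", "date") %>%
    select_index_lab(index_dates) %>%
    rename(creatinine = "value", creatinine_date = "date")

  vit <- vitals %>%
    inner_join(index_dates, by = "patient_id") %>%
    filter(.data$date <= .data$index_date) %>%
    arrange(.data$patient_id, dplyr::desc(.data$date)) %>%
    group_by(.data$patient_id) %>%
    slice(1) %>%
    ungroup() %>%
    select("patient_id", "weight_kg", "height_cm")

  risk_conditions <- c(
    "heart_failure", "hypertension", "diabetes", "stroke",
    "vascular_disease", "prior_bleeding"
  )
  flags <- condition_flags(
    diagnoses, code_map, index_dates$patient_id, risk_conditions,
    index_dates = index_dates
  )
  elix <- count_elixhauser(diagnoses, code_map, index_dates)

  panel <- index_dates %>%
    left_join(patients, by = "patient_id") %>%
    left_join(cr, by = "patient_id") %>%
    left_join(vit, by = "patient_id") %>%
    left_join(flags, by = "patient_id") %>%
    left_join(elix, by = "patient_id") %>%
    mutate(
      age = floor(as.numeric(.data$index_date - .data$birth_date) / 365.25),
      female = .data$sex == "F",
      black = .data$race == "Black",
      bmi = as.numeric(ifelse(
        is.na(.data$weight_kg) | is.na(.data$height_cm),
        NA_real_, compute_bmi(.data$weight_kg, .data$height_cm)
      )),
      egfr = egfr_mdrd_na(
        .data$creatinine, .data$age, .data$female, .data$black,
        coefficient = mdrd_coefficient
      ),
      egfr_category = egfr_category(.data$egfr),
      bmi_category = bmi_category(.data$bmi),
      age_category = age_category(.data$age),
      chads_vasc = chads_vasc(
        .data$age, .data$female, .data$heart_failure, .data$hypertension,
        .data$diabetes, .data$stroke, .data$vascular_disease
      )
    )
  panel
}
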