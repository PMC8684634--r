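# run the full audit on a table bundle
run_audit <- function(b, ...) {
  audit_cohort(b$patients, b$diagnoses, b$labs, b$vitals, b$dispenses, ...)
}

# minimal single-patient tables for hand-built scenarios
one_patient <- function(patient_id = "P1", sex = "M", race = "White",
                        birth_date = as.Date("1950-06-15"),
                        region = "Northeast", site_id = "S001") {
  tibble::tibble(
    patient_id = patient_id, sex = sex, race = race,
    birth_date = birth_date, region = region, site_id = site_id
  )
}

fill <- function(patient_id, drug, dose_mg, frequency, fill_date,
                 days_supply = 90L, site_id = "S001") {
  tibble::tibble(
    patient_id = patient_id, drug = drug, dose_mg = dose_mg,
    frequency = frequency, days_supply = as.integer(days_supply),
    fill_date = as.Date(fill_date), site_id = site_id
  )
}

dx <- function(patient_id, code, date = "2013-01-01") {
  tibble::tibble(patient_id = patient_id, code = code, date = as.Date(date))
}

lab <- function(patient_id, value, date) {
  tibble::tibble(
    patient_id = patient_id, analyte = "creatinine", value = value,
    date = as.Date(date)
  )
}

vital <- function(patient_id, weight_kg = 80, height_cm = 175,
                  date = "2013-01-01") {
  tibble::tibble(
    patient_id = patient_id, weight_kg = weight_kg, height_cm = height_cm,
    date = as.Date(date)
  )
}

# fixture cells helper: recommended-full denominators only
full_cells <- function(year, drug, denominator, numerator, site_id = "S001") {
  tibble::tibble(
    year = year, drug = drug,
    n_recommended_full = denominator, n_received_low = numerator,
    n_recommended_low = 0, n_received_full = 0, site_id = site_id
  )
}
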