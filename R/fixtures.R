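#' Deterministic fixture construction from count specifications
#'
#' Builds a full EHR table bundle in which the audit reproduces exactly the
#' requested numerators and denominators per (year, drug, site) cell — no
#' randomness anywhere. Each cell creates four archetype blocks:
#'
#' * recommended FULL, received FULL: `n_recommended_full - n_received_low`
#' * recommended FULL, received LOW: `n_received_low`
#' * recommended LOW, received LOW: `n_recommended_low - n_received_full`
#' * recommended LOW, received FULL: `n_received_full`
#'
#' Archetype covariates force the recommendation: for dabigatran and
#' rivaroxaban a creatinine placing eGFR clearly on the required side of
#' the drug's cutoff; for apixaban age/weight meeting two criteria (LOW) or
#' none (FULL). This is the workhorse behind the audit's exact-arithmetic
#' tests: published count tables can be re-expanded into patient-level data
#' and pushed through the complete pipeline.
#'
#' @param cells Tibble with columns `year`, `drug`, and counts
#'   `n_recommended_full`, `n_received_low`, `n_recommended_low`,
#'   `n_received_full`; optional `site_id` (default `"S001"`).
#' @return A `doacaudit_bundle` (see [generate_cohort()]) without a `truth`
#'   element.
#' @export
#' @examples
#' b <- make_fixture(tibble::tibble(
#'   year = 2013, drug = "apixaban",
#'   n_recommended_full = 68, n_received_low = 16,
#'   n_recommended_low = 0, n_received_full = 0
#' ))
#' nrow(b$patients) # 68
make_fixture <- function(cells) {
  required <- c(
    "year", "drug", "n_recommended_full", "n_received_low",
    "n_recommended_low", "n_received_full"
  )
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    abort(paste0("fixture cells missing column(s): ", paste(missing, collapse = ", ")),
      class = "doacaudit_config_error"
    )
  }
  if (!"site_id" %in% names(cells)) cells$site_id <- "S001"
  counts <- cells[, c("n_recommended_full", "n_received_low",
    "n_recommended_low", "n_received_full")]
  if (any(as.matrix(counts) < 0)) {
    abort("fixture counts must be non-negative", class = "doacaudit_config_error")
  }
  if (any(cells$n_received_low > cells$n_recommended_full) ||
    any(cells$n_received_full > cells$n_recommended_low)) {
    abort("infeasible fixture cell: numerator exceeds denominator",
      class = "doacaudit_config_error"
    )
  }

  blocks <- bind_rows(
    mutate(cells, recommended = "FULL", received = "FULL",
      n = .data$n_recommended_full - .data$n_received_low),
    mutate(cells, recommended = "FULL", received = "LOW",
      n = .data$n_received_low),
    mutate(cells, recommended = "LOW", received = "LOW",
      n = .data$n_recommended_low - .data$n_received_full),
    mutate(cells, recommended = "LOW", received = "FULL",
      n = .data$n_received_full)
  ) %>%
    filter(n > 0) %>%
    select("year", "drug", "site_id", "recommended", "received", "n") %>%
    tidyr::uncount(.data$n)

  n <- nrow(blocks)
  if (n == 0) {
    return(empty_bundle())
  }
  arch <- fixture_archetype(blocks$drug, blocks$recommended)
  ids <- sprintf("F%07d", seq_len(n))
  fill_date <- as.Date(paste0(blocks$year, "-06-15"))
  birth_date <- fill_date - round(arch$age * 365.25) - 100
  reg <- dose_regimen(blocks$drug, blocks$received)

  bundle(
    patients = tibble(
      patient_id = ids, sex = "M", race = "White", birth_date = birth_date,
      region = "Northeast", site_id = blocks$site_id
    ),
    diagnoses = tibble(
      patient_id = ids, code = "427.31", date = fill_date - 200
    ),
    labs = tibble(
      patient_id = ids, analyte = "creatinine", value = arch$creatinine,
      date = fill_date - 30
    ),
    vitals = tibble(
      patient_id = ids, weight_kg = arch$weight, height_cm = 175,
      date = fill_date - 30
    ),
    dispenses = tibble(
      patient_id = ids, drug = blocks$drug, dose_mg = reg$dose_mg,
      frequency = reg$frequency, days_supply = 30L, fill_date = fill_date,
      site_id = blocks$site_id
    )
  )
}

# covariates that force a recommendation, per drug
# (eGFR at creatinine 1.0 / age 60 / male / non-Black is ~76; at 2.5 it is
# ~27 (< 30) and at 1.6 it is ~44 (< 50))
fixture_archetype <- function(drug, recommended) {
  low <- recommended == "LOW"
  age <- ifelse(drug == "apixaban" & low, 85, 60)
  weight <- ifelse(drug == "apixaban" & low, 55, 80)
  creatinine <- dplyr::case_when(
    drug == "dabigatran" & low ~ 2.5,
    drug == "rivaroxaban" & low ~ 1.6,
    TRUE ~ 1.0
  )
  list(age = age, weight = weight, creatinine = creatinine)
}

bundle <- function(patients, diagnoses, labs, vitals, dispenses,
                   truth = NULL, provenance = NULL) {
  structure(
    list(
      patients = patients, diagnoses = diagnoses, labs = labs,
      vitals = vitals, dispenses = dispenses, truth = truth,
      provenance = provenance
    ),
    class = "doacaudit_bundle"
  )
}

empty_bundle <- function() {
  bundle(
    patients = tibble(
      patient_id = character(), sex = character(), race = character(),
      birth_date = as.Date(character()), region = character(),
      site_id = character()
    ),
    diagnoses = tibble(
      patient_id = character(), code = character(), date = as.Date(character())
    ),
    labs = tibble(
      patient_id = character(), analyte = character(), value = numeric(),
      date = as.Date(character())
    ),
    vitals = tibble(
      patient_id = character(), weight_kg = numeric(), height_cm = numeric(),
      date = as.Date(character())
    ),
    dispenses = tibble(
      patient_id = character(), drug = character(), dose_mg = numeric(),
      frequency = character(), days_supply = integer(),
      fill_date = as.Date(character()), site_id = character()
    )
  )
}

#' Deterministic fixture for the dose-switch analysis
#'
#' Builds patients who would be excluded from the main cohort for multiple
#' DOACs or multiple rivaroxaban dose strengths, with exact group sizes and
#' appropriateness counts. Defaults reproduce the bundled published switch
#' counts ([doac_switch_counts()]).
#'
#' @param counts List with elements:
#'   `group1` (`n_low_appropriate`, `n_low_inappropriate`,
#'   `n_full_appropriate`, `n_full_inappropriate`, `n_missing_egfr` — the
#'   missing-eGFR patients receive the full dose),
#'   `group2` (`n_full_first_appropriate`, `n_full_first_inappropriate`,
#'   `n_full_first_missing`, `n_low_first_appropriate`,
#'   `n_low_first_inappropriate`, `n_low_first_missing`),
#'   `group3` (`n`).
#' @return A `doacaudit_bundle`. Running [apply_exclusions()] on it routes
#'   every patient into the switch side table.
#' @export
make_switch_fixture <- function(counts = doac_switch_counts()) {
  g1 <- counts$group1
  g2 <- counts$group2
  g3 <- counts$group3

  # creatinine 1.0 -> eGFR ~76 (>= 50); 1.6 -> ~44 (< 50), at age 60 male
  rows <- bind_rows(
    # group 1: single riva dose + dabigatran
    tibble(group = "g1", riva_dose = "LOW", egfr_ge_50 = FALSE,
      n = g1$n_low_appropriate),
    tibble(group = "g1", riva_dose = "LOW", egfr_ge_50 = TRUE,
      n = g1$n_low_inappropriate),
    tibble(group = "g1", riva_dose = "FULL", egfr_ge_50 = TRUE,
      n = g1$n_full_appropriate),
    tibble(group = "g1", riva_dose = "FULL", egfr_ge_50 = FALSE,
      n = g1$n_full_inappropriate),
    tibble(group = "g1", riva_dose = "FULL", egfr_ge_50 = NA,
      n = g1$n_missing_egfr),
    # group 2: both riva doses, full or low first
    tibble(group = "g2", riva_dose = "FULL_FIRST", egfr_ge_50 = TRUE,
      n = g2$n_full_first_appropriate),
    tibble(group = "g2", riva_dose = "FULL_FIRST", egfr_ge_50 = FALSE,
      n = g2$n_full_first_inappropriate),
    tibble(group = "g2", riva_dose = "FULL_FIRST", egfr_ge_50 = NA,
      n = g2$n_full_first_missing),
    tibble(group = "g2", riva_dose = "LOW_FIRST", egfr_ge_50 = FALSE,
      n = g2$n_low_first_appropriate),
    tibble(group = "g2", riva_dose = "LOW_FIRST", egfr_ge_50 = TRUE,
      n = g2$n_low_first_inappropriate),
    tibble(group = "g2", riva_dose = "LOW_FIRST", egfr_ge_50 = NA,
      n = g2$n_low_first_missing),
    # group 3: both riva doses + apixaban
    tibble(group = "g3", riva_dose = "FULL_FIRST", egfr_ge_50 = TRUE, n = g3$n)
  ) %>%
    filter(.data$n > 0) %>%
    tidyr::uncount(.data$n)

  n <- nrow(rows)
  ids <- sprintf("W%07d", seq_len(n))
  fill_date <- as.Date("2014-03-01")
  birth_date <- fill_date - round(60 * 365.25) - 100

  patients <- tibble(
    patient_id = ids, sex = "M", race = "White", birth_date = birth_date,
    region = "Northeast", site_id = "S001"
  )
  diagnoses <- tibble(patient_id = ids, code = "427.31", date = fill_date - 200)
  has_egfr <- !is.na(rows$egfr_ge_50)
  labs <- tibble(
    patient_id = ids[has_egfr], analyte = "creatinine",
    value = ifelse(rows$egfr_ge_50[has_egfr], 1.0, 1.6),
    date = fill_date - 30
  )
  vitals <- tibble(
    patient_id = ids, weight_kg = 80, height_cm = 175, date = fill_date - 30
  )

  riva_fill <- function(ids, dose_mg, date) {
    tibble(
      patient_id = ids, drug = "rivaroxaban", dose_mg = dose_mg,
      frequency = "once daily", days_supply = 30L, fill_date = date,
      site_id = "S001"
    )
  }
  other_fill <- function(ids, drug, date) {
    reg <- dose_regimen(rep(drug, length(ids)), rep("FULL", length(ids)))
    tibble(
      patient_id = ids, drug = drug, dose_mg = reg$dose_mg,
      frequency = reg$frequency, days_supply = 30L, fill_date = date,
      site_id = "S001"
    )
  }
  d <- list()
  i1 <- rows$group == "g1"
  d$g1_riva <- riva_fill(ids[i1], ifelse(rows$riva_dose[i1] == "LOW", 15, 20),
    fill_date)
  d$g1_other <- other_fill(ids[i1], "dabigatran", fill_date + 90)
  ff <- rows$riva_dose == "FULL_FIRST"
  i2 <- rows$group == "g2"
  d$g2_first <- riva_fill(ids[i2], ifelse(ff[i2], 20, 15), fill_date)
  d$g2_second <- riva_fill(ids[i2], ifelse(ff[i2], 15, 20), fill_date + 120)
  i3 <- rows$group == "g3"
  d$g3_first <- riva_fill(ids[i3], 20, fill_date)
  d$g3_second <- riva_fill(ids[i3], 15, fill_date + 120)
  d$g3_other <- other_fill(ids[i3], "apixaban", fill_date + 240)
  dispenses <- bind_rows(d) %>% arrange(.data$patient_id, .data$fill_date)

  bundle(patients, diagnoses, labs, vitals, dispenses)
}
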