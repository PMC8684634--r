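#' Partition excluded rivaroxaban-exposed patients
#'
#' Patients excluded from the main cohort for multiple DOACs or multiple
#' dose strengths, restricted to those with at least one rivaroxaban fill,
#' fall into three disjoint groups:
#'
#' * `riva_plus_other`: rivaroxaban at a single dose strength plus at least
#'   one other DOAC;
#' * `both_riva_doses`: both rivaroxaban strengths (20 and 15 mg), no other
#'   DOAC;
#' * `both_doses_plus_other`: both rivaroxaban strengths and another DOAC.
#'
#' Excluded patients with no rivaroxaban fill are ignored by this analysis.
#'
#' @param side_table Dispense rows of the patients excluded at the
#'   multiple-drug/dose/site step (from [apply_exclusions()]).
#' @return List: `membership` (tibble `patient_id`, `group`), `counts`
#'   (tibble `group`, `n`, `percent` of the rivaroxaban-exposed total).
#' @export
partition_excluded_rivaroxaban <- function(side_table) {
  riva <- side_table %>%
    group_by(.data$patient_id) %>%
    summarise(
      any_riva = any(.data$drug == "rivaroxaban"),
      other_doac = any(.data$drug != "rivaroxaban"),
      riva_full = any(.data$drug == "rivaroxaban" & .data$dose_mg == 20),
      riva_low = any(.data$drug == "rivaroxaban" & .data$dose_mg == 15),
      .groups = "drop"
    ) %>%
    filter(.data$any_riva) %>%
    mutate(group = case_when(
      .data$riva_full & .data$riva_low & .data$other_doac ~ "both_doses_plus_other",
      .data$riva_full & .data$riva_low ~ "both_riva_doses",
      TRUE ~ "riva_plus_other"
    ))
  groups <- c("riva_plus_other", "both_riva_doses", "both_doses_plus_other")
  counts <- riva %>%
    count(group = factor(.data$group, levels = groups), .drop = FALSE) %>%
    mutate(percent = percent_of(.data$n, sum(.data$n)))
  list(
    membership = select(riva, "patient_id", "group"),
    counts = counts
  )
}

# index eGFR for switch patients: most recent creatinine on/before first
# rivaroxaban fill, MDRD with the patient's demographics
switch_egfr <- function(patient_ids, dispenses, patients, labs,
                        mdrd_coefficient = 175) {
  idx <- dispenses %>%
    filter(.data$patient_id %in% patient_ids, .data$drug == "rivaroxaban") %>%
    first_fill_dates()
  cr <- labs %>%
    filter(.data$analyte == "creatinine") %>%
    select("patient_id", "value", "date") %>%
    select_index_lab(idx)
  idx %>%
    left_join(cr, by = "patient_id") %>%
    left_join(patients, by = "patient_id") %>%
    mutate(
      age = floor(as.numeric(.data$index_date - .data$birth_date) / 365.25),
      egfr = egfr_mdrd_na(
        .data$value, .data$age, .data$sex == "F", .data$race == "Black",
        coefficient = mdrd_coefficient
      )
    ) %>%
    select("patient_id", "egfr")
}

#' Appropriateness of the rivaroxaban dose among single-dose switchers
#'
#' For the `riva_plus_other` group (one rivaroxaban strength plus another
#' DOAC), judges the rivaroxaban dose against the eGFR < 50 rule at the
#' first rivaroxaban fill. Patients without an index eGFR are tallied as
#' `missing`, not dropped.
#'
#' @param membership Partition membership from
#'   [partition_excluded_rivaroxaban()].
#' @param dispenses,patients,labs EHR tables covering the excluded
#'   patients.
#' @param mdrd_coefficient Passed to the eGFR calculation.
#' @return Tibble `dose` (`LOW`/`FULL`), `appropriate`, `inappropriate`,
#'   `missing_egfr`, `percent_inappropriate` (of those with eGFR).
#' @export
assess_single_dose_switchers <- function(membership, dispenses, patients,
                                         labs, mdrd_coefficient = 175) {
  ids <- membership$patient_id[membership$group == "riva_plus_other"]
  dose <- dispenses %>%
    filter(.data$patient_id %in% ids, .data$drug == "rivaroxaban",
      .data$dose_mg %in% c(15, 20)) %>%
    group_by(.data$patient_id) %>%
    summarise(dose = if (any(.data$dose_mg == 15)) "LOW" else "FULL",
      .groups = "drop")
  eg <- switch_egfr(ids, dispenses, patients, labs, mdrd_coefficient)
  dat <- left_join(dose, eg, by = "patient_id") %>%
    mutate(
      appropriate_dose = ifelse(is.na(.data$egfr), NA,
        ifelse(.data$egfr < 50, "LOW", "FULL"))
    )
  dat %>%
    group_by(.data$dose) %>%
    summarise(
      n = n(),
      appropriate = sum(.data$dose == .data$appropriate_dose, na.rm = TRUE),
      inappropriate = sum(.data$dose != .data$appropriate_dose, na.rm = TRUE),
      missing_egfr = sum(is.na(.data$egfr)),
      .groups = "drop"
    ) %>%
    mutate(percent_inappropriate = percent_of(
      .data$inappropriate, .data$appropriate + .data$inappropriate
    ))
}

#' First-dose order among patients who received both rivaroxaban doses
#'
#' For the `both_riva_doses` group, determines which strength came first
#' (by earliest fill date; if both strengths share the earliest date the
#' higher strength is deemed first and the tie is flagged) and judges that
#' first dose against the eGFR < 50 rule.
#'
#' @inheritParams assess_single_dose_switchers
#' @return List: `order_counts` (tibble `first_dose`, `n`, `percent`,
#'   `n_ties`), `appropriateness` (tibble `first_dose`, `appropriate`,
#'   `inappropriate`, `missing_egfr`).
#' @export
assess_dose_order <- function(membership, dispenses, patients, labs,
                              mdrd_coefficient = 175) {
  ids <- membership$patient_id[membership$group == "both_riva_doses"]
  if (length(ids) == 0) {
    empty <- tibble(
      first_dose = factor(character(), levels = c("FULL", "LOW")),
      n = integer(), n_ties = integer(), percent = numeric()
    )
    return(list(order_counts = empty,
      appropriateness = select(empty, "first_dose")))
  }
  first <- dispenses %>%
    filter(.data$patient_id %in% ids, .data$drug == "rivaroxaban") %>%
    group_by(.data$patient_id) %>%
    summarise(
      first_date = min(.data$fill_date),
      # higher strength wins a same-day tie
      first_dose = ifelse(any(.data$dose_mg == 20 & .data$fill_date == min(.data$fill_date)),
        "FULL", "LOW"),
      tie = all(c(20, 15) %in% .data$dose_mg[.data$fill_date == min(.data$fill_date)]),
      .groups = "drop"
    )
  eg <- switch_egfr(ids, dispenses, patients, labs, mdrd_coefficient)
  dat <- left_join(first, eg, by = "patient_id") %>%
    mutate(appropriate_dose = ifelse(is.na(.data$egfr), NA,
      ifelse(.data$egfr < 50, "LOW", "FULL")))
  order_counts <- dat %>%
    group_by(first_dose = factor(.data$first_dose, levels = c("FULL", "LOW"))) %>%
    summarise(n = n(), n_ties = sum(.data$tie), .groups = "drop") %>%
    tidyr::complete(.data$first_dose, fill = list(n = 0L, n_ties = 0L)) %>%
    mutate(percent = percent_of(.data$n, sum(.data$n)))
  appropriateness <- dat %>%
    group_by(first_dose = factor(.data$first_dose, levels = c("FULL", "LOW"))) %>%
    summarise(
      appropriate = sum(.data$first_dose == .data$appropriate_dose, na.rm = TRUE),
      inappropriate = sum(.data$first_dose != .data$appropriate_dose, na.rm = TRUE),
      missing_egfr = sum(is.na(.data$egfr)),
      .groups = "drop"
    )
  list(order_counts = order_counts, appropriateness = appropriateness)
}
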