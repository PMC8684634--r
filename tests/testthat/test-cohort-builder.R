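make_clean_tables <- function(n = 10) {
  ids <- sprintf("C%03d", seq_len(n))
  list(
    patients = dplyr::bind_rows(lapply(ids, one_patient)),
    diagnoses = dplyr::bind_rows(lapply(ids, dx, code = "427.31")),
    labs = dplyr::bind_rows(lapply(ids, lab, value = 1.0, date = "2013-06-01")),
    vitals = dplyr::bind_rows(lapply(ids, vital)),
    dispenses = dplyr::bind_rows(lapply(
      ids, fill,
      drug = "dabigatran", dose_mg = 150, frequency = "twice daily",
      fill_date = "2013-07-01"
    ))
  )
}

test_that("NVAF identification requires an AF code and no valvular code", {
  d <- dplyr::bind_rows(
    dx("P1", "427.31"),
    dx("P2", "I48.0"), dx("P2", "I05.1"), # valvular -> excluded
    dx("P3", "401.9") # no AF code
  )
  expect_equal(identify_nvaf(d), "P1")
  bad_map <- dplyr::filter(default_code_map(), class != "valvular")
  expect_error(identify_nvaf(d, bad_map), class = "doacaudit_config_error")
})

test_that("a clean cohort passes every step with zero exclusions", {
  t <- make_clean_tables(10)
  ex <- apply_exclusions(t$patients, t$diagnoses, t$labs, t$vitals, t$dispenses)
  expect_equal(nrow(ex$cohort), 10)
  steps <- ex$exclusion_log[-1, ]
  expect_true(all(steps$n_excluded == 0))
  expect_equal(ex$exclusion_log$n_remaining[nrow(ex$exclusion_log)], 10)
})

test_that("each exclusion step catches its own failure mode", {
  t <- make_clean_tables(8)
  # C001: under 30 days total supply
  t$dispenses$days_supply[t$dispenses$patient_id == "C001"] <- 20L
  # C002: VTE code
  t$diagnoses <- dplyr::bind_rows(t$diagnoses, dx("C002", "415.19"))
  # C003: both dabigatran dose strengths -> step 3, retained for switch
  t$dispenses <- dplyr::bind_rows(
    t$dispenses,
    fill("C003", "dabigatran", 75, "twice daily", "2013-09-01")
  )
  # C004: fills at two sites
  t$dispenses <- dplyr::bind_rows(
    t$dispenses,
    fill("C004", "dabigatran", 150, "twice daily", "2013-09-01", site_id = "S002")
  )
  # C005: only an unclassifiable regimen
  t$dispenses$dose_mg[t$dispenses$patient_id == "C005"] <- 110
  # C006: missing race
  t$patients$race[t$patients$patient_id == "C006"] <- NA
  # C007: creatinine only after the fill
  t$labs$date[t$labs$patient_id == "C007"] <- as.Date("2013-08-01")

  ex <- apply_exclusions(t$patients, t$diagnoses, t$labs, t$vitals, t$dispenses)
  log <- ex$exclusion_log
  got <- setNames(log$n_excluded, log$step)
  expect_equal(got[["supply_lt_30"]], 1L)
  expect_equal(got[["vte_code"]], 1L)
  expect_equal(got[["multiple_drug_dose_site"]], 2L)
  expect_equal(got[["other_dose_only"]], 1L)
  expect_equal(got[["missing_demographics"]], 1L)
  expect_equal(got[["missing_clinical"]], 1L)
  expect_equal(ex$cohort$patient_id, "C008")
  # side table holds the multi-dose patient's fills
  expect_setequal(unique(ex$switch_side$patient_id), c("C003", "C004"))
  # waterfall conservation: initial N = final + sum of exclusions
  expect_equal(
    log$n_remaining[1],
    log$n_remaining[nrow(log)] + sum(log$n_excluded, na.rm = TRUE)
  )
  expect_true(all(diff(log$n_remaining) <= 0))
})

test_that("apixaban patients additionally require an index weight", {
  t <- make_clean_tables(2)
  t$dispenses$drug <- "apixaban"
  t$dispenses$dose_mg <- 5
  t$vitals <- t$vitals[t$vitals$patient_id != "C001", ]
  ex <- apply_exclusions(t$patients, t$diagnoses, t$labs, t$vitals, t$dispenses)
  expect_equal(ex$cohort$patient_id, "C002")
  log <- ex$exclusion_log
  expect_equal(log$n_excluded[log$step == "missing_clinical"], 1L)
})

test_that("site assignment is unique and guards its precondition", {
  d <- fill("P1", "dabigatran", 150, "twice daily", "2013-01-01")
  expect_equal(assign_site(d)$site_id, "S001")
  d2 <- dplyr::bind_rows(
    d, fill("P1", "dabigatran", 150, "twice daily", "2013-02-01", site_id = "S002")
  )
  expect_error(assign_site(d2), class = "doacaudit_internal_error")
  expect_error(assign_site(d[0, ]), class = "doacaudit_data_error")
})

test_that("exclusion order changes step counts but not final membership", {
  # a patient failing both supply and VTE is counted once, at the first step
  t <- make_clean_tables(3)
  t$dispenses$days_supply[t$dispenses$patient_id == "C001"] <- 10L
  t$diagnoses <- dplyr::bind_rows(t$diagnoses, dx("C001", "I26.0"))
  ex <- apply_exclusions(t$patients, t$diagnoses, t$labs, t$vitals, t$dispenses)
  log <- ex$exclusion_log
  expect_equal(log$n_excluded[log$step == "supply_lt_30"], 1L)
  expect_equal(log$n_excluded[log$step == "vte_code"], 0L)
  expect_setequal(ex$cohort$patient_id, c("C002", "C003"))
})
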