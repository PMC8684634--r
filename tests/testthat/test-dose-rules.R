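test_that("dispense classification covers the defined regimens exactly", {
  expect_equal(classify_dispense("dabigatran", 150, "twice daily"), "FULL")
  expect_equal(classify_dispense("dabigatran", 75, "BID"), "LOW")
  expect_equal(classify_dispense("dabigatran", 110, "twice daily"), "OTHER")
  expect_equal(classify_dispense("rivaroxaban", 20, "once daily"), "FULL")
  expect_equal(classify_dispense("rivaroxaban", 15, "QD"), "LOW")
  expect_equal(classify_dispense("rivaroxaban", 10, "once daily"), "OTHER")
  expect_equal(classify_dispense("apixaban", 5, "twice daily"), "FULL")
  expect_equal(classify_dispense("apixaban", 2.5, "twice daily"), "LOW")
  # right dose at the wrong frequency is not a defined regimen
  expect_equal(classify_dispense("rivaroxaban", 20, "twice daily"), "OTHER")
  expect_error(classify_dispense("warfarin", 5, "once daily"),
    class = "doacaudit_data_error")
})

test_that("renal thresholds are strict inequalities as printed", {
  expect_equal(recommend_dose("dabigatran", egfr = 29.999), "LOW")
  expect_equal(recommend_dose("dabigatran", egfr = 30), "FULL")
  expect_equal(recommend_dose("dabigatran", egfr = 30.001), "FULL")
  expect_equal(recommend_dose("rivaroxaban", egfr = 49.999), "LOW")
  expect_equal(recommend_dose("rivaroxaban", egfr = 50), "FULL")
  # dabigatran tolerates eGFR in [30, 50) that rivaroxaban does not
  expect_equal(recommend_dose("dabigatran", egfr = 45), "FULL")
  expect_equal(recommend_dose("rivaroxaban", egfr = 45), "LOW")
  expect_error(recommend_dose("dabigatran"), "egfr",
    class = "doacaudit_data_error")
})

test_that("apixaban rule needs two of three inclusive criteria", {
  expect_equal(
    recommend_dose("apixaban", age = 81, weight_kg = 59, creatinine = 1.2),
    "LOW"
  )
  expect_equal(
    recommend_dose("apixaban", age = 81, weight_kg = 61, creatinine = 1.2),
    "FULL"
  )
  # every boundary is inclusive: age 80, weight 60, creatinine 1.5 all count
  expect_equal(
    recommend_dose("apixaban", age = 80, weight_kg = 60, creatinine = 1.0),
    "LOW"
  )
  expect_equal(
    recommend_dose("apixaban", age = 79, weight_kg = 60.001, creatinine = 1.5),
    "FULL"
  )
  expect_equal(
    recommend_dose("apixaban", age = 79, weight_kg = 60, creatinine = 1.499),
    "FULL"
  )
  expect_error(
    recommend_dose("apixaban", age = 80, weight_kg = NA, creatinine = 1),
    "weight_kg",
    class = "doacaudit_data_error"
  )
})

test_that("the eight apixaban groups partition every flag combination", {
  crit <- apixaban_criteria(85, 55, 1.8)
  expect_equal(as.character(crit$group), "all_three")
  expect_equal(as.character(apixaban_criteria(70, 80, 1.0)$group), "none")
  expect_equal(as.character(apixaban_criteria(80, 60, 1.4)$group), "age_weight")
  expect_equal(as.character(apixaban_criteria(80, 70, 1.5)$group), "age_creatinine")
  expect_equal(as.character(apixaban_criteria(65, 52, 1.6)$group), "weight_creatinine")

  grid <- expand.grid(
    age = c(79, 80), weight = c(60, 60.001), cr = c(1.499, 1.5)
  )
  g <- apixaban_criteria(grid$age, grid$weight, grid$cr)
  expect_equal(sort(as.character(g$group)), sort(APIXABAN_GROUPS))
  # n_criteria >= 2 exactly in the four low-dose groups
  expect_setequal(
    as.character(g$group[g$n_criteria >= 2]),
    c("all_three", "age_weight", "age_creatinine", "weight_creatinine")
  )
})

test_that("recommendation is deterministic and monotone in its inputs", {
  eg <- runif(200, 5, 120)
  r1 <- recommend_dose(rep("rivaroxaban", 200), egfr = eg)
  r2 <- recommend_dose(rep("rivaroxaban", 200), egfr = eg)
  expect_identical(r1, r2)
  # lowering eGFR never flips LOW -> FULL
  low_idx <- which(r1 == "LOW")
  if (length(low_idx) > 0) {
    r3 <- recommend_dose(rep("rivaroxaban", length(low_idx)),
      egfr = eg[low_idx] - 5)
    expect_true(all(r3 == "LOW"))
  }
  # adding an apixaban criterion never flips LOW -> FULL
  base <- apixaban_criteria(81, 59, 1.0) # two criteria -> LOW
  stopifnot(base$n_criteria == 2)
  expect_equal(
    recommend_dose("apixaban", age = 81, weight_kg = 59, creatinine = 1.6),
    "LOW"
  )
})

test_that("cohort assessment joins facts, rules, and criteria groups", {
  pats <- dplyr::bind_rows(one_patient("P1"), one_patient("P2"))
  # P1: full-dose rivaroxaban with eGFR ~44 -> recommended LOW, discordant
  # P2: low-dose dabigatran with eGFR ~27 -> concordant
  disp <- dplyr::bind_rows(
    fill("P1", "rivaroxaban", 20, "once daily", "2014-03-01"),
    fill("P2", "dabigatran", 75, "twice daily", "2014-05-01")
  )
  labs <- dplyr::bind_rows(
    lab("P1", 1.6, "2014-02-01"), lab("P2", 2.5, "2014-04-01")
  )
  vit <- dplyr::bind_rows(vital("P1"), vital("P2"))
  diag <- dplyr::bind_rows(dx("P1", "427.31"), dx("P2", "427.31"))
  idx <- tibble::tibble(
    patient_id = c("P1", "P2"),
    index_date = as.Date(c("2014-03-01", "2014-05-01"))
  )
  panel <- build_score_panel(pats, diag, labs, vit, idx)
  a <- assess_cohort(disp, panel)
  a <- a[order(a$patient_id), ]
  expect_equal(a$received, c("FULL", "LOW"))
  expect_equal(a$recommended, c("LOW", "LOW"))
  expect_equal(a$concordant, c(FALSE, TRUE))
  expect_equal(a$year, c(2014L, 2014L))
  expect_true(all(is.na(a$apixaban_group)))
  # empty cohort -> empty assessment
  expect_equal(nrow(assess_cohort(disp[0, ], panel)), 0)
})
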