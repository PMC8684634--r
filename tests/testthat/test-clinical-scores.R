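test_that("MDRD eGFR matches hand-evaluated closed form and multipliers", {
  # 175 * 1.0^-1.154 * 60^-0.203 = 76.22 (hand evaluation)
  expect_equal(egfr_mdrd(1.0, 60, FALSE, FALSE), 76.2, tolerance = 1e-3)
  # female and Black multipliers are exact factors
  base <- egfr_mdrd(1.3, 72, FALSE, FALSE)
  expect_identical(egfr_mdrd(1.3, 72, TRUE, FALSE), 0.742 * base)
  expect_identical(egfr_mdrd(1.3, 72, FALSE, TRUE), 1.212 * base)
  # original-assay variant
  expect_equal(
    egfr_mdrd(1, 60, FALSE, FALSE, coefficient = 186) /
      egfr_mdrd(1, 60, FALSE, FALSE),
    186 / 175
  )
})

test_that("eGFR is strictly decreasing in creatinine and age", {
  cr <- seq(0.5, 5, by = 0.25)
  expect_true(all(diff(egfr_mdrd(cr, 60, FALSE, FALSE)) < 0))
  ages <- seq(30, 95, by = 5)
  expect_true(all(diff(egfr_mdrd(1.2, ages, FALSE, FALSE)) < 0))
  expect_error(egfr_mdrd(0, 60, FALSE, FALSE), class = "doacaudit_domain_error")
  expect_error(egfr_mdrd(1, -1, FALSE, FALSE), class = "doacaudit_domain_error")
})

test_that("creatinine_for_egfr inverts the MDRD equation", {
  for (eg in c(25, 45, 70, 100)) {
    cr <- creatinine_for_egfr(eg, 71, TRUE, FALSE)
    expect_equal(egfr_mdrd(cr, 71, TRUE, FALSE), eg, tolerance = 1e-12)
  }
})

test_that("index lab selection takes the most recent value on/before index", {
  idx <- tibble::tibble(patient_id = "P1", index_date = as.Date("2014-01-01"))
  labs <- lab("P1", c(2.0, 1.1, 0.9),
    c("2012-11-27", "2013-12-02", "2014-01-06")) # -400, -30, +5 days
  sel <- select_index_lab(labs, idx)
  expect_equal(sel$value, 1.1)
  expect_equal(sel$date, as.Date("2013-12-02"))
  # same-day lab counts; tie on date broken by the larger creatinine
  labs2 <- lab("P1", c(1.0, 1.4), c("2014-01-01", "2014-01-01"))
  expect_equal(select_index_lab(labs2, idx)$value, 1.4)
  # nothing before index -> patient absent
  labs3 <- lab("P1", 1.0, "2014-02-01")
  expect_equal(nrow(select_index_lab(labs3, idx)), 0)
})

test_that("CHA2DS2-VASc sums the published point values and is bounded", {
  expect_equal(chads_vasc(50, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), 0L)
  # female (1) + age 76 (2) + hypertension (1) = 4
  expect_equal(chads_vasc(76, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE), 4L)
  # age 70 (1) + diabetes (1) + stroke (2) = 4
  expect_equal(chads_vasc(70, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE), 4L)
  # maximum attainable score is 9
  expect_equal(chads_vasc(80, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE), 9L)
  # adding any single condition never decreases the score
  base <- chads_vasc(68, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  for (i in 1:5) {
    args <- as.list(rep(FALSE, 5))
    args[[i]] <- TRUE
    with_one <- do.call(chads_vasc, c(list(68, FALSE), args))
    expect_gte(with_one, base)
  }
})

test_that("Elixhauser count is over distinct conditions, duplicates ignored", {
  cm <- default_code_map()
  idx <- tibble::tibble(patient_id = c("P1", "P2"),
    index_date = as.Date("2014-01-01"))
  d <- dplyr::bind_rows(
    dx("P1", "496.1"), # copd (prefix 496)
    dx("P1", "J44.9"), # copd again, different coding system
    dx("P1", "571.5"), # liver
    dx("P1", "N18.3"), # renal
    dx("P1", "428.0") # heart failure: stroke-risk class, not Elixhauser here
  )
  res <- count_elixhauser(d, cm, idx)
  expect_equal(res$elixhauser_count[res$patient_id == "P1"], 3L)
  expect_equal(res$elixhauser_count[res$patient_id == "P2"], 0L)
  expect_equal(as.character(res$elixhauser_category), c("3-4", "0-2"))
  # codes after index never count
  late <- count_elixhauser(dx("P2", "496.1", "2015-01-01"), cm, idx)
  expect_equal(late$elixhauser_count[late$patient_id == "P2"], 0L)
})

test_that("BMI and its bins follow left-closed boundaries", {
  expect_equal(compute_bmi(80, 200), 20)
  expect_equal(round(compute_bmi(97.5, 170), 1), 33.7)
  expect_equal(as.character(bmi_category(compute_bmi(97.5, 170))), "30-34.9")
  expect_equal(as.character(bmi_category(25)), "25-29.9")
  expect_equal(as.character(bmi_category(24.999)), "<25")
  expect_error(compute_bmi(-1, 170), class = "doacaudit_domain_error")
})

test_that("category bins partition their domains", {
  egfr <- runif(500, 1, 150)
  expect_false(anyNA(egfr_category(egfr)))
  bmi <- runif(500, 10, 70)
  expect_false(anyNA(bmi_category(bmi)))
  ages <- sample(18:105, 200, replace = TRUE)
  expect_false(anyNA(age_category(ages)))
  counts <- sample(0:12, 200, replace = TRUE)
  expect_false(anyNA(elixhauser_category(counts)))
  # audit bins at the published boundaries
  expect_equal(as.character(egfr_category(c(29.9, 30, 44.9, 45, 60))),
    c("<30", "30-44", "30-44", "45-59", ">=60"))
})
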