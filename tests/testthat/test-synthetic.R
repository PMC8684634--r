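test_that("generation is deterministic given config and seed", {
  cfg <- sim_config(300, seed = 5)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  for (tbl in c("patients", "diagnoses", "labs", "vitals", "dispenses")) {
    expect_identical(b1[[tbl]], b2[[tbl]])
  }
  b3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(b1$patients, b3$patients))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(0), class = "doacaudit_config_error")
  expect_error(sim_config(10, n_sites = 0), class = "doacaudit_config_error")
  expect_error(
    sim_config(10, drug_shares = c(dabigatran = 0.5, rivaroxaban = 0.5, apixaban = 0.1)),
    class = "doacaudit_config_error"
  )
  m <- default_marginals()
  m$comorbidity["diabetes"] <- 1.2
  expect_error(sim_config(10, marginals = m), class = "doacaudit_config_error")
})

test_that("zero missing-lab fraction gives every patient an index creatinine", {
  cfg <- sim_config(400, seed = 2, missing_lab_fraction = 0)
  b <- generate_cohort(cfg)
  idx <- dplyr::summarise(dplyr::group_by(b$dispenses, patient_id),
    index_date = min(fill_date), .groups = "drop")
  sel <- select_index_lab(
    dplyr::select(b$labs, patient_id, value, date), idx
  )
  expect_setequal(sel$patient_id, b$patients$patient_id)
  # and a half-missing config loses about half
  cfg2 <- sim_config(400, seed = 2, missing_lab_fraction = 0.5)
  b2 <- generate_cohort(cfg2)
  expect_lt(length(unique(b2$labs$patient_id)), 300)
})

test_that("degenerate discordance probabilities behave as limits", {
  m0 <- discordance_model(intercept = -Inf,
    coefficients = list(recommended = c(FULL = 0, LOW = 0)))
  cfg <- sim_config(500, seed = 3, discordance_model = m0)
  b <- generate_cohort(cfg)
  expect_true(all(b$truth$received == b$truth$recommended))
  a <- run_audit(b)
  expect_true(all(a$assessments$concordant))

  m1 <- discordance_model(intercept = Inf,
    coefficients = list(recommended = c(FULL = 0, LOW = 0)))
  b1 <- generate_cohort(sim_config(200, seed = 3, discordance_model = m1))
  expect_true(all(b1$truth$received != b1$truth$recommended))
})

test_that("flat discordance model reproduces its binomial rate", {
  m <- discordance_model(intercept = qlogis(0.1),
    coefficients = list(recommended = c(FULL = 0, LOW = 0)))
  cov <- tibble::tibble(recommended = rep("FULL", 10000))
  rec <- cov$recommended
  recv <- inject_discordance(rec, cov, m, seed = 11)
  p_hat <- mean(recv != rec)
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("a covariate bin absent from the model is an error naming it", {
  m <- discordance_model(intercept = 0,
    coefficients = list(age_bin = c("<=69" = 0)))
  cov <- tibble::tibble(age_bin = c("<=69", "80+"))
  expect_error(
    inject_discordance(c("FULL", "FULL"), cov, m),
    "80\\+",
    class = "doacaudit_config_error"
  )
})

test_that("generated marginals match the configured ones within 3 SE", {
  n <- 10000
  cfg <- sim_config(n, seed = 9)
  b <- generate_cohort(cfg)
  a <- run_audit(b)
  m <- cfg$marginals
  tol <- function(p) 3 * sqrt(p * (1 - p) / n)

  sex_p <- mean(b$patients$sex == "F")
  expect_lt(abs(sex_p - m$female), tol(m$female))
  for (r in names(m$race)) {
    expect_lt(abs(mean(b$patients$race == r) - m$race[[r]]), tol(m$race[[r]]))
  }
  age_counts <- table(a$panel$age_category) / nrow(a$panel)
  expect_lt(abs(age_counts[["<65"]] - 0.16), tol(0.16) + 0.01)
  expect_lt(abs(age_counts[["65-74"]] - 0.44), tol(0.44) + 0.01)
  egfr_counts <- table(a$panel$egfr_category) / nrow(a$panel)
  for (i in seq_along(m$egfr$probs)) {
    p <- m$egfr$probs[i]
    expect_lt(abs(egfr_counts[[i]] - p), tol(p) + 0.005)
  }
  bmi_counts <- table(a$panel$bmi_category) / nrow(a$panel)
  for (i in seq_along(m$bmi$probs)) {
    p <- m$bmi$probs[i]
    expect_lt(abs(bmi_counts[[i]] - p), tol(p) + 0.005)
  }
})

test_that("the audit reproduces the generator's truth labels exactly", {
  cfg <- sim_config(3000, seed = 21)
  b <- generate_cohort(cfg)
  a <- run_audit(b)
  tr <- dplyr::inner_join(a$assessments, b$truth, by = "patient_id",
    suffix = c("", ".truth"))
  expect_equal(nrow(tr), nrow(a$assessments))
  expect_identical(tr$recommended, tr$recommended.truth)
  expect_identical(tr$received, tr$received.truth)
  expect_identical(tr$year, as.integer(tr$year.truth))
})

test_that("switch scenario routes rivaroxaban switchers to the side table", {
  cfg <- sim_config(2000, seed = 13, switch_scenario = TRUE, switch_fraction = 0.3)
  b <- generate_cohort(cfg)
  a <- run_audit(b)
  expect_gt(nrow(a$switch_side), 0)
  part <- partition_excluded_rivaroxaban(a$switch_side)
  expect_gt(sum(part$counts$n), 0)
  expect_equal(
    sum(part$counts$n),
    length(unique(a$switch_side$patient_id[
      a$switch_side$drug == "rivaroxaban"
    ]))
  )
})
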