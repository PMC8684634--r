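test_that("covariate binning follows the published bin layouts", {
  spec <- default_covariate_spec("dabigatran", "low_given_full")
  panel <- tibble::tibble(
    age = c(69, 70, 80, 91), sex = "M", race = "White", region = "South",
    bmi = c(24, 25, 33, 40), egfr = c(35, 49.9, 60, 95),
    heart_failure = FALSE, hypertension = TRUE, vascular_disease = FALSE,
    diabetes = FALSE, prior_bleeding = FALSE, stroke = FALSE,
    elixhauser_category = factor("0-2", levels = c("0-2", "3-4", ">=5"))
  )
  binned <- bin_covariates(panel, spec)
  expect_equal(as.character(binned$egfr), c("30-39", "40-49", "60+", "60+"))
  expect_equal(as.character(binned$age), c("<=69", "70-74", "80+", "80+"))
  expect_equal(as.character(binned$bmi), c("<25", "25-29.9", "30-34.9", ">=35"))
  expect_equal(levels(binned$age)[1], "<=69") # reference first

  apix <- default_covariate_spec("apixaban", "low_given_full", group = "none")
  p2 <- dplyr::mutate(panel[1, ], weight_kg = 65, creatinine = 1.35)
  b2 <- bin_covariates(p2, apix)
  expect_equal(as.character(b2$creatinine), "1.3-1.49")
  expect_equal(as.character(b2$weight), "61-69")

  # bins must partition: a value outside every bin errors, naming the covariate
  p3 <- dplyr::mutate(panel[1, ], egfr = 25) # below the recommended-full range
  expect_error(bin_covariates(p3, spec), "egfr", class = "doacaudit_data_error")
})

test_that("single binary covariate fit equals the ad/bc odds ratio", {
  # contingency table: exposed 40/160, unexposed 25/400 -> OR = 40*400/(160*25)
  a <- 40; b <- 160; c <- 25; d <- 400
  dat <- tibble::tibble(
    exposed = factor(c(rep("yes", a + b), rep("no", c + d)), levels = c("no", "yes")),
    discordant = c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  )
  f <- fit_discordance_model(dat)
  aor <- f$terms$aor[f$terms$level == "yes"]
  expect_equal(aor, a * d / (b * c), tolerance = 1e-7)
  expect_equal(f$terms$aor[f$terms$level == "no"], 1)
  expect_true(f$terms$reference[f$terms$level == "no"])
  # CI straddles the point estimate
  expect_lt(f$terms$ci_low[f$terms$level == "yes"], aor)
  expect_gt(f$terms$ci_high[f$terms$level == "yes"], aor)
})

test_that("degenerate fits fail loudly with the culprit named", {
  dat <- tibble::tibble(
    exposed = factor(rep("yes", 10), levels = c("no", "yes")),
    discordant = rep(c(TRUE, FALSE), 5)
  )
  expect_error(fit_discordance_model(dat), "no", class = "doacaudit_data_error")
  dat2 <- tibble::tibble(
    exposed = factor(rep(c("no", "yes"), each = 5), levels = c("no", "yes")),
    discordant = rep(FALSE, 10)
  )
  expect_error(fit_discordance_model(dat2), class = "doacaudit_data_error")
  # complete separation
  dat3 <- tibble::tibble(
    exposed = factor(rep(c("no", "yes"), each = 50), levels = c("no", "yes")),
    discordant = rep(c(FALSE, TRUE), each = 50)
  )
  expect_error(fit_discordance_model(dat3), class = "doacaudit_numeric_error")
})

test_that("c-statistic is rank-based and monotone-invariant", {
  set.seed(1)
  y <- rep(c(TRUE, FALSE), each = 100)
  s <- ifelse(y, rnorm(200, 1), rnorm(200, 0))
  c1 <- c_statistic(s, y)
  expect_gt(c1, 0.5)
  expect_equal(c_statistic(plogis(3 * s - 1), y), c1)
  expect_equal(c_statistic(rank(s), y), c1)
  # perfect and random separation limits
  expect_equal(c_statistic(as.numeric(y), y), 1)
  expect_equal(c_statistic(rep(0.5, 200), y), 0.5)
})

test_that("run_all_models covers both directions and flags inestimable strata", {
  cfg <- sim_config(6000, seed = 31)
  b <- generate_cohort(cfg)
  a <- run_audit(b)
  res <- run_all_models(a$assessments, a$panel)
  expect_setequal(unique(res$direction), c("low_given_full", "full_given_low"))
  # the big recommended-full strata must be estimable at this size
  dab <- res[res$direction == "low_given_full" & res$drug == "dabigatran", ]
  expect_equal(dab$status, "fitted")
  fit <- dab$result[[1]]
  expect_true(all(fit$terms$aor[fit$terms$reference] == 1))
  expect_true(fit$c_statistic > 0.5 && fit$c_statistic <= 1)
  # skipped strata say why
  skipped <- res[res$status == "skipped", ]
  expect_true(all(!is.na(skipped$reason)))
  # apixaban recommended-full models come only from no/one-criterion groups
  apix <- res[res$drug == "apixaban" & res$direction == "low_given_full", ]
  expect_setequal(apix$group,
    c("none", "age_only", "weight_only", "creatinine_only"))
})
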