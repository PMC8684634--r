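#' Default marginal distributions for the synthetic EHR generator
#'
#' Marginals emulating the published characteristics of the national VA
#' DOAC cohort: age, sex, race, region, BMI, eGFR-category and comorbidity
#' prevalences, plus fill-volume weights by calendar year that grow the way
#' DOAC uptake grew over 2010-2016. Categorical probabilities are
#' normalised to sum to 1 (the published BMI column sums to 106% as
#' printed; normalisation preserves the ratios).
#'
#' @return Named list of marginal definitions consumed by [sim_config()].
#' @export
default_marginals <- function() {
  list(
    age = list(breaks = c(40, 65, 75, 85, 100), probs = c(0.16, 0.44, 0.27, 0.13)),
    female = 0.02,
    race = c(White = 0.86, Black = 0.08, Other = 0.06),
    region = c(Northeast = 0.14, Midwest = 0.24, West = 0.22, South = 0.40),
    bmi = list(
      breaks = c(17, 25, 30, 35, 45),
      probs = c(0.19, 0.33, 0.26, 0.28) / sum(c(0.19, 0.33, 0.26, 0.28))
    ),
    egfr = list(breaks = c(15, 30, 45, 60, 120), probs = c(0.02, 0.09, 0.15, 0.74)),
    height = list(male = c(mean = 176, sd = 7), female = c(mean = 163, sd = 6)),
    comorbidity = c(
      heart_failure = 0.15, hypertension = 0.73, vascular_disease = 0.17,
      diabetes = 0.48, prior_bleeding = 0.04, stroke = 0.07
    ),
    elixhauser = c("0-2" = 0.30, "3-4" = 0.41, ">=5" = 0.29),
    year_weights = c(
      "2010" = 92, "2011" = 1635, "2012" = 2860, "2013" = 3958,
      "2014" = 9791, "2015" = 18345, "2016" = 31327
    )
  )
}

#' Default covariate-dependent discordance model
#'
#' The data-generating model for receiving the non-recommended dose:
#' log-odds are an intercept plus per-bin offsets. The default makes
#' discordance more likely for older patients, for renal function just
#' above a dose-reduction cutoff, and much more likely (in relative terms)
#' among patients recommended the low dose — the pattern seen in published
#' audits.
#'
#' @param intercept Baseline log-odds of discordance (reference bins).
#' @param coefficients Named list: covariate name -> named numeric vector of
#'   per-level log-odds offsets. Every level a generated patient can occupy
#'   must be present (use explicit zeros).
#' @return List of class `doacaudit_discordance_model`.
#' @export
discordance_model <- function(intercept = qlogis(0.02),
                              coefficients = list(
                                recommended = c(FULL = 0, LOW = 0.5),
                                age_bin = c("<=69" = 0, "70-74" = log(1.5),
                                  "75-79" = log(2.5), "80+" = log(5)),
                                egfr_bin = c("<30" = log(2), "30-39" = log(6),
                                  "40-49" = log(3), "50-59" = log(2.5), "60+" = 0)
                              )) {
  structure(list(intercept = intercept, coefficients = coefficients),
    class = "doacaudit_discordance_model"
  )
}

#' Simulation configuration
#'
#' Validated configuration for [generate_cohort()].
#'
#' @param n_patients Number of patients (positive).
#' @param n_sites Number of sites (>= 1).
#' @param year_range Inclusive first-fill year interval, default
#'   `c(2010, 2016)`.
#' @param drug_shares Probability simplex over the three DOACs; must sum to
#'   1 within 1e-9. The default approximates the published cohort
#'   composition. Shares are renormalised within each year over the drugs
#'   already on the market that year (dabigatran 2010, rivaroxaban 2012,
#'   apixaban 2013).
#' @param marginals See [default_marginals()].
#' @param discordance_model See [discordance_model()].
#' @param site_effects Per-site log-odds offsets added to the discordance
#'   model; either `NULL` (all zero), a single number (the SD of seeded
#'   normal draws), or a numeric vector of length `n_sites`.
#' @param missing_lab_fraction Fraction of patients generated without any
#'   pre-fill creatinine (they hit the missing-data exclusion).
#' @param extra_lab_fraction Fraction of patients given an additional,
#'   older creatinine (exercises index-lab selection).
#' @param switch_scenario If `TRUE`, a `switch_fraction` of rivaroxaban
#'   patients receive a second, different regimen so they flow into the
#'   switch analysis.
#' @param switch_fraction Fraction used when `switch_scenario` is on.
#' @param seed Integer seed; identical config and seed give byte-identical
#'   tables.
#' @return List of class `doacaudit_sim_config`.
#' @export
sim_config <- function(n_patients, n_sites = 10, year_range = c(2010, 2016),
                       drug_shares = c(dabigatran = 0.36, rivaroxaban = 0.24,
                         apixaban = 0.40),
                       marginals = default_marginals(),
                       discordance_model = doacaudit::discordance_model(),
                       site_effects = NULL,
                       missing_lab_fraction = 0,
                       extra_lab_fraction = 0.3,
                       switch_scenario = FALSE,
                       switch_fraction = 0.1,
                       seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("n_patients must be a positive count", class = "doacaudit_config_error")
  }
  if (!is.numeric(n_sites) || n_sites < 1) {
    abort("n_sites must be >= 1", class = "doacaudit_config_error")
  }
  if (abs(sum(drug_shares) - 1) > 1e-9 || any(drug_shares < 0)) {
    abort("drug_shares must be a probability simplex summing to 1 (tol 1e-9)",
      class = "doacaudit_config_error"
    )
  }
  if (!all(names(drug_shares) %in% DOAC_DRUGS)) {
    abort("drug_shares must be named by the three DOACs",
      class = "doacaudit_config_error"
    )
  }
  prev <- marginals$comorbidity
  if (any(prev < 0 | prev > 1)) {
    abort("comorbidity prevalences must be in [0, 1]",
      class = "doacaudit_config_error"
    )
  }
  for (frac in c(missing_lab_fraction, extra_lab_fraction, marginals$female)) {
    if (frac < 0 || frac > 1) {
      abort("fractions must be in [0, 1]", class = "doacaudit_config_error")
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_sites = as.integer(n_sites),
      year_range = as.integer(year_range), drug_shares = drug_shares,
      marginals = marginals, discordance_model = discordance_model,
      site_effects = site_effects,
      missing_lab_fraction = missing_lab_fraction,
      extra_lab_fraction = extra_lab_fraction,
      switch_scenario = switch_scenario, switch_fraction = switch_fraction,
      seed = as.integer(seed)
    ),
    class = "doacaudit_sim_config"
  )
}

sample_bin <- function(n, breaks, probs, margin = 0.25) {
  k <- length(probs)
  bin <- sample.int(k, n, replace = TRUE, prob = probs)
  lo <- breaks[bin] + margin
  hi <- breaks[bin + 1] - margin
  runif(n, lo, hi)
}

# concrete code emitting a match for a condition's first pattern
condition_code <- function(code_map, condition) {
  row <- code_map[code_map$condition == condition, ][1, ]
  if (row$prefix) paste0(row$pattern, ".0") else row$pattern
}

#' Generate a synthetic EHR table bundle
#'
#' Draws a DOAC-treated NVAF cohort with the configured marginals, then the
#' five EHR tables the audit consumes. Covariates are drawn independently
#' except two coupled blocks: (weight, height, BMI) and (creatinine, age,
#' sex, race, eGFR) — creatinine is obtained by inverting the MDRD equation
#' at a sampled eGFR so that renal categories, the emitted labs, and the
#' dose rules stay internally consistent. Each patient's recommended dose
#' follows from their covariates; the received dose then flips to the
#' non-recommended regimen with probability
#' `plogis(intercept + sum(bin offsets) + site offset)` via
#' [inject_discordance()].
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return List of class `doacaudit_bundle`: tibbles `patients`,
#'   `diagnoses`, `labs`, `vitals`, `dispenses`, plus `truth` (per-patient
#'   recommended/received/probability — for tests, never consumed by the
#'   audit) and `provenance` (seed and config echo).
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "doacaudit_sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  withr::with_seed(seed, generate_cohort_impl(config, seed))
}

generate_cohort_impl <- function(config, seed) {
  n <- config$n_patients
  m <- config$marginals
  code_map <- default_code_map()
  ids <- sprintf("P%07d", seq_len(n))

  female <- runif(n) < m$female
  race <- sample(names(m$race), n, replace = TRUE, prob = m$race)
  region <- sample(names(m$region), n, replace = TRUE, prob = m$region)
  site_idx <- sample.int(config$n_sites, n, replace = TRUE)
  site_id <- sprintf("S%03d", site_idx)

  years <- seq(config$year_range[1], config$year_range[2])
  yw <- m$year_weights[as.character(years)]
  yw[is.na(yw)] <- 1
  year <- sample(years, n, replace = TRUE, prob = yw)
  fill_date <- as.Date(paste0(year, "-01-01")) + sample.int(365, n, replace = TRUE) - 1

  # drug by year-restricted shares
  drug <- character(n)
  for (y in unique(year)) {
    idx <- which(year == y)
    avail <- DOAC_DRUGS[DRUG_START_YEAR <= y]
    if (length(avail) == 0) {
      abort(paste0("no DOAC on the market in ", y), class = "doacaudit_config_error")
    }
    p <- config$drug_shares[avail] / sum(config$drug_shares[avail])
    drug[idx] <- sample(avail, length(idx), replace = TRUE, prob = p)
  }

  # age derived exactly as the audit derives it (floor of years before fill)
  age_exact <- sample_bin(n, m$age$breaks, m$age$probs, margin = 0.1)
  birth_date <- fill_date - round(age_exact * 365.25)
  age <- floor(as.numeric(fill_date - birth_date) / 365.25)

  # coupled block: height -> BMI -> weight
  height <- round(rnorm(
    n,
    mean = ifelse(female, m$height$female["mean"], m$height$male["mean"]),
    sd = ifelse(female, m$height$female["sd"], m$height$male["sd"])
  ), 1)
  bmi <- sample_bin(n, m$bmi$breaks, m$bmi$probs, margin = 0.05)
  weight <- round(bmi * (height / 100)^2, 1)

  # coupled block: eGFR category -> creatinine via MDRD inversion
  egfr_target <- sample_bin(n, m$egfr$breaks, m$egfr$probs, margin = 0.25)
  creatinine <- creatinine_for_egfr(egfr_target, age, female, race == "Black")
  egfr <- egfr_mdrd(creatinine, age, female, race == "Black")

  # comorbidity flags and Elixhauser count
  com <- m$comorbidity
  flags <- tibble(patient_id = ids)
  for (cond in names(com)) flags[[cond]] <- runif(n) < com[[cond]]
  elix_bin <- sample(names(m$elixhauser), n, replace = TRUE, prob = m$elixhauser)
  elix_n <- ifelse(elix_bin == "0-2", sample(0:2, n, replace = TRUE),
    ifelse(elix_bin == "3-4", sample(3:4, n, replace = TRUE),
      sample(5:7, n, replace = TRUE)))
  elix_conditions <- condition_names(code_map, "elixhauser")

  # recommended and received doses
  recommended <- recommend_dose(drug,
    egfr = egfr, age = age,
    weight_kg = weight, creatinine = creatinine
  )
  covars <- tibble(
    recommended = recommended,
    age_bin = as.character(cut(age, c(0, 70, 75, 80, Inf),
      labels = c("<=69", "70-74", "75-79", "80+"), right = FALSE)),
    egfr_bin = as.character(cut(egfr, c(0, 30, 40, 50, 60, Inf),
      labels = c("<30", "30-39", "40-49", "50-59", "60+"), right = FALSE)),
    site_id = site_id
  )
  site_eff <- resolve_site_effects(config)
  p_disc <- discordance_probability(covars, config$discordance_model, site_eff)
  flip <- runif(n) < p_disc
  received <- ifelse(flip, ifelse(recommended == "FULL", "LOW", "FULL"), recommended)

  # tables -------------------------------------------------------------
  patients <- tibble(
    patient_id = ids, sex = ifelse(female, "F", "M"), race = race,
    birth_date = birth_date, region = region, site_id = site_id
  )

  af_code <- condition_code(code_map, "nvaf")
  dx <- list(tibble(
    patient_id = ids, code = af_code,
    date = fill_date - sample(30:720, n, replace = TRUE)
  ))
  for (cond in names(com)) {
    has <- flags[[cond]]
    if (any(has)) {
      dx[[length(dx) + 1]] <- tibble(
        patient_id = ids[has], code = condition_code(code_map, cond),
        date = fill_date[has] - sample(30:720, sum(has), replace = TRUE)
      )
    }
  }
  if (any(elix_n > 0)) {
    elix_codes <- vapply(elix_conditions, condition_code, character(1),
      code_map = code_map)
    long_idx <- rep(seq_len(n), elix_n)
    dx[[length(dx) + 1]] <- tibble(
      patient_id = ids[long_idx],
      code = unname(elix_codes[sequence(elix_n)]),
      date = fill_date[long_idx] - sample(30:720, length(long_idx), replace = TRUE)
    )
  }
  diagnoses <- bind_rows(dx) %>% arrange(.data$patient_id, .data$date)

  has_lab <- runif(n) >= config$missing_lab_fraction
  labs <- tibble(
    patient_id = ids[has_lab], analyte = "creatinine",
    value = creatinine[has_lab],
    date = fill_date[has_lab] - sample(1:180, sum(has_lab), replace = TRUE)
  )
  extra <- has_lab & runif(n) < config$extra_lab_fraction
  if (any(extra)) {
    labs <- bind_rows(labs, tibble(
      patient_id = ids[extra], analyte = "creatinine",
      value = round(creatinine[extra] * 1.15, 2),
      date = fill_date[extra] - sample(300:400, sum(extra), replace = TRUE)
    ))
  }
  labs <- arrange(labs, .data$patient_id, .data$date)

  vitals <- tibble(
    patient_id = ids, weight_kg = weight, height_cm = height,
    date = fill_date - sample(1:180, n, replace = TRUE)
  )

  reg <- dose_regimen(drug, received)
  dispenses <- tibble(
    patient_id = ids, drug = drug, dose_mg = reg$dose_mg,
    frequency = reg$frequency,
    days_supply = sample(c(30L, 60L, 90L), n, replace = TRUE),
    fill_date = fill_date, site_id = site_id
  )
  if (config$switch_scenario) {
    sw <- which(drug == "rivaroxaban" & runif(n) < config$switch_fraction)
    if (length(sw) > 0) {
      other <- ifelse(received[sw] == "FULL", "LOW", "FULL")
      reg2 <- dose_regimen(drug[sw], other)
      dispenses <- bind_rows(dispenses, tibble(
        patient_id = ids[sw], drug = drug[sw], dose_mg = reg2$dose_mg,
        frequency = reg2$frequency,
        days_supply = sample(c(30L, 60L, 90L), length(sw), replace = TRUE),
        fill_date = fill_date[sw] + sample(30:180, length(sw), replace = TRUE),
        site_id = site_id[sw]
      ))
    }
  }
  dispenses <- arrange(dispenses, .data$patient_id, .data$fill_date)

  structure(
    list(
      patients = patients, diagnoses = diagnoses, labs = labs,
      vitals = vitals, dispenses = dispenses,
      truth = tibble(
        patient_id = ids, drug = drug, recommended = recommended,
        received = received, p_discordant = p_disc, egfr = egfr,
        year = year
      ),
      provenance = list(seed = seed, n_patients = n, n_sites = config$n_sites)
    ),
    class = "doacaudit_bundle"
  )
}

resolve_site_effects <- function(config) {
  se <- config$site_effects
  sites <- sprintf("S%03d", seq_len(config$n_sites))
  if (is.null(se)) {
    return(setNames(rep(0, config$n_sites), sites))
  }
  if (length(se) == 1 && is.null(names(se))) {
    return(setNames(rnorm(config$n_sites, 0, se), sites))
  }
  if (length(se) != config$n_sites) {
    abort("site_effects must have length n_sites", class = "doacaudit_config_error")
  }
  setNames(as.numeric(se), sites)
}

discordance_probability <- function(covariates, model, site_effects = NULL) {
  lp <- rep(model$intercept, nrow(covariates))
  for (var in names(model$coefficients)) {
    if (!var %in% names(covariates)) {
      abort(paste0("model covariate '", var, "' absent from covariate frame"),
        class = "doacaudit_config_error")
    }
    lv <- as.character(covariates[[var]])
    coefs <- model$coefficients[[var]]
    missing <- setdiff(unique(lv), names(coefs))
    if (length(missing) > 0) {
      abort(paste0(
        "covariate bin absent from discordance model: ", var, " = ",
        paste(missing, collapse = ", ")
      ), class = "doacaudit_config_error")
    }
    lp <- lp + unname(coefs[lv])
  }
  if (!is.null(site_effects) && "site_id" %in% names(covariates)) {
    off <- site_effects[as.character(covariates$site_id)]
    off[is.na(off)] <- 0
    lp <- lp + unname(off)
  }
  plogis(lp)
}

#' Flip recommended doses per a discordance model
#'
#' Given each patient's recommended dose label and covariate bins, draws
#' the received label: it differs from the recommendation with probability
#' `plogis(intercept + sum of bin offsets + site offset)`, independently
#' across patients. Any covariate bin observed in the data but absent from
#' the model is an error naming the bin — the model must be explicit about
#' every stratum it covers.
#'
#' @param recommended Character vector of `"FULL"`/`"LOW"` labels.
#' @param covariates Tibble of covariate bins (character/factor columns),
#'   one row per patient; may include `site_id`.
#' @param model A [discordance_model()].
#' @param site_effects Optional named log-odds offsets keyed by `site_id`.
#' @param seed Optional seed for the flip draws.
#' @return Character vector of received labels.
#' @export
inject_discordance <- function(recommended, covariates, model,
                               site_effects = NULL, seed = NULL) {
  p <- discordance_probability(covariates, model, site_effects)
  draw <- function() runif(length(recommended)) < p
  flip <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ifelse(flip, ifelse(recommended == "FULL", "LOW", "FULL"), recommended)
}

# regimen lookup: (drug, category) -> dose_mg + frequency
dose_regimen <- function(drug, category) {
  dose_mg <- dplyr::case_when(
    drug == "dabigatran" & category == "FULL" ~ 150,
    drug == "dabigatran" & category == "LOW" ~ 75,
    drug == "rivaroxaban" & category == "FULL" ~ 20,
    drug == "rivaroxaban" & category == "LOW" ~ 15,
    drug == "apixaban" & category == "FULL" ~ 5,
    drug == "apixaban" & category == "LOW" ~ 2.5
  )
  frequency <- ifelse(drug == "rivaroxaban", "once daily", "twice daily")
  list(dose_mg = dose_mg, frequency = frequency)
}
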