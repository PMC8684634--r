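#' Covariate specifications for the discordance models
#'
#' A covariate spec is a named list of covariate definitions. Each
#' definition is one of:
#'
#' * numeric: `list(type = "numeric", var, breaks, labels, ref)` — binned
#'   with left-closed, right-open intervals (top bin closed above by
#'   `Inf`);
#' * factor: `list(type = "factor", var, levels, ref)`;
#' * logical: `list(type = "logical", var)` — reference is `no`.
#'
#' `default_covariate_spec()` returns the audit's published model layouts:
#' age, sex, race, region, body-size bins, the stroke-risk comorbidity
#' flags, renal-function bins, and Elixhauser bins, with bin boundaries
#' specific to the drug, direction, and (for apixaban) criteria group. The
#' renal bins differ by drug because each stratum is bounded by that drug's
#' own dose-reduction threshold: e.g. among patients recommended full-dose
#' dabigatran every eGFR is >= 30, and the bins resolve how close to that
#' cutoff a patient sits.
#'
#' @param drug `"dabigatran"`, `"rivaroxaban"`, or `"apixaban"`.
#' @param direction `"low_given_full"` (received low among recommended
#'   full) or `"full_given_low"`.
#' @param group Apixaban criteria group (required when `drug =
#'   "apixaban"`).
#' @return A covariate spec (named list).
#' @export
default_covariate_spec <- function(drug, direction = "low_given_full",
                                   group = NULL) {
  num <- function(var, breaks, labels, ref) {
    list(type = "numeric", var = var, breaks = breaks, labels = labels, ref = ref)
  }
  fac <- function(var, levels, ref) {
    list(type = "factor", var = var, levels = levels, ref = ref)
  }
  flag <- function(var) list(type = "logical", var = var)

  age_std <- num("age", c(0, 70, 75, 80, Inf), c("<=69", "70-74", "75-79", "80+"), "<=69")
  age_lt80 <- num("age", c(0, 70, 75, 80), c("<=69", "70-74", "75-79"), "<=69")
  age_ge80 <- num("age", c(80, 85, 90, Inf), c("80-84", "85-89", "90+"), "80-84")
  wt_gt60 <- num("weight_kg", c(60, 70, 80, Inf), c("61-69", "70-79", "80+"), "80+")
  wt_le60 <- num("weight_kg", c(0, 50, Inf), c("<50", "50-60"), "50-60")
  cr_lt15 <- num("creatinine", c(0, 1, 1.3, 1.5), c("<1", "1.0-1.29", "1.3-1.49"), "<1")
  cr_ge15 <- num("creatinine", c(1.5, 1.6, 1.8, Inf),
    c("1.50-1.59", "1.60-1.79", ">=1.80"), "1.50-1.59")
  bmi_bins <- num("bmi", c(0, 25, 30, 35, Inf),
    c("<25", "25-29.9", "30-34.9", ">=35"), "<25")

  common <- list(
    sex = fac("sex", c("M", "F"), "M"),
    race = fac("race", RACES, "White"),
    region = fac("region", REGIONS, "Northeast"),
    heart_failure = flag("heart_failure"),
    hypertension = flag("hypertension"),
    vascular_disease = flag("vascular_disease"),
    diabetes = flag("diabetes"),
    prior_bleeding = flag("prior_bleeding"),
    stroke = flag("stroke"),
    elixhauser = fac("elixhauser_category", c("0-2", "3-4", ">=5"), "0-2")
  )

  head <- if (drug == "dabigatran") {
    if (direction == "low_given_full") {
      list(
        age = age_std, bmi = bmi_bins,
        egfr = num("egfr", c(30, 40, 50, 60, Inf),
          c("30-39", "40-49", "50-59", "60+"), "60+")
      )
    } else {
      # recommended-low stratum: all eGFR < 30, no further renal binning
      list(age = age_std, bmi = bmi_bins)
    }
  } else if (drug == "rivaroxaban") {
    if (direction == "low_given_full") {
      list(
        age = age_std, bmi = bmi_bins,
        egfr = num("egfr", c(50, 60, Inf), c("50-59", "60+"), "60+")
      )
    } else {
      list(
        age = age_std, bmi = bmi_bins,
        egfr = num("egfr", c(0, 30, 50), c("<30", "30-49"), "30-49")
      )
    }
  } else if (drug == "apixaban") {
    if (is.null(group)) {
      abort("apixaban covariate spec requires a criteria group",
        class = "doacaudit_config_error")
    }
    switch(group,
      none = list(age = age_lt80, weight = wt_gt60, creatinine = cr_lt15),
      age_only = list(age = age_ge80, weight = wt_gt60, creatinine = cr_lt15),
      weight_only = list(age = age_lt80, weight = wt_le60, creatinine = cr_lt15),
      creatinine_only = list(age = age_lt80, weight = wt_gt60, creatinine = cr_ge15),
      all_three = list(age = age_ge80, weight = wt_le60, creatinine = cr_ge15),
      age_weight = list(age = age_ge80, weight = wt_le60, creatinine = cr_lt15),
      age_creatinine = list(age = age_ge80, weight = wt_gt60, creatinine = cr_ge15),
      weight_creatinine = list(age = age_lt80, weight = wt_le60, creatinine = cr_ge15),
      abort(paste0("unknown apixaban group: ", group),
        class = "doacaudit_config_error")
    )
  } else {
    abort(paste0("unknown drug: ", drug), class = "doacaudit_data_error")
  }
  c(head, common)
}

#' Bin raw covariates per a covariate spec
#'
#' Maps each covariate to exactly one categorical level, with the spec's
#' reference level first. Bins must partition the covariate's observed
#' domain: a value falling outside every bin (or a missing value) is an
#' error naming the covariate, never a silent `NA`.
#'
#' @param panel Score-panel tibble (one row per patient).
#' @param spec Covariate spec (see [default_covariate_spec()]).
#' @return Tibble of factors, one column per spec entry, plus `patient_id`
#'   when present in `panel`.
#' @export
bin_covariates <- function(panel, spec) {
  out <- if ("patient_id" %in% names(panel)) {
    tibble(patient_id = panel$patient_id)
  } else {
    tibble(.rows = nrow(panel))
  }
  for (name in names(spec)) {
    def <- spec[[name]]
    v <- panel[[def$var]]
    if (is.null(v)) {
      abort(paste0("covariate '", def$var, "' absent from panel"),
        class = "doacaudit_data_error")
    }
    f <- switch(def$type,
      numeric = {
        fb <- cut(v, breaks = def$breaks, labels = def$labels,
          right = FALSE, include.lowest = FALSE)
        # close the top bin when the last break is finite
        top <- def$breaks[length(def$breaks)]
        if (is.finite(top)) fb[!is.na(v) & v == top] <- def$labels[length(def$labels)]
        fb
      },
      factor = factor(as.character(v), levels = def$levels),
      logical = factor(ifelse(v, "yes", "no"), levels = c("no", "yes")),
      abort(paste0("unknown covariate type: ", def$type),
        class = "doacaudit_config_error")
    )
    if (any(is.na(f))) {
      bad <- utils::head(unique(v[is.na(f)]), 3)
      abort(paste0(
        "covariate '", name, "' (", def$var, "): value(s) outside bins: ",
        paste(format(bad), collapse = ", ")
      ), class = "doacaudit_data_error")
    }
    ref <- if (def$type == "logical") "no" else def$ref
    out[[name]] <- stats::relevel(factor(f, levels = levels(f)), ref = ref)
  }
  out
}

#' Fit a multivariable logistic model of discordant dosing
#'
#' Maximum-likelihood logistic regression with every spec covariate entered
#' simultaneously. Effects are reported as adjusted odds ratios with Wald
#' 95% confidence intervals (normal approximation on the log-odds scale,
#' exponentiated) and Wald p-values; reference levels are reported with AOR
#' fixed at 1. Discrimination is summarised by the c-statistic (area under
#' the ROC curve of the fitted probabilities).
#'
#' The fit refuses degenerate inputs loudly: a declared covariate level
#' with zero observations, a single-class outcome, apparent complete
#' separation, or IRLS non-convergence all raise errors identifying the
#' culprit rather than returning a silently unstable model.
#'
#' @param data Tibble of binned covariate factors plus a logical outcome
#'   column.
#' @param outcome Name of the logical outcome column (default
#'   `"discordant"`).
#' @return List of class `doacaudit_fit`: `terms` (tibble `covariate`,
#'   `level`, `reference`, `n_outcome`, `n_other`, `aor`, `ci_low`,
#'   `ci_high`, `p`), `c_statistic`, `n`, `n_outcome`, `fit` (the `glm`
#'   object).
#' @export
fit_discordance_model <- function(data, outcome = "discordant") {
  covars <- setdiff(names(data), c(outcome, "patient_id"))
  y <- data[[outcome]]
  if (length(unique(y)) < 2) {
    abort("outcome has a single class; model not estimable",
      class = "doacaudit_data_error")
  }
  for (cv in covars) {
    tab <- table(data[[cv]])
    if (any(tab == 0)) {
      abort(paste0(
        "empty covariate level: ", cv, " = ",
        paste(names(tab)[tab == 0], collapse = ", ")
      ), class = "doacaudit_data_error")
    }
  }
  fml <- stats::as.formula(paste0(
    "`", outcome, "` ~ ", paste0("`", covars, "`", collapse = " + ")
  ))
  fit <- withCallingHandlers(
    glm(fml, data = data, family = binomial()),
    # separation / convergence are re-checked explicitly below
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    abort(paste0("logistic fit did not converge after ", fit$iter, " iterations"),
      class = "doacaudit_numeric_error")
  }
  est <- coef(fit)
  if (any(is.na(est))) {
    abort(paste0("aliased coefficient(s): ",
      paste(names(est)[is.na(est)], collapse = ", ")),
      class = "doacaudit_numeric_error")
  }
  if (any(abs(est[-1]) > 15)) {
    abort(paste0("apparent complete separation at: ",
      paste(names(est)[-1][abs(est[-1]) > 15], collapse = ", ")),
      class = "doacaudit_numeric_error")
  }
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))

  rows <- list()
  for (cv in covars) {
    lv <- levels(data[[cv]])
    for (l in lv) {
      term <- if (paste0(cv, l) %in% names(est)) {
        paste0(cv, l)
      } else {
        paste0("`", cv, "`", l)
      }
      is_ref <- l == lv[1]
      if (!is_ref && !term %in% names(est)) {
        abort(paste0("coefficient not found for ", cv, " = ", l),
          class = "doacaudit_internal_error")
      }
      sel <- data[[cv]] == l
      rows[[length(rows) + 1]] <- tibble(
        covariate = cv, level = l, reference = is_ref,
        n_outcome = sum(sel & y), n_other = sum(sel & !y),
        aor = if (is_ref) 1 else unname(exp(est[term])),
        ci_low = if (is_ref) NA_real_ else unname(exp(est[term] - 1.96 * se[term])),
        ci_high = if (is_ref) NA_real_ else unname(exp(est[term] + 1.96 * se[term])),
        p = if (is_ref) NA_real_ else unname(p[term])
      )
    }
  }
  structure(
    list(
      terms = bind_rows(rows),
      c_statistic = c_statistic(stats::fitted(fit), y),
      n = nrow(data), n_outcome = sum(y),
      fit = fit
    ),
    class = "doacaudit_fit"
  )
}

#' Concordance statistic (AUC)
#'
#' Probability that a randomly chosen positive outcome has a higher fitted
#' probability than a randomly chosen negative one, ties counted half.
#' Invariant to any monotone transformation of the scores.
#'
#' @param scores Numeric fitted probabilities (or any monotone score).
#' @param outcome Logical outcomes.
#' @return c-statistic in `[0, 1]`.
#' @export
c_statistic <- function(scores, outcome) {
  n1 <- sum(outcome)
  n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.doacaudit_fit <- function(x, ...) {
  cat(sprintf(
    "logistic discordance model: n = %d (%d discordant), c-statistic = %.2f\n",
    x$n, x$n_outcome, x$c_statistic
  ))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

#' Fit every discordance model stratum
#'
#' Runs the logistic model for both discordance directions in every
#' drug/group stratum: dabigatran, rivaroxaban, and the estimable apixaban
#' criteria groups (recommended-full direction: the `none` and three
#' single-criterion groups; recommended-low direction: `all_three` and the
#' three two-criteria groups). Covariates declared in the spec but constant
#' within a stratum are dropped before fitting (their AOR is inestimable
#' there); strata that still cannot be fitted — too few patients, a
#' single-class outcome, separation — are reported with an explicit skip
#' reason rather than silently omitted.
#'
#' @param assessments Assessment tibble from [assess_cohort()].
#' @param panel Score panel for the same patients.
#' @param spec_fn Function `(drug, direction, group)` returning a covariate
#'   spec; default [default_covariate_spec()].
#' @return Tibble `direction`, `drug`, `group`, `n`, `status`, `reason`,
#'   `result` (list column of `doacaudit_fit` or `NULL`).
#' @export
run_all_models <- function(assessments, panel,
                           spec_fn = default_covariate_spec) {
  strata <- bind_rows(
    tidyr::crossing(
      direction = "low_given_full",
      tibble(
        drug = c("dabigatran", "rivaroxaban", rep("apixaban", 4)),
        group = c(NA, NA, "none", "age_only", "weight_only", "creatinine_only")
      )
    ),
    tidyr::crossing(
      direction = "full_given_low",
      tibble(
        drug = c("dabigatran", "rivaroxaban", rep("apixaban", 4)),
        group = c(NA, NA, "all_three", "age_weight", "age_creatinine",
          "weight_creatinine")
      )
    )
  )
  out <- list()
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    rec <- if (s$direction == "low_given_full") "FULL" else "LOW"
    recv <- if (s$direction == "low_given_full") "LOW" else "FULL"
    sub <- assessments %>%
      filter(.data$drug == s$drug, .data$recommended == rec)
    if (!is.na(s$group)) {
      sub <- filter(sub, as.character(.data$apixaban_group) == s$group)
    }
    row <- tibble(
      direction = s$direction, drug = s$drug, group = s$group,
      n = nrow(sub), status = "fitted", reason = NA_character_,
      result = list(NULL)
    )
    res <- tryCatch(
      {
        if (nrow(sub) == 0) stop("empty stratum")
        spec <- spec_fn(s$drug, s$direction,
          group = if (is.na(s$group)) NULL else s$group)
        dat <- bin_covariates(semi_join(panel, sub, by = "patient_id"), spec)
        dat <- dat %>%
          left_join(select(sub, "patient_id", "received"), by = "patient_id") %>%
          mutate(discordant = .data$received == recv) %>%
          select(-"received", -"patient_id")
        # drop covariates constant in this stratum
        keep <- vapply(
          dat[setdiff(names(dat), "discordant")],
          function(col) dplyr::n_distinct(col) > 1, logical(1)
        )
        dat <- dat[, c(names(keep)[keep], "discordant")]
        if (sum(keep) == 0) stop("no varying covariates")
        # unobserved declared levels carry no information in this stratum
        dat <- droplevels(dat)
        fit_discordance_model(dat)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      row$status <- "skipped"
      row$reason <- conditionMessage(res)
    } else {
      row$result <- list(res)
    }
    out[[i]] <- row
  }
  bind_rows(out)
}
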