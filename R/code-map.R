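#' Condition code maps
#'
#' A code map links named clinical conditions to ICD-9/ICD-10 code patterns.
#' Patterns are either exact codes or prefixes (matched against the start of
#' the code, so prefix `"I48"` matches `I48.0`, `I48.91`, ...). Each pattern
#' carries a `class` saying what the condition is used for:
#'
#' * `"nvaf"` — atrial fibrillation codes defining the candidate population.
#' * `"valvular"` — valvular heart disease; their presence disqualifies a
#'   patient from the non-valvular AF cohort.
#' * `"vte"` — venous thromboembolism; an exclusion (anticoagulation
#'   indication is ambiguous).
#' * `"stroke_risk"` — the comorbid conditions feeding the CHA2DS2-VASc
#'   score and the predictor models (heart_failure, hypertension, diabetes,
#'   stroke, vascular_disease) plus prior_bleeding.
#' * `"elixhauser"` — the comorbidity list counted for the Elixhauser index.
#'
#' The bundled default map (`default_code_map()`) is synthetic: its condition
#' names are realistic and its code patterns are plausible ICD stems, but it
#' is a stand-in for the proprietary supplementary code lists used in real
#' audits. Real lists can be supplied as a CSV with the same columns via
#' [read_code_map()].
#'
#' @return A tibble with columns `condition`, `class`, `pattern`, `prefix`
#'   (logical; `TRUE` means prefix match).
#' @export
#' @examples
#' cm <- default_code_map()
#' head(cm)
default_code_map <- function() {
  path <- system.file("extdata", "default_code_map.csv", package = "doacaudit")
  read_code_map(path)
}

#' Read a code map from CSV
#'
#' @param path CSV file with columns `condition`, `class`, `pattern`,
#'   `prefix` (logical or 0/1).
#' @return A validated code-map tibble (see [default_code_map()]).
#' @export
read_code_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("code map file not found: ", path), class = "doacaudit_config_error")
  }
  map <- readr::read_csv(
    path,
    col_types = readr::cols(
      condition = readr::col_character(),
      class = readr::col_character(),
      pattern = readr::col_character(),
      prefix = readr::col_logical()
    )
  )
  validate_code_map(map)
  map
}

validate_code_map <- function(map) {
  required <- c("condition", "class", "pattern", "prefix")
  missing <- setdiff(required, names(map))
  if (length(missing) > 0) {
    abort(paste0("code map missing column(s): ", paste(missing, collapse = ", ")),
      class = "doacaudit_config_error"
    )
  }
  empty <- map %>%
    group_by(.data$condition) %>%
    summarise(n = sum(!is.na(.data$pattern) & nzchar(.data$pattern))) %>%
    filter(n == 0)
  if (nrow(empty) > 0) {
    abort(paste0(
      "code map condition(s) with no patterns: ",
      paste(empty$condition, collapse = ", ")
    ), class = "doacaudit_config_error")
  }
  invisible(map)
}

#' Flag patients matching code-map conditions
#'
#' Resolves, for each patient, which named conditions have at least one
#' matching diagnosis code dated on or before that patient's index date.
#'
#' @param diagnoses Tibble with `patient_id`, `code`, `date`.
#' @param code_map A code-map tibble (see [default_code_map()]).
#' @param index_dates Optional tibble with `patient_id`, `index_date`; when
#'   supplied only diagnoses dated on/before the patient's index date count.
#'   Patients absent from `index_dates` are dropped.
#' @param conditions Optional character vector restricting to a subset of
#'   condition names.
#' @return Tibble `patient_id`, `condition` — one row per (patient,
#'   condition) with at least one matching code.
#' @export
match_conditions <- function(diagnoses, code_map, index_dates = NULL,
                             conditions = NULL) {
  if (!is.null(conditions)) {
    code_map <- filter(code_map, .data$condition %in% conditions)
  }
  dx <- diagnoses
  if (!is.null(index_dates)) {
    dx <- dx %>%
      inner_join(index_dates, by = "patient_id") %>%
      filter(.data$date <= .data$index_date)
  }
  if (nrow(dx) == 0 || nrow(code_map) == 0) {
    return(tibble(patient_id = character(), condition = character()))
  }
  exact <- filter(code_map, !.data$prefix)
  pref <- filter(code_map, .data$prefix)
  hits <- list()
  if (nrow(exact) > 0) {
    hits$exact <- dx %>%
      inner_join(select(exact, code = "pattern", "condition"),
        by = "code", relationship = "many-to-many"
      ) %>%
      select("patient_id", "condition")
  }
  if (nrow(pref) > 0) {
    # prefix match: cross each distinct code against the prefix patterns
    codes <- distinct(dx, .data$code)
    pairs <- tidyr::crossing(codes, select(pref, "pattern", "condition")) %>%
      filter(startsWith(.data$code, .data$pattern)) %>%
      distinct(.data$code, .data$condition)
    hits$prefix <- dx %>%
      inner_join(pairs, by = "code", relationship = "many-to-many") %>%
      select("patient_id", "condition")
  }
  bind_rows(hits) %>% distinct(.data$patient_id, .data$condition)
}

#' Per-patient condition flags as a wide logical table
#'
#' @inheritParams match_conditions
#' @param patient_ids Character vector of patients to report (rows are
#'   emitted for all of them, `FALSE` where no code matched).
#' @return Tibble with `patient_id` and one logical column per condition
#'   name in `conditions`.
#' @export
condition_flags <- function(diagnoses, code_map, patient_ids, conditions,
                            index_dates = NULL) {
  long <- match_conditions(diagnoses, code_map,
    index_dates = index_dates, conditions = conditions
  )
  out <- tibble(patient_id = patient_ids)
  for (cond in conditions) {
    flagged <- long$patient_id[long$condition == cond]
    out[[cond]] <- out$patient_id %in% flagged
  }
  out
}

condition_names <- function(code_map, class) {
  unique(code_map$condition[code_map$class %in% class])
}
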