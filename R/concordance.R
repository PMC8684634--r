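#' Round half away from zero
#'
#' Integer percent rounding used throughout the audit's published-style
#' tables: .5 rounds away from zero (22.80 -> 23, 6.52 -> 7, 6.29 -> 6),
#' unlike base R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal digits (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5) * sign(x) / scale
}

percent_of <- function(numerator, denominator) {
  out <- round_half_up(100 * numerator / denominator)
  out[rep_len(!(denominator > 0), length(out))] <- NA_real_
  out
}

#' Guideline-discordance rate summaries
#'
#' Aggregates dose assessments into discordance rates, optionally
#' stratified. Two directions are reported:
#'
#' * `inappropriate_low`: denominator = patients recommended FULL,
#'   numerator = those who received LOW;
#' * `inappropriate_full`: denominator = patients recommended LOW,
#'   numerator = those who received FULL.
#'
#' Percents are integers rounded half away from zero; a zero denominator
#' yields `NA` percent (undefined, not 0).
#'
#' @param assessments Assessment tibble from [assess_cohort()].
#' @param by Character vector of stratifier columns (e.g. `"drug"`,
#'   `"year"`, `"site_id"`); default none (overall rates).
#' @return Tibble `direction`, stratifiers, `numerator`, `denominator`,
#'   `percent`.
#' @export
#' @examples
#' a <- tibble::tibble(
#'   recommended = c(rep("LOW", 4), rep("FULL", 6)),
#'   received = c("FULL", rep("LOW", 3), "LOW", rep("FULL", 5))
#' )
#' summarize_rates(a)
summarize_rates <- function(assessments, by = character()) {
  one_direction <- function(direction, rec, recv) {
    assessments %>%
      filter(.data$recommended == rec) %>%
      group_by(across(all_of(by))) %>%
      summarise(
        numerator = sum(.data$received == recv),
        denominator = n(),
        .groups = "drop"
      ) %>%
      mutate(direction = direction, percent = percent_of(.data$numerator, .data$denominator))
  }
  bind_rows(
    one_direction("inappropriate_low", "FULL", "LOW"),
    one_direction("inappropriate_full", "LOW", "FULL")
  ) %>%
    select("direction", all_of(by), "numerator", "denominator", "percent")
}

#' Site-level discordance profiles
#'
#' One profile per site with the discordance percent in the requested
#' direction. Sites below the minimum denominator are listed but flagged
#' `included = FALSE` and ignored by the observed range, mirroring audit
#' practice of profiling only sites with enough eligible patients.
#'
#' @param assessments Assessment tibble.
#' @param direction `"inappropriate_low"` (default) or
#'   `"inappropriate_full"`.
#' @param min_denominator Minimum eligible patients for inclusion; audit
#'   defaults are 100 for the full-dose-recommended denominator and 20 for
#'   the low-dose-recommended denominator.
#' @return List with `profiles` (tibble `site_id`, `numerator`,
#'   `denominator`, `percent`, `included`) and `range` (numeric
#'   `c(min, max)` percent over included sites; `c(NA, NA)` if none).
#' @export
profile_sites <- function(assessments, direction = "inappropriate_low",
                          min_denominator = if (direction == "inappropriate_low") 100 else 20) {
  profiles <- summarize_rates(assessments, by = "site_id") %>%
    filter(.data$direction == !!direction) %>%
    select("site_id", "numerator", "denominator", "percent") %>%
    mutate(included = .data$denominator >= min_denominator)
  inc <- filter(profiles, .data$included)
  rng <- if (nrow(inc) == 0) c(NA_real_, NA_real_) else range(inc$percent)
  list(profiles = profiles, range = rng)
}

#' Year-by-drug trend table of inappropriate low-dose therapy
#'
#' For each calendar year (of the patient's first fill) and drug, the number
#' of patients recommended full-dose therapy, the number of those who
#' received low-dose therapy instead, and the integer percent; plus an
#' `all` row per year summing the drug columns.
#'
#' @param assessments Assessment tibble.
#' @param direction Discordance direction, default `"inappropriate_low"`.
#' @return Tibble `year`, `drug` (including `"all"`), `denominator`,
#'   `numerator`, `percent`, sorted by year; drugs with no
#'   recommended-full patients in a year are omitted.
#' @export
trend_table <- function(assessments, direction = "inappropriate_low") {
  per_drug <- summarize_rates(assessments, by = c("year", "drug")) %>%
    filter(.data$direction == !!direction)
  overall <- summarize_rates(assessments, by = "year") %>%
    filter(.data$direction == !!direction) %>%
    mutate(drug = "all")
  bind_rows(overall, per_drug) %>%
    select("year", "drug", "denominator", "numerator", "percent") %>%
    arrange(.data$year, match(.data$drug, c("all", DOAC_DRUGS)))
}

#' Plain-text histogram of site discordance percents
#'
#' A terminal-friendly analogue of the audit's site-variation figures.
#'
#' @param profiles Profile tibble from [profile_sites()].
#' @param bin_width Percent bin width (default 2).
#' @param print Cat the histogram to the console (default `FALSE`).
#' @return Character vector of lines, invisibly printed with `cat()` when
#'   `print = TRUE`.
#' @export
site_histogram <- function(profiles, bin_width = 2, print = FALSE) {
  inc <- filter(profiles, .data$included)
  if (nrow(inc) == 0) {
    lines <- "no sites meet the minimum denominator"
  } else {
    top <- max(inc$percent, bin_width)
    breaks <- seq(0, ceiling(top / bin_width) * bin_width + bin_width, by = bin_width)
    bins <- cut(inc$percent, breaks = breaks, right = FALSE, include.lowest = TRUE)
    counts <- table(bins)
    lines <- sprintf(
      "%8s | %s (%d)", names(counts),
      strrep("#", counts), as.integer(counts)
    )
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
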