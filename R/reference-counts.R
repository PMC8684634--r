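#' Published audit counts bundled for fixture reconstruction
#'
#' Counts reported by a published national audit of DOAC dosing in the US
#' Veterans Health Administration (73,672 patients, 2010-2016). They are
#' bundled so that the package's exact-arithmetic checks can re-expand the
#' printed tables into patient-level fixtures via [make_fixture()] /
#' [make_switch_fixture()] and verify that the full pipeline reproduces
#' every printed count and rounded percent.
#'
#' * `doac_headline_counts()`: overall discordance in both directions, with
#'   a per-drug split of the numerators (the published per-drug
#'   denominators do not all reconcile; the split here preserves the exact
#'   overall denominators 5,837 and 67,935 and the per-drug numerators).
#' * `doac_trend_counts()`: the year-by-drug table of patients recommended
#'   full-dose therapy and the subset receiving low-dose therapy,
#'   2010-2016. Every year row is internally consistent: drug columns sum
#'   to the overall column.
#' * `doac_switch_counts()`: the excluded-rivaroxaban switch analysis —
#'   partition sizes 4,027 / 1,264 / 1,188 and the per-group
#'   appropriateness tallies (missing-eGFR counts inferred from the
#'   published margins: 343 in group 1; 63 + 30 = 93 in group 2).
#'
#' @return A tibble (`doac_headline_counts`, `doac_trend_counts`) or nested
#'   list (`doac_switch_counts`).
#' @name reference_counts
NULL

#' @rdname reference_counts
#' @export
doac_headline_counts <- function() {
  tibble(
    direction = rep(c("inappropriate_low", "inappropriate_full"), each = 3),
    drug = rep(DOAC_DRUGS, 2),
    numerator = c(482, 1221, 2376, 173, 661, 497),
    denominator = c(26146, 16831, 24958, 1337, 2000, 2500)
  )
}

#' @rdname reference_counts
#' @export
doac_trend_counts <- function() {
  tribble_rows <- list(
    # year, drug, denominator (recommended full), numerator (received low)
    list(2010, "dabigatran", 92, 2),
    list(2011, "dabigatran", 1635, 37),
    list(2012, "dabigatran", 2814, 76),
    list(2012, "rivaroxaban", 46, 3),
    list(2013, "dabigatran", 3383, 92),
    list(2013, "rivaroxaban", 507, 50),
    list(2013, "apixaban", 68, 16),
    list(2014, "dabigatran", 5431, 104),
    list(2014, "rivaroxaban", 2904, 289),
    list(2014, "apixaban", 1456, 233),
    list(2015, "dabigatran", 5530, 73),
    list(2015, "rivaroxaban", 5424, 389),
    list(2015, "apixaban", 7391, 744),
    list(2016, "dabigatran", 7344, 98),
    list(2016, "rivaroxaban", 7946, 490),
    list(2016, "apixaban", 16037, 1383)
  )
  purrr::map_dfr(tribble_rows, function(r) {
    tibble(year = r[[1]], drug = r[[2]], denominator = r[[3]], numerator = r[[4]])
  })
}

#' Published year-by-drug percents for the trend table
#'
#' The integer percents as printed alongside [doac_trend_counts()],
#' including the per-year overall column. Used to verify the rounding
#' convention end to end.
#'
#' @return Tibble `year`, `drug` (including `"all"`), `percent`.
#' @export
doac_trend_percents <- function() {
  purrr::map_dfr(
    list(
      list(2010, "all", 2), list(2010, "dabigatran", 2),
      list(2011, "all", 2), list(2011, "dabigatran", 2),
      list(2012, "all", 3), list(2012, "dabigatran", 3), list(2012, "rivaroxaban", 7),
      list(2013, "all", 4), list(2013, "dabigatran", 3), list(2013, "rivaroxaban", 10),
      list(2013, "apixaban", 24),
      list(2014, "all", 6), list(2014, "dabigatran", 2), list(2014, "rivaroxaban", 10),
      list(2014, "apixaban", 16),
      list(2015, "all", 7), list(2015, "dabigatran", 1), list(2015, "rivaroxaban", 7),
      list(2015, "apixaban", 10),
      list(2016, "all", 6), list(2016, "dabigatran", 1), list(2016, "rivaroxaban", 6),
      list(2016, "apixaban", 9)
    ),
    function(r) tibble(year = r[[1]], drug = r[[2]], percent = r[[3]])
  )
}

#' @rdname reference_counts
#' @export
doac_switch_counts <- function() {
  list(
    group1 = list(
      n_low_appropriate = 209, n_low_inappropriate = 42,
      n_full_appropriate = 3303, n_full_inappropriate = 130,
      n_missing_egfr = 343
    ),
    group2 = list(
      n_full_first_appropriate = 529, n_full_first_inappropriate = 307,
      n_full_first_missing = 63,
      n_low_first_appropriate = 60, n_low_first_inappropriate = 275,
      n_low_first_missing = 30
    ),
    group3 = list(n = 1188)
  )
}
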