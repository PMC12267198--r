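#' Round half away from zero
#'
#' Commercial rounding to the nearest integer, with exact halves moved away
#' from zero (`round_half_out(2.5)` is 3, `round_half_out(-2.5)` is -3).
#' This is the convention used for all reported integer percent changes; it
#' differs from base [round()], which rounds halves to even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, with integral values.
#' @export
#' @examples
#' round_half_out(c(2.5, -2.5, 9.83, -26.1))
round_half_out <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' The three tumor types covered by the model
#' @return Character vector `c("melanoma", "rcc", "tnbc")`.
#' @export
tumor_types <- function() c("melanoma", "rcc", "tnbc")

#' The five health states of the cohort model
#'
#' Patients enter in `recurrence_free`, may move to `locoregional_recurrence`
#' or directly to first-line metastatic treatment (`metastatic_1L`), progress
#' to second-line treatment (`metastatic_2L`), and are absorbed in `dead`.
#'
#' @return Character vector of the five state labels, in model order.
#' @export
health_states <- function() {
  c("recurrence_free", "locoregional_recurrence",
    "metastatic_1L", "metastatic_2L", "dead")
}

#' Retreatment-eligibility strata
#' @return Character vector `c("before_threshold", "at_or_after_threshold")`.
#' @export
eligibility_strata <- function() c("before_threshold", "at_or_after_threshold")

# Label for the anti-PD-(L)1 adjuvant/neoadjuvant arm, used throughout.
pdl1_arm <- "anti_pdl1"

#' The eight reported outcomes
#'
#' Column order used throughout: recurrence-free life-years, total
#' life-years, QALYs, recurrences/events, metastatic treatment initiations,
#' adverse events, total deaths, deaths after the first event.
#'
#' @return Character vector of the eight outcome names.
#' @export
outcome_names <- function() {
  c("rf_life_years", "life_years", "qalys", "recurrences",
    "metastatic_treatments", "adverse_events", "deaths", "deaths_after_event")
}

# Outcomes reported as counts of occurrences (undiscounted by default).
count_outcomes <- function() {
  c("recurrences", "metastatic_treatments", "adverse_events",
    "deaths", "deaths_after_event")
}
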