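#' Adverse-event burden of a block of treatment initiations
#'
#' Adverse events are one-time events incurred at treatment initiation: the
#' expected event count is `initiations x events_per_patient`, and the QALY
#' loss is event count x mean weeks per event x |disutility| / 52.
#'
#' @param initiations Number of treatment initiations (persons).
#' @param events_per_patient Expected events per initiating patient.
#' @param weeks_per_event Mean duration of one event, weeks.
#' @param disutility Utility decrement while an event lasts (`<= 0`).
#' @return Tibble `ae_count, qaly_loss` (both undiscounted).
#' @export
#' @examples
#' ae_burden(100, 0.5, 4, -0.05)
ae_burden <- function(initiations, events_per_patient, weeks_per_event,
                      disutility) {
  stopifnot(all(initiations >= 0), all(events_per_patient >= 0),
            all(weeks_per_event >= 0), all(disutility <= 0))
  n_events <- initiations * events_per_patient
  tibble::tibble(
    ae_count = n_events,
    qaly_loss = n_events * weeks_per_event * abs(disutility) / 52)
}

# Undiscounted per-cycle outcome streams of a unit trace: K x 8 matrix in
# outcome_names() order.  Life-years use start-of-cycle occupancy at 1/52
# year per cycle (no half-cycle correction; weekly cycles make its effect
# negligible).  QALYs apply state utilities and the sex-weighted age
# adjustment, minus adverse-event losses at the initiation cycles.
trace_streams <- function(trace, params) {
  tumor <- trace$tumor
  K <- trace$n_cycles
  occ <- trace$occupancy
  u <- utility_vector(params, tumor)
  demo <- params$demographics[params$demographics$tumor == tumor, ]
  ages <- demo$mean_age + (seq_len(K) - 1L) / 52
  adj <- adjustment_vector(params, ages, demo$fraction_female)

  ly_rf <- occ[, 1L] / 52
  ly_total <- (occ[, 1L] + occ[, 2L] + occ[, 3L] + occ[, 4L]) / 52
  qaly_state <- (occ[, 1L] * u[1] + occ[, 2L] * u[2] +
                   occ[, 3L] * u[3] + occ[, 4L] * u[4]) * adj / 52

  ae1 <- ae_vectors(params, tumor, "m1l", colnames(trace$m1_initiations))
  ae2 <- ae_vectors(params, tumor, "m2l", colnames(trace$m2_initiations))
  ae_adj <- ae_profile_row(params, tumor, "adjuvant", trace$arm)
  ae_count <- as.numeric(trace$m1_initiations %*% ae1$events +
                           trace$m2_initiations %*% ae2$events)
  ae_loss <- as.numeric(trace$m1_initiations %*% ae1$qaly_loss +
                          trace$m2_initiations %*% ae2$qaly_loss)
  adj_burden <- ae_burden(trace$entry_size, ae_adj$events_per_patient,
                          ae_adj$weeks_per_event, ae_adj$disutility)
  ae_count[1L] <- ae_count[1L] + adj_burden$ae_count
  ae_loss[1L] <- ae_loss[1L] + adj_burden$qaly_loss

  cbind(rf_life_years = ly_rf,
        life_years = ly_total,
        qalys = qaly_state - ae_loss,
        recurrences = trace$recurrences,
        metastatic_treatments = rowSums(trace$m1_initiations) +
          rowSums(trace$m2_initiations),
        adverse_events = ae_count,
        deaths = trace$deaths,
        deaths_after_event = trace$deaths_after_event)
}

# Fold per-cycle streams into per-calendar-year outcomes with discounting.
# Life-years and QALYs are always discounted; the count outcomes only when
# settings$discount_event_counts is TRUE.  Discounting runs on calendar
# time from the start of the window (settings$discount_from =
# "model_start") or on time since cohort entry ("entry").
accumulate_streams <- function(streams, entry_week, settings) {
  K <- nrow(streams)
  calendar <- entry_week + seq_len(K) - 1L
  dc_cycles <- if (settings$discount_from == "model_start") calendar
               else seq_len(K) - 1L
  d <- discount_factor(dc_cycles, settings$annual_discount_rate)
  w <- matrix(1, K, length(outcome_names()),
              dimnames = list(NULL, outcome_names()))
  w[, c("rf_life_years", "life_years", "qalys")] <- d
  if (settings$discount_event_counts) w[, count_outcomes()] <- d
  year_idx <- calendar %/% 52L
  out <- rowsum(streams * w, year_idx)
  yrs <- settings$start_year + as.integer(rownames(out))
  rownames(out) <- NULL
  list(per_year = out, years = yrs)
}

new_outcome_set <- function(per_year_matrix, years) {
  per_year <- dplyr::bind_cols(tibble::tibble(year = as.integer(years)),
                               tibble::as_tibble(per_year_matrix))
  structure(list(per_year = per_year,
                 cumulative = colSums(per_year_matrix)),
            class = "outcome_set")
}

#' Discounted life-years of a cohort trace, per calendar year
#'
#' Each cycle contributes start-of-cycle occupancy x 1/52 year x discount
#' factor; recurrence-free life-years count only the recurrence-free state,
#' total life-years all alive states.
#'
#' @param trace A [run_cohort()] trace.
#' @param params The `pdl1_params` bundle the trace was run under.
#' @return Tibble `year, rf_life_years, life_years`.
#' @export
accumulate_life_years <- function(trace, params) {
  acc <- accumulate_streams(trace_streams(trace, params), trace$entry_week,
                            params$settings)
  dplyr::bind_cols(tibble::tibble(year = acc$years),
                   tibble::as_tibble(acc$per_year[, c("rf_life_years",
                                                      "life_years"),
                                                  drop = FALSE]))
}

#' Discounted QALYs of a cohort trace, per calendar year
#'
#' State occupancy weighted by tumor/state utility and the sex-weighted
#' age-band adjustment, with adverse-event QALY losses subtracted at the
#' treatment initiation cycles.
#'
#' @inheritParams accumulate_life_years
#' @return Tibble `year, qalys`.
#' @export
accumulate_qalys <- function(trace, params) {
  acc <- accumulate_streams(trace_streams(trace, params), trace$entry_week,
                            params$settings)
  tibble::tibble(year = acc$years, qalys = acc$per_year[, "qalys"])
}

#' Event counts of a cohort trace, per calendar year
#'
#' Recurrences (first exits from the recurrence-free state), metastatic
#' treatment initiations (1L + 2L), adverse events, total deaths and deaths
#' after the first event.  Counts are reported undiscounted by default
#' (they are counts of occurrences, not valued outcomes); set
#' `settings$discount_event_counts` to discount them as well.
#'
#' @inheritParams accumulate_life_years
#' @return Tibble `year, recurrences, metastatic_treatments,
#'   adverse_events, deaths, deaths_after_event`.
#' @export
count_events <- function(trace, params) {
  acc <- accumulate_streams(trace_streams(trace, params), trace$entry_week,
                            params$settings)
  dplyr::bind_cols(tibble::tibble(year = acc$years),
                   tibble::as_tibble(acc$per_year[, count_outcomes(),
                                                  drop = FALSE]))
}

#' All eight outcomes of a single cohort trace
#'
#' @inheritParams accumulate_life_years
#' @return An `outcome_set` (per-year tibble plus cumulative totals).
#' @export
trace_outcomes <- function(trace, params) {
  acc <- accumulate_streams(trace_streams(trace, params), trace$entry_week,
                            params$settings)
  new_outcome_set(acc$per_year, acc$years)
}

#' @export
print.outcome_set <- function(x, ...) {
  cat("<outcome_set> years ", min(x$per_year$year), "-",
      max(x$per_year$year), ", cumulative:\n", sep = "")
  print(tibble::as_tibble(as.list(round(x$cumulative, 1))))
  invisible(x)
}

#' @describeIn trace_outcomes Tidy per-year outcomes in long form.
#' @param x An `outcome_set`.
#' @param ... Unused.
#' @export
tidy.outcome_set <- function(x, ...) {
  tidyr::pivot_longer(x$per_year, -"year", names_to = "outcome",
                      values_to = "value")
}

#' @describeIn trace_outcomes One-row tibble of cumulative outcomes.
#' @export
glance.outcome_set <- function(x, ...) {
  tibble::as_tibble(as.list(x$cumulative))
}

#' Compare the outcomes of two policy scenarios
#'
#' Produces the reporting layer of the projection: per-outcome differences
#' (scenario II minus scenario I), per year and cumulative, and integer
#' percent changes relative to scenario I under half-away-from-zero
#' rounding.  A percent change with a zero scenario I denominator is
#' reported as `NA`.
#'
#' @param outcomes_i,outcomes_ii `outcome_set` objects for scenario I
#'   (anti-PD-(L)1 agents reserved for the metastatic setting) and
#'   scenario II (also available in the early setting), over the same
#'   years.
#' @return An object of class `pdl1_comparison` with elements `outcomes_i`,
#'   `outcomes_ii`, `per_year` (tibble of per-year differences) and
#'   `cumulative` (tibble `outcome, scenario_i, scenario_ii, difference,
#'   pct_change`).
#' @export
#' @examples
#' # reproduce a reported comparison line from cumulative scenario totals
#' oi <- as_outcome_set(tibble::tibble(year = 2022, rf_life_years = 34755))
#' oii <- as_outcome_set(tibble::tibble(year = 2022, rf_life_years = 38171))
#' compare_scenarios(oi, oii)$cumulative
compare_scenarios <- function(outcomes_i, outcomes_ii) {
  stopifnot(inherits(outcomes_i, "outcome_set"),
            inherits(outcomes_ii, "outcome_set"))
  if (!identical(outcomes_i$per_year$year, outcomes_ii$per_year$year)) {
    stop("scenario outcome sets cover different years", call. = FALSE)
  }
  cols <- setdiff(names(outcomes_i$per_year), "year")
  per_year <- outcomes_i$per_year["year"]
  for (cl in cols) {
    per_year[[cl]] <- outcomes_ii$per_year[[cl]] - outcomes_i$per_year[[cl]]
  }
  ci <- outcomes_i$cumulative; cii <- outcomes_ii$cumulative
  diff <- cii - ci
  pct <- ifelse(ci == 0, NA_real_, round_half_out(100 * diff / ci))
  cumulative <- tibble::tibble(
    outcome = cols, scenario_i = unname(ci[cols]),
    scenario_ii = unname(cii[cols]), difference = unname(diff[cols]),
    pct_change = unname(pct[cols]))
  structure(list(outcomes_i = outcomes_i, outcomes_ii = outcomes_ii,
                 per_year = per_year, cumulative = cumulative),
            class = "pdl1_comparison")
}

#' Build an outcome set from a per-year table
#'
#' Wraps an existing per-year outcome table (for instance published
#' cumulative scenario totals entered as a single pseudo-year) as an
#' `outcome_set` so it can be fed to [compare_scenarios()].
#'
#' @param per_year Tibble with a `year` column and one column per outcome.
#' @return An `outcome_set`.
#' @export
as_outcome_set <- function(per_year) {
  per_year <- tibble::as_tibble(per_year)
  stopifnot("year" %in% names(per_year))
  m <- as.matrix(per_year[setdiff(names(per_year), "year")])
  new_outcome_set(m, per_year$year)
}

#' @export
print.pdl1_comparison <- function(x, ...) {
  cat("<pdl1_comparison> scenario II vs scenario I, cumulative:\n")
  print(dplyr::mutate(x$cumulative,
                      dplyr::across(dplyr::where(is.numeric),
                                    ~ round(.x, 1))), n = Inf)
  invisible(x)
}

#' Tidy a scenario comparison
#'
#' @param x A `pdl1_comparison`.
#' @param type `"cumulative"` (default) for the reporting table, or
#'   `"per_year"` for the per-year differences in long form.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pdl1_comparison <- function(x, type = c("cumulative", "per_year"),
                                 ...) {
  type <- match.arg(type)
  if (type == "cumulative") return(x$cumulative)
  tidyr::pivot_longer(x$per_year, -"year", names_to = "outcome",
                      values_to = "difference")
}

#' @describeIn tidy.pdl1_comparison One-row summary of the headline
#'   cumulative differences.
#' @export
glance.pdl1_comparison <- function(x, ...) {
  cm <- x$cumulative
  tibble::as_tibble(as.list(setNames(cm$difference,
                                     paste0(cm$outcome, "_diff"))))
}
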