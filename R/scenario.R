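#' Project national outcomes under one policy scenario
#'
#' Builds weekly entry cohorts from the annual eligible population,
#' allocates them to adjuvant arms under the scenario, propagates each
#' tumor/arm combination through the cohort engine, and accumulates the
#' eight outcomes per calendar year with discounting.  Every cohort's trace
#' is truncated at the end of the projection window, so a final-year
#' entrant contributes at most 52 cycles.
#'
#' The engine is run once per tumor/arm on a unit cohort; entry cohorts for
#' all 520 entry weeks reuse that trace (the dynamics depend only on time
#' since entry), which makes the projection linear in the entry sizes by
#' construction.
#'
#' @param params A `pdl1_params` bundle.
#' @param scenario A [scenario_definition()].
#' @param .trace_cache Optional environment reusing unit traces across
#'   scenario runs under the *same* bundle (used internally by
#'   [run_comparison()]).
#' @return An `outcome_set`.
#' @export
run_scenario <- function(params, scenario = scenario_definition("scenario_I"),
                         .trace_cache = NULL) {
  stopifnot(inherits(params, "pdl1_params"),
            inherits(scenario, "scenario_definition"))
  st <- params$settings
  W <- st$horizon_years * 52L
  cache <- .trace_cache %||% new.env(parent = emptyenv())
  subset <- intersect(scenario$tumor_subset,
                      unique(params$population$tumor))
  if (length(subset) == 0) {
    stop("tumor_subset has no tumors present in the bundle", call. = FALSE)
  }
  alloc <- allocate_arms(weekly_cohorts(params$population, st), scenario,
                         params)
  years <- st$start_year + seq_len(st$horizon_years) - 1L

  per_tumor <- lapply(subset, function(tm) {
    total <- matrix(0, st$horizon_years, length(outcome_names()),
                    dimnames = list(NULL, outcome_names()))
    sub <- alloc[alloc$tumor == tm, ]
    for (arm in unique(sub$arm)) {
      n_w <- numeric(W)
      rows <- sub[sub$arm == arm, ]
      n_w[rows$entry_week + 1L] <- rows$size
      if (all(n_w == 0)) next
      key <- paste(tm, arm, scenario$retreatment_allowed, sep = "\r")
      if (is.null(cache[[key]])) {
        trace <- run_cohort(params, tm, arm, entry_size = 1,
                            entry_week = 0L,
                            retreatment_allowed =
                              scenario$retreatment_allowed)
        cache[[key]] <- trace_streams(trace, params)
      }
      S <- cache[[key]]
      st_acc <- st
      if (st$discount_from == "entry") {
        # entry-clock discounting attaches to the cohort stream itself
        d <- discount_factor(seq_len(nrow(S)) - 1L, st$annual_discount_rate)
        dw <- matrix(1, nrow(S), ncol(S),
                     dimnames = list(NULL, colnames(S)))
        dw[, c("rf_life_years", "life_years", "qalys")] <- d
        if (st$discount_event_counts) dw[, count_outcomes()] <- d
        S <- S * dw
        st_acc$annual_discount_rate <- 0
      }
      # accrual by calendar cycle: convolution of entry sizes with the
      # unit-cohort streams, truncated at the end of the window
      A <- matrix(0, W, ncol(S))
      for (w in which(n_w != 0)) {
        len <- W - w + 1L
        A[w:W, ] <- A[w:W, ] + n_w[w] * S[seq_len(len), ]
      }
      acc <- accumulate_streams(A, entry_week = 0L, settings = st_acc)
      total <- total + acc$per_year
    }
    total
  })
  new_outcome_set(Reduce(`+`, per_tumor), years)
}

#' Compare scenario I and scenario II end to end
#'
#' Runs the full projection under both policies — scenario I with
#' early-setting anti-PD-(L)1 uptake identically zero, scenario II with the
#' bundle's (or an overridden) uptake schedule — and returns the per-year
#' and cumulative differences with integer percent changes.  Unit cohort
#' traces are shared between the two runs, so with uptake identically zero
#' the two scenarios are bit-for-bit identical.
#'
#' @param params A `pdl1_params` bundle.
#' @param scenario_ii A [scenario_definition()] for the adoption scenario;
#'   its tumor subset and retreatment flag are mirrored in scenario I.
#' @return A `pdl1_comparison`.
#' @export
#' @examples
#' \donttest{
#' params <- synth_params(seed = 2024)
#' cmp <- run_comparison(params)
#' cmp$cumulative
#' }
run_comparison <- function(params,
                           scenario_ii = scenario_definition("scenario_II")) {
  stopifnot(identical(scenario_ii$label, "scenario_II"))
  scenario_i <- scenario_definition(
    "scenario_I", tumor_subset = scenario_ii$tumor_subset,
    retreatment_allowed = scenario_ii$retreatment_allowed)
  cache <- new.env(parent = emptyenv())
  oi <- run_scenario(params, scenario_i, .trace_cache = cache)
  oii <- run_scenario(params, scenario_ii, .trace_cache = cache)
  compare_scenarios(oi, oii)
}
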