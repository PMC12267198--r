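sens_outcomes <- function() {
  # the seven reported impact rows (recurrence-free life-years are part of
  # the main comparison table but not of the sensitivity table)
  c("life_years", "qalys", "recurrences", "metastatic_treatments",
    "adverse_events", "deaths", "deaths_after_event")
}

#' Scenario-based sensitivity analysis
#'
#' Re-runs the full scenario I vs II projection with exactly one setting
#' varied and reports, for each of the seven impact rows, the base-case
#' impact (cumulative scenario II minus scenario I), the varied-case
#' impact, and the integer percent change of the impact relative to the
#' base case.  The percent change is `round(100 * (varied - base) / base)`
#' with half-away-from-zero rounding, so a positive sign always means a
#' larger benefit (a more positive gain or a more negative avoided count),
#' matching the reporting convention of the projection.
#'
#' Available toggles:
#' \describe{
#'   \item{`uptake_100`}{100% early-setting uptake in scenario II.}
#'   \item{`pop_up_20`, `pop_down_20`}{target population +/-20% in all
#'     years (both scenarios); by linearity every impact changes by exactly
#'     +/-20%.}
#'   \item{`launch_delay`}{anti-PD-(L)1 launch delayed by
#'     `settings$launch_delay_years` (default 2) in scenario II.}
#'   \item{`no_retreatment`}{no anti-PD-(L)1 rechallenge at recurrence.}
#'   \item{`none`}{no change; varied equals base bit-for-bit.}
#' }
#'
#' @param params A `pdl1_params` bundle.
#' @param toggle One of the toggle names above.
#' @return Object of class `pdl1_sensitivity`: tibble `outcome,
#'   base_impact, varied_impact, pct_change` with the toggle as attribute.
#' @export
run_scenario_analysis <- function(params,
                                  toggle = c("none", "uptake_100",
                                             "pop_up_20", "pop_down_20",
                                             "launch_delay",
                                             "no_retreatment")) {
  toggle <- match.arg(toggle)
  base <- run_comparison(params)
  varied <- switch(toggle,
    none = base,
    uptake_100 = run_comparison(params,
      scenario_definition("scenario_II", uptake = 1)),
    pop_up_20 = run_comparison(scale_population(params, 1.2)),
    pop_down_20 = run_comparison(scale_population(params, 0.8)),
    launch_delay = run_comparison(params,
      scenario_definition("scenario_II",
        launch_delay_years = params$settings$launch_delay_years)),
    no_retreatment = run_comparison(params,
      scenario_definition("scenario_II", retreatment_allowed = FALSE)))
  b <- setNames(base$cumulative$difference, base$cumulative$outcome)
  v <- setNames(varied$cumulative$difference, varied$cumulative$outcome)
  b <- b[sens_outcomes()]; v <- v[sens_outcomes()]
  out <- tibble::tibble(
    outcome = sens_outcomes(), base_impact = unname(b),
    varied_impact = unname(v),
    pct_change = ifelse(b == 0, NA_real_,
                        round_half_out(100 * (unname(v) - unname(b)) /
                                         unname(b))))
  structure(out, toggle = toggle, base = base, varied = varied,
            class = c("pdl1_sensitivity", class(out)))
}

#' Tumor-subgroup analyses
#'
#' Runs the scenario comparison for each of the six tumor subset
#' combinations (each single tumor and each pair) plus all three tumors.
#' The tumors are independent strata of the model, so any subset's impact
#' equals the sum of its members' single-tumor impacts.
#'
#' @param params A `pdl1_params` bundle.
#' @return Object of class `pdl1_subgroups`: tibble `subset, outcome,
#'   impact` with the full comparisons in the `comparisons` attribute.
#' @export
run_subgroups <- function(params) {
  tumors <- tumor_types()
  subsets <- c(lapply(tumors, identity),
               utils::combn(tumors, 2, simplify = FALSE),
               list(tumors))
  names(subsets) <- vapply(subsets, paste, "", collapse = "+")
  comparisons <- lapply(subsets, function(s) {
    run_comparison(params,
                   scenario_definition("scenario_II", tumor_subset = s))
  })
  out <- purrr::map2_dfr(comparisons, names(comparisons), function(cmp, nm) {
    tibble::tibble(subset = nm, outcome = cmp$cumulative$outcome,
                   impact = cmp$cumulative$difference)
  })
  structure(out, comparisons = comparisons,
            class = c("pdl1_subgroups", class(out)))
}

#' Registered one-way sensitivity variables
#'
#' The deterministic one-way analysis perturbs each registered input by
#' +/-10% of its base value, except hazard ratios, which move to the lower
#' and upper bounds of their 95% CI (falling back to +/-10% with a warning
#' when no CI is stored).  Mean body weight is carried as a demographic
#' input with no effect on health outcomes and is registered for interface
#' completeness.
#'
#' @param params A `pdl1_params` bundle.
#' @return Tibble `variable, kind`.
#' @export
sa_variables <- function(params) {
  tumors <- sort(unique(params$population$tumor))
  states <- setdiff(health_states(), "dead")
  dplyr::bind_rows(
    tibble::tibble(variable = "population_size", kind = "scale"),
    tibble::tibble(variable = paste0("eligible_", tumors), kind = "scale"),
    tibble::tibble(variable = c("fraction_female", "mean_age",
                                "mean_weight"), kind = "scale"),
    tibble::tibble(variable = paste0("utility_", states), kind = "scale"),
    tibble::tibble(variable = "ae_disutility", kind = "scale"),
    tibble::tibble(variable = paste0("hr_os_", tumors), kind = "hr_ci"),
    tibble::tibble(variable = paste0("hr_pfs_", tumors), kind = "hr_ci"))
}

perturb_params <- function(params, variable, side) {
  stopifnot(side %in% c("low", "high"))
  f <- if (side == "low") 0.9 else 1.1
  tumors <- sort(unique(params$population$tumor))
  if (variable == "population_size") {
    return(scale_population(params, f))
  }
  if (grepl("^eligible_", variable)) {
    return(scale_population(params, f, sub("^eligible_", "", variable)))
  }
  if (variable == "fraction_female") {
    params$demographics$fraction_female <-
      pmin(1, params$demographics$fraction_female * f)
    return(params)
  }
  if (variable == "mean_age") {
    params$demographics$mean_age <- params$demographics$mean_age * f
    return(params)
  }
  if (variable == "mean_weight") {
    params$demographics$mean_weight <- params$demographics$mean_weight * f
    return(params)
  }
  if (grepl("^utility_", variable)) {
    stt <- sub("^utility_", "", variable)
    sel <- params$utilities$state == stt
    params$utilities$utility[sel] <-
      pmin(1, params$utilities$utility[sel] * f)
    return(params)
  }
  if (variable == "ae_disutility") {
    params$ae_profiles$disutility <- params$ae_profiles$disutility * f
    return(params)
  }
  if (grepl("^hr_(os|pfs)_", variable)) {
    trn <- if (grepl("^hr_os_", variable)) "m1l_to_death" else "m1l_to_m2l"
    tm <- sub("^hr_(os|pfs)_", "", variable)
    tr <- params$transitions
    sel <- tr$tumor == tm & tr$transition == trn & tr$hazard_ratio != 1
    if (!any(sel)) {
      sel <- tr$tumor == tm & tr$transition == trn
    }
    has_ci <- sel & !is.na(tr$hr_lower) & !is.na(tr$hr_upper)
    if (any(has_ci)) {
      tr$hazard_ratio[has_ci] <- if (side == "low") tr$hr_lower[has_ci]
                                 else tr$hr_upper[has_ci]
      # keep the stored CI consistent with the shifted point value
      tr$hr_lower[has_ci] <- pmin(tr$hr_lower[has_ci],
                                  tr$hazard_ratio[has_ci])
      tr$hr_upper[has_ci] <- pmax(tr$hr_upper[has_ci],
                                  tr$hazard_ratio[has_ci])
    }
    no_ci <- sel & !(!is.na(tr$hr_lower) & !is.na(tr$hr_upper))
    if (any(no_ci)) {
      warning("no CI stored for ", variable,
              "; falling back to +/-10% of the hazard ratio",
              call. = FALSE)
      tr$hazard_ratio[no_ci] <- tr$hazard_ratio[no_ci] * f
    }
    params$transitions <- tr
    return(params)
  }
  stop("unknown sensitivity variable: ", variable, call. = FALSE)
}

#' One-way sensitivity analysis (tornado table)
#'
#' For each registered variable the full scenario comparison is re-run at
#' the variable's low and high perturbation with everything else at base
#' case, and the cumulative impact on each outcome is recorded.  Rows are
#' sorted by the impact range on `sort_by` (tornado ordering).
#'
#' @param params A `pdl1_params` bundle.
#' @param variables Character vector of variables to perturb (default: all
#'   of [sa_variables()]).
#' @param sort_by Outcome used for the tornado ordering (default
#'   `"life_years"`).
#' @return Object of class `pdl1_tornado`: tibble `variable, outcome,
#'   base, low, high, range`.
#' @export
one_way_sa <- function(params, variables = NULL, sort_by = "life_years") {
  vars <- variables %||% sa_variables(params)$variable
  sort_by <- match.arg(sort_by, sens_outcomes())
  base_cmp <- run_comparison(params)
  base <- setNames(base_cmp$cumulative$difference,
                   base_cmp$cumulative$outcome)
  impact <- function(p) {
    cmp <- run_comparison(p)
    setNames(cmp$cumulative$difference, cmp$cumulative$outcome)
  }
  rows <- purrr::map_dfr(vars, function(v) {
    lo <- impact(perturb_params(params, v, "low"))
    hi <- impact(perturb_params(params, v, "high"))
    tibble::tibble(variable = v, outcome = sens_outcomes(),
                   base = unname(base[sens_outcomes()]),
                   low = unname(lo[sens_outcomes()]),
                   high = unname(hi[sens_outcomes()]))
  })
  rows$range <- abs(rows$high - rows$low)
  ord <- rows[rows$outcome == sort_by, ]
  lev <- ord$variable[order(-ord$range)]
  rows <- dplyr::arrange(rows, match(.data$variable, lev), .data$outcome)
  structure(rows, sort_by = sort_by,
            class = c("pdl1_tornado", class(rows)))
}
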