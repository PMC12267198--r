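#' Uptake fractions implied by treated and eligible counts
#'
#' Elementwise `treated / eligible` per tumor and year (0 where the
#' eligible count is 0).  Applied to the shipped population fixture this
#' yields the default adoption-scenario uptake schedule, 63.3% in 2022
#' ramping to 88.7% from 2029 on.
#'
#' @param population Tibble with columns `tumor`, `year`, `eligible`,
#'   `treated` (as returned by [target_population()]).
#' @return Tibble `tumor, year, uptake`.
#' @export
#' @examples
#' implied_uptake(target_population())
implied_uptake <- function(population) {
  dplyr::transmute(population, .data$tumor, .data$year,
                   uptake = ifelse(.data$eligible > 0,
                                   .data$treated / .data$eligible, 0))
}

#' Shift an uptake schedule by a launch delay
#'
#' Sets uptake to 0 for the first `delay_years` years and shifts the
#' original ramp forward, truncating at the horizon.  A delay of 0 is the
#' identity; a delay at least as long as the horizon degenerates the
#' adoption scenario to the reference scenario.
#'
#' @param uptake Tibble `tumor, year, uptake`.
#' @param delay_years Non-negative integer delay.
#' @return Tibble of the same shape with the shifted schedule.
#' @export
delay_uptake <- function(uptake, delay_years) {
  delay_years <- as.integer(delay_years)
  stopifnot(delay_years >= 0)
  if (delay_years == 0) return(uptake)
  uptake |>
    dplyr::group_by(.data$tumor) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(uptake = dplyr::lag(.data$uptake, delay_years,
                                      default = 0)) |>
    dplyr::ungroup()
}

#' Build weekly entry cohorts from annual eligible counts
#'
#' Each calendar year's eligible count is divided evenly across its 52
#' model weeks (the model year is exactly 52 weeks), producing one entry
#' cohort per tumor and week.  The cohort sizes sum back to the annual
#' projection totals.
#'
#' @param population Tibble `tumor, year, eligible` (extra columns are
#'   ignored).
#' @param settings Settings list from a `pdl1_params` bundle (used for
#'   `start_year` and `horizon_years`).
#' @return Tibble `tumor, year, entry_week, size` with `entry_week` counted
#'   from the start of the projection window (0-based).
#' @export
weekly_cohorts <- function(population, settings) {
  years <- settings$start_year + seq_len(settings$horizon_years) - 1L
  missing <- setdiff(years, unique(population$year))
  if (length(missing) > 0) {
    stop("population projection missing year(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  population |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::select("tumor", "year", "eligible") |>
    tidyr::expand_grid(week = 0:51) |>
    dplyr::mutate(
      entry_week = (.data$year - settings$start_year) * 52L + .data$week,
      size = .data$eligible / 52) |>
    dplyr::select("tumor", "year", "entry_week", "size") |>
    dplyr::arrange(.data$tumor, .data$entry_week)
}

#' Define a policy scenario
#'
#' Scenario I reserves anti-PD-(L)1 agents for the metastatic setting: the
#' early-setting uptake is identically 0.  Scenario II adds them in the
#' neoadjuvant/adjuvant setting with a per-year uptake schedule, optionally
#' overridden, delayed, or restricted to a tumor subset.
#'
#' @param label `"scenario_I"` or `"scenario_II"`.
#' @param uptake Scenario II early-setting uptake override: `NULL` (use the
#'   bundle's schedule), a single fraction applied to every tumor and year
#'   (e.g. `1` for the 100%-uptake sensitivity scenario), or a tibble
#'   `tumor, year, uptake`.  Ignored for scenario I.
#' @param launch_delay_years Non-negative delay applied to the uptake
#'   schedule (scenario II only).
#' @param retreatment_allowed If `FALSE`, recurring patients are never
#'   rechallenged with anti-PD-(L)1 agents regardless of the time since
#'   adjuvant initiation (the no-retreatment sensitivity scenario).
#' @param tumor_subset Non-empty subset of [tumor_types()] to include.
#' @return An object of class `scenario_definition`.
#' @export
scenario_definition <- function(label = c("scenario_II", "scenario_I"),
                                uptake = NULL, launch_delay_years = 0L,
                                retreatment_allowed = TRUE,
                                tumor_subset = tumor_types()) {
  label <- match.arg(label)
  if (length(tumor_subset) == 0) {
    stop("tumor_subset must be non-empty", call. = FALSE)
  }
  tumor_subset <- match.arg(tumor_subset, tumor_types(), several.ok = TRUE)
  if (is.numeric(uptake) && length(uptake) == 1 &&
      (uptake < 0 || uptake > 1)) {
    stop("uptake override must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(label = label, uptake = uptake,
         launch_delay_years = as.integer(launch_delay_years),
         retreatment_allowed = isTRUE(retreatment_allowed),
         tumor_subset = tumor_subset),
    class = "scenario_definition")
}

#' @export
print.scenario_definition <- function(x, ...) {
  cat("<scenario_definition> ", x$label, "\n", sep = "")
  cat("  tumors: ", paste(x$tumor_subset, collapse = ", "), "\n", sep = "")
  if (x$label == "scenario_II") {
    up <- if (is.null(x$uptake)) "bundle schedule"
          else if (is.numeric(x$uptake) && length(x$uptake) == 1)
            paste0(100 * x$uptake, "% flat") else "custom schedule"
    cat("  uptake: ", up, "; launch delay ", x$launch_delay_years,
        " y; retreatment ",
        if (x$retreatment_allowed) "allowed" else "disallowed", "\n",
        sep = "")
  }
  invisible(x)
}

# Resolved per-tumor/year uptake under a scenario definition.
scenario_uptake <- function(params, scenario) {
  up <- params$uptake[params$uptake$tumor %in% scenario$tumor_subset, ]
  if (scenario$label == "scenario_I") {
    up$uptake <- 0
    return(up)
  }
  if (!is.null(scenario$uptake)) {
    if (is.numeric(scenario$uptake) && length(scenario$uptake) == 1) {
      up$uptake <- scenario$uptake
    } else {
      ov <- tibble::as_tibble(scenario$uptake)
      up <- up |>
        dplyr::select(-"uptake") |>
        dplyr::left_join(ov, by = c("tumor", "year"))
      if (anyNA(up$uptake)) {
        stop("uptake override does not cover every tumor/year", call. = FALSE)
      }
    }
  }
  if (scenario$launch_delay_years > 0) {
    up <- delay_uptake(up, scenario$launch_delay_years)
  }
  up
}

#' Allocate weekly cohorts to adjuvant treatment arms
#'
#' Splits each weekly entry cohort across the adjuvant arms according to
#' the scenario: under scenario I the whole cohort goes to the traditional
#' early-setting options (watchful waiting or dabrafenib+trametinib for
#' melanoma, watchful waiting for RCC, chemotherapy for TNBC); under
#' scenario II the year's uptake fraction goes to the anti-PD-(L)1 arm and
#' the remainder to the traditional options.  Arm sizes sum exactly to the
#' cohort size.
#'
#' @param cohorts Tibble from [weekly_cohorts()].
#' @param scenario A [scenario_definition()].
#' @param params The `pdl1_params` bundle (for the uptake schedule and
#'   traditional shares).
#' @return Tibble `tumor, year, entry_week, arm, size`.
#' @export
allocate_arms <- function(cohorts, scenario, params) {
  up <- scenario_uptake(params, scenario)
  shares <- params$traditional_shares
  arms <- dplyr::bind_rows(
    tibble::tibble(tumor = unique(shares$tumor), arm = pdl1_arm,
                   weight_kind = "uptake", weight = 1),
    dplyr::transmute(shares, .data$tumor, .data$arm,
                     weight_kind = "traditional", weight = .data$share))
  cohorts |>
    dplyr::filter(.data$tumor %in% scenario$tumor_subset) |>
    dplyr::inner_join(up, by = c("tumor", "year")) |>
    dplyr::inner_join(arms, by = "tumor", relationship = "many-to-many") |>
    dplyr::mutate(size = .data$size *
                    ifelse(.data$weight_kind == "uptake", .data$uptake,
                           (1 - .data$uptake) * .data$weight)) |>
    dplyr::select("tumor", "year", "entry_week", "arm", "size") |>
    dplyr::arrange(.data$tumor, .data$entry_week, .data$arm)
}
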