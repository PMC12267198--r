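#' Assemble and validate a full model parameter bundle
#'
#' Collects every input the projection needs into a single validated object.
#' All user-facing components are tibbles; `settings` is a named list.  Every
#' invariant of the model inputs is checked here, so downstream engines can
#' assume a well-formed bundle.
#'
#' @param settings Named list of global settings.  Recognised fields (with
#'   defaults): `start_year` (2022), `horizon_years` (10),
#'   `annual_discount_rate` (0.015), `retreatment_threshold_weeks` (78, i.e.
#'   18 months), `discount_event_counts` (FALSE: recurrences, treatments,
#'   adverse events and deaths are reported as undiscounted counts of
#'   occurrences), `discount_from` (`"model_start"` or `"entry"`) and
#'   `launch_delay_years` (2, used by the delayed-launch sensitivity
#'   scenario).
#' @param population Tibble `tumor, year, eligible, treated`: annual counts
#'   of patients eligible for early-setting anti-PD-(L)1 treatment, and the
#'   number projected to receive it under the adoption scenario.
#' @param uptake Tibble `tumor, year, uptake`: scenario II early-setting
#'   uptake fractions.
#' @param traditional_shares Tibble `tumor, arm, share`: allocation among
#'   the traditional early-setting options (shares sum to 1 per tumor).
#' @param transitions Tibble `tumor, arm, transition, treatment, family, p1,
#'   p2, p3, hazard_ratio, hr_lower, hr_upper`: one parametric law per
#'   health-state transition and arm.  `treatment` is `NA` except for the
#'   first-line metastatic laws (`m1l_to_m2l`, `m1l_to_death`), which are
#'   keyed by 1L treatment option.
#' @param mixes Tibble `tumor, arm, stratum, line, treatment, fraction`:
#'   metastatic treatment mixes conditional on the adjuvant arm and the
#'   retreatment-eligibility stratum; fractions sum to 1 per
#'   tumor/arm/stratum/line.
#' @param utilities Tibble `tumor, state, utility` for the four alive
#'   states; the dead state has utility 0 implicitly.
#' @param age_adjustment Tibble `age_low, age_high, female, male`:
#'   multiplicative age/sex utility adjustment factors in `(0, 1]` on
#'   contiguous age bands.
#' @param ae_profiles Tibble `tumor, setting, treatment, events_per_patient,
#'   weeks_per_event, disutility`: adverse-event profiles per treatment
#'   setting (`adjuvant`, `m1l`, `m2l`).
#' @param life_table Tibble `age, sex, qx`: annual background death
#'   probabilities for ages 0 to a closing row with `qx = 1`.
#' @param demographics Tibble `tumor, mean_age, fraction_female,
#'   mean_weight`: cohort entry characteristics.  Weight is carried for
#'   interface completeness only; it has no effect on health outcomes.
#' @return A validated object of class `pdl1_params`.
#' @seealso [synth_params()] for a complete synthetic bundle,
#'   [read_model_config()] / [write_model_config()] for file round-trips.
#' @export
model_params <- function(settings = list(), population, uptake,
                         traditional_shares, transitions, mixes, utilities,
                         age_adjustment, ae_profiles, life_table,
                         demographics) {
  settings <- utils::modifyList(default_settings(), settings)
  params <- structure(
    list(settings = settings,
         population = tibble::as_tibble(population),
         uptake = tibble::as_tibble(uptake),
         traditional_shares = tibble::as_tibble(traditional_shares),
         transitions = tibble::as_tibble(transitions),
         mixes = tibble::as_tibble(mixes),
         utilities = tibble::as_tibble(utilities),
         age_adjustment = tibble::as_tibble(age_adjustment),
         ae_profiles = tibble::as_tibble(ae_profiles),
         life_table = tibble::as_tibble(life_table),
         demographics = tibble::as_tibble(demographics)),
    class = "pdl1_params")
  params <- canonicalize_params(params)
  validate_params(params)
  params
}

default_settings <- function() {
  list(start_year = 2022L,
       horizon_years = 10L,
       annual_discount_rate = 0.015,
       retreatment_threshold_weeks = 78L,  # 18 months x 52/12
       discount_event_counts = FALSE,
       discount_from = "model_start",
       launch_delay_years = 2L)
}

canonicalize_params <- function(params) {
  st <- params$settings
  st$start_year <- as.integer(st$start_year)
  st$horizon_years <- as.integer(st$horizon_years)
  st$retreatment_threshold_weeks <- as.integer(st$retreatment_threshold_weeks)
  st$launch_delay_years <- as.integer(st$launch_delay_years)
  st$discount_event_counts <- isTRUE(st$discount_event_counts)
  st$annual_discount_rate <- as.numeric(st$annual_discount_rate)
  params$settings <- st[order(names(st))]
  # canonical column types, so a JSON write/read round trip is the identity
  num_cols <- list(
    population = c("eligible", "treated"), uptake = "uptake",
    traditional_shares = "share",
    transitions = c("p1", "p2", "p3", "hazard_ratio", "hr_lower",
                    "hr_upper"),
    mixes = "fraction", utilities = "utility",
    age_adjustment = c("age_low", "age_high", "female", "male"),
    ae_profiles = c("events_per_patient", "weeks_per_event", "disutility"),
    life_table = "qx",
    demographics = c("mean_age", "fraction_female", "mean_weight"))
  for (nm in names(num_cols)) {
    for (cl in intersect(num_cols[[nm]], names(params[[nm]]))) {
      params[[nm]][[cl]] <- as.numeric(params[[nm]][[cl]])
    }
  }
  params$transitions$treatment <- as.character(params$transitions$treatment)
  for (nm in c("population", "uptake")) {
    params[[nm]]$year <- as.integer(params[[nm]]$year)
    params[[nm]] <- dplyr::arrange(params[[nm]], .data$tumor, .data$year)
  }
  params$life_table$age <- as.integer(params$life_table$age)
  params$life_table <- dplyr::arrange(params$life_table, .data$sex, .data$age)
  params$transitions <- dplyr::arrange(params$transitions, .data$tumor,
                                       .data$arm, .data$transition,
                                       .data$treatment)
  params$mixes <- dplyr::arrange(params$mixes, .data$tumor, .data$arm,
                                 .data$line, .data$stratum, .data$treatment)
  params
}

fail <- function(section, field, rule) {
  stop("config validation [", section, "]: ", field, ": ", rule,
       call. = FALSE)
}

#' Validate a parameter bundle
#'
#' Checks every structural and numeric invariant of a [model_params()]
#' bundle and fails with an error naming the offending section and field.
#' Called automatically by the constructor and the config reader.
#'
#' @param params A `pdl1_params` object.
#' @return `params`, invisibly, if all checks pass.
#' @export
validate_params <- function(params) {
  st <- params$settings
  if (st$annual_discount_rate < 0)
    fail("settings", "annual_discount_rate", "must be >= 0")
  if (st$retreatment_threshold_weeks <= 0)
    fail("settings", "retreatment_threshold_weeks", "must be > 0")
  if (st$horizon_years < 1)
    fail("settings", "horizon_years", "must be >= 1")
  if (!st$discount_from %in% c("model_start", "entry"))
    fail("settings", "discount_from", "must be 'model_start' or 'entry'")
  if (st$launch_delay_years < 0)
    fail("settings", "launch_delay_years", "must be >= 0")

  tumors <- sort(unique(params$population$tumor))
  if (length(tumors) == 0) fail("population", "tumor", "no rows")
  if (!all(tumors %in% tumor_types()))
    fail("population", "tumor",
         paste("unknown tumor label(s):",
               paste(setdiff(tumors, tumor_types()), collapse = ", ")))
  years <- st$start_year + seq_len(st$horizon_years) - 1L
  for (tm in tumors) {
    py <- params$population$year[params$population$tumor == tm]
    if (!identical(sort(py), years))
      fail("population", tm, "years must cover the full horizon exactly once")
  }
  if (any(params$population$eligible < 0))
    fail("population", "eligible", "counts must be >= 0")
  if (any(params$population$treated < 0))
    fail("population", "treated", "counts must be >= 0")

  if (any(params$uptake$uptake < 0 | params$uptake$uptake > 1))
    fail("uptake", "uptake", "fractions must lie in [0, 1]")
  for (tm in tumors) {
    uy <- params$uptake$year[params$uptake$tumor == tm]
    if (!identical(sort(uy), years))
      fail("uptake", tm, "years must cover the full horizon exactly once")
  }

  ts <- params$traditional_shares
  if (any(ts$share < 0 | ts$share > 1))
    fail("traditional_shares", "share", "must lie in [0, 1]")
  for (tm in tumors) {
    s <- sum(ts$share[ts$tumor == tm])
    if (abs(s - 1) > 1e-9)
      fail("traditional_shares", tm,
           paste0("shares sum to ", signif(s, 10), ", not 1"))
    if (pdl1_arm %in% ts$arm[ts$tumor == tm])
      fail("traditional_shares", tm,
           "the anti-PD-(L)1 arm is not a traditional option")
  }

  mx <- params$mixes
  if (any(mx$fraction < 0 | mx$fraction > 1))
    fail("mixes", "fraction", "must lie in [0, 1]")
  if (!all(mx$stratum %in% eligibility_strata()))
    fail("mixes", "stratum", "unknown stratum label")
  if (!all(mx$line %in% c("m1l", "m2l")))
    fail("mixes", "line", "must be 'm1l' or 'm2l'")
  key <- paste(mx$tumor, mx$arm, mx$stratum, mx$line)
  sums <- tapply(mx$fraction, key, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad) > 0)
    fail("mixes", bad[1],
         paste0("fractions sum to ", signif(sums[bad[1]], 10), ", not 1"))

  # every arm must have a complete set of transition laws
  tr <- params$transitions
  plain <- c("rf_to_lr", "rf_to_met", "rf_to_death", "lr_to_met",
             "lr_to_death", "m2l_to_death")
  for (tm in tumors) {
    arms <- arm_labels(params, tm)
    t1 <- m1l_treatments(params, tm)
    t2 <- m2l_treatments(params, tm)
    if (length(t1) == 0) fail("mixes", tm, "no 1L metastatic mix defined")
    if (length(t2) == 0) fail("mixes", tm, "no 2L metastatic mix defined")
    for (arm in arms) {
      sub <- tr[tr$tumor == tm & tr$arm == arm, ]
      for (trn in plain) {
        if (sum(sub$transition == trn & is.na(sub$treatment)) != 1L)
          fail("transitions", paste(tm, arm, trn),
               "exactly one law required")
      }
      for (trn in c("m1l_to_m2l", "m1l_to_death")) {
        for (t in t1) {
          if (sum(sub$transition == trn & sub$treatment %in% t) != 1L)
            fail("transitions", paste(tm, arm, trn, t),
                 "exactly one law required per 1L treatment")
        }
      }
      mix_arms <- unique(mx$arm[mx$tumor == tm])
      if (!arm %in% mix_arms)
        fail("mixes", paste(tm, arm), "no metastatic mixes for this arm")
      for (s in eligibility_strata()) {
        for (ln in c("m1l", "m2l")) {
          if (sum(mx$tumor == tm & mx$arm == arm & mx$stratum == s &
                    mx$line == ln) == 0)
            fail("mixes", paste(tm, arm, s, ln), "mix missing")
        }
      }
    }
  }
  # each stored law must construct a valid survival_spec
  for (i in seq_len(nrow(tr))) {
    res <- tryCatch(spec_from_row(tr[i, ]), error = function(e) e)
    if (inherits(res, "error"))
      fail("transitions",
           paste(tr$tumor[i], tr$arm[i], tr$transition[i]),
           conditionMessage(res))
  }
  # post-recurrence laws are shared across adjuvant arms
  rep_shared <- validate_shared_transitions(params)
  if (!all(rep_shared$consistent))
    fail("transitions",
         paste(rep_shared$tumor[!rep_shared$consistent],
               rep_shared$transition[!rep_shared$consistent],
               collapse = "; "),
         "locoregional-recurrence laws must be identical across arms")

  ut <- params$utilities
  if (any(ut$utility < 0 | ut$utility > 1))
    fail("utilities", "utility", "must lie in [0, 1]")
  alive <- setdiff(health_states(), "dead")
  for (tm in tumors) {
    have <- ut$state[ut$tumor == tm]
    if (!all(alive %in% have))
      fail("utilities", tm, "a utility is required for every alive state")
    if (any(ut$utility[ut$tumor == tm & ut$state == "dead"] != 0))
      fail("utilities", tm, "utility of the dead state must be 0")
  }

  aa <- params$age_adjustment
  if (any(aa$female <= 0 | aa$female > 1) || any(aa$male <= 0 | aa$male > 1))
    fail("age_adjustment", "factor", "must lie in (0, 1]")
  aa <- aa[order(aa$age_low), ]
  if (nrow(aa) > 1 && any(aa$age_low[-1] != aa$age_high[-nrow(aa)] + 1))
    fail("age_adjustment", "bands", "age bands must be contiguous")

  ae <- params$ae_profiles
  if (any(ae$events_per_patient < 0))
    fail("ae_profiles", "events_per_patient", "must be >= 0")
  if (any(ae$weeks_per_event < 0))
    fail("ae_profiles", "weeks_per_event", "must be >= 0")
  if (any(ae$disutility > 0))
    fail("ae_profiles", "disutility", "must be <= 0")
  if (!all(ae$setting %in% c("adjuvant", "m1l", "m2l")))
    fail("ae_profiles", "setting", "must be adjuvant, m1l or m2l")
  for (tm in tumors) {
    for (arm in arm_labels(params, tm)) {
      if (sum(ae$tumor == tm & ae$setting == "adjuvant" &
                ae$treatment == arm) != 1L)
        fail("ae_profiles", paste(tm, "adjuvant", arm),
             "exactly one adjuvant AE profile required per arm")
    }
    for (t in m1l_treatments(params, tm)) {
      if (sum(ae$tumor == tm & ae$setting == "m1l" & ae$treatment == t) != 1L)
        fail("ae_profiles", paste(tm, "m1l", t),
             "exactly one AE profile required per 1L treatment")
    }
    for (t in m2l_treatments(params, tm)) {
      if (sum(ae$tumor == tm & ae$setting == "m2l" & ae$treatment == t) != 1L)
        fail("ae_profiles", paste(tm, "m2l", t),
             "exactly one AE profile required per 2L treatment")
    }
  }

  lt <- params$life_table
  if (any(lt$qx < 0 | lt$qx > 1))
    fail("life_table", "qx", "must lie in [0, 1]")
  for (sx in c("female", "male")) {
    sub <- lt[lt$sex == sx, ]
    if (nrow(sub) == 0) fail("life_table", sx, "missing sex stratum")
    if (sub$qx[which.max(sub$age)] != 1)
      fail("life_table", sx, "the closing row must have qx = 1")
  }

  dm <- params$demographics
  for (tm in tumors) {
    if (sum(dm$tumor == tm) != 1L)
      fail("demographics", tm, "exactly one row required per tumor")
  }
  if (any(dm$mean_age < 0)) fail("demographics", "mean_age", "must be >= 0")
  if (any(dm$fraction_female < 0 | dm$fraction_female > 1))
    fail("demographics", "fraction_female", "must lie in [0, 1]")
  if (any(dm$mean_weight <= 0))
    fail("demographics", "mean_weight", "must be > 0")

  invisible(params)
}

#' Report on sharing of post-recurrence laws across adjuvant arms
#'
#' The transitions out of the locoregional-recurrence state are assumed
#' identical across adjuvant treatment arms within a tumor: the adjuvant
#' choice changes who recurs, not what happens after recurrence.  This
#' report-only check compares the `lr_to_met` and `lr_to_death` laws across
#' arms and lists any mismatch; a single-arm tumor passes vacuously.
#'
#' @param params A `pdl1_params` bundle (or its `transitions` tibble).
#' @return Tibble `tumor, transition, consistent, detail`.
#' @export
validate_shared_transitions <- function(params) {
  tr <- if (inherits(params, "pdl1_params")) params$transitions else params
  out <- list()
  for (tm in sort(unique(tr$tumor))) {
    for (trn in c("lr_to_met", "lr_to_death")) {
      sub <- tr[tr$tumor == tm & tr$transition == trn, ]
      cols <- c("family", "p1", "p2", "p3", "hazard_ratio")
      uniq <- unique(sub[, cols])
      ok <- nrow(uniq) <= 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        tumor = tm, transition = trn, consistent = ok,
        detail = if (ok) "shared across arms" else
          paste0(nrow(uniq), " distinct laws across arms: ",
                 paste(sub$arm, collapse = ", ")))
    }
  }
  dplyr::bind_rows(out)
}

# ---- internal accessors -------------------------------------------------

arm_labels <- function(params, tumor) {
  trad <- params$traditional_shares$arm[params$traditional_shares$tumor ==
                                          tumor]
  c(pdl1_arm, sort(trad))
}

m1l_treatments <- function(params, tumor) {
  mx <- params$mixes
  sort(unique(mx$treatment[mx$tumor == tumor & mx$line == "m1l"]))
}

m2l_treatments <- function(params, tumor) {
  mx <- params$mixes
  sort(unique(mx$treatment[mx$tumor == tumor & mx$line == "m2l"]))
}

spec_from_row <- function(row) {
  npar <- surv_family_npar()[[row$family]]
  survival_spec(row$family,
                as.numeric(row[1, c("p1", "p2", "p3")])[seq_len(npar)],
                hazard_ratio = row$hazard_ratio,
                hr_lower = row$hr_lower, hr_upper = row$hr_upper)
}

get_transition_spec <- function(params, tumor, arm, transition,
                                treatment = NA_character_) {
  tr <- params$transitions
  sel <- tr$tumor == tumor & tr$arm == arm & tr$transition == transition
  sel <- sel & (if (is.na(treatment)) is.na(tr$treatment)
                else tr$treatment %in% treatment)
  row <- tr[sel, ]
  if (nrow(row) != 1L) {
    stop("no unique transition law for ",
         paste(tumor, arm, transition, treatment), call. = FALSE)
  }
  spec_from_row(row)
}

# Mix fractions per stratum for one tumor/arm/line, ordered as `treatments`.
# With retreatment disabled every stratum maps to the no-retreatment
# (before-threshold) mix.
mix_by_stratum <- function(params, tumor, arm, line, treatments,
                           retreatment_allowed = TRUE) {
  mx <- params$mixes
  get1 <- function(stratum) {
    sub <- mx[mx$tumor == tumor & mx$arm == arm & mx$line == line &
                mx$stratum == stratum, ]
    f <- setNames(rep(0, length(treatments)), treatments)
    f[sub$treatment] <- sub$fraction
    f
  }
  before <- get1("before_threshold")
  after <- if (retreatment_allowed) get1("at_or_after_threshold") else before
  list(before_threshold = before, at_or_after_threshold = after)
}

utility_vector <- function(params, tumor) {
  ut <- params$utilities
  alive <- setdiff(health_states(), "dead")
  vapply(alive, function(s) {
    ut$utility[ut$tumor == tumor & ut$state == s][1]
  }, numeric(1))
}

# Sex-weighted multiplicative utility adjustment per age.
adjustment_vector <- function(params, ages, fraction_female) {
  aa <- params$age_adjustment[order(params$age_adjustment$age_low), ]
  idx <- pmin(findInterval(floor(ages), aa$age_low), nrow(aa))
  idx[idx < 1L] <- 1L
  fraction_female * aa$female[idx] + (1 - fraction_female) * aa$male[idx]
}

ae_profile_row <- function(params, tumor, setting, treatment) {
  ae <- params$ae_profiles
  row <- ae[ae$tumor == tumor & ae$setting == setting &
              ae$treatment == treatment, ]
  if (nrow(row) != 1L) {
    stop("no unique AE profile for ", paste(tumor, setting, treatment),
         call. = FALSE)
  }
  row
}

ae_vectors <- function(params, tumor, setting, treatments) {
  rows <- lapply(treatments, function(t)
    ae_profile_row(params, tumor, setting, t))
  epp <- vapply(rows, function(r) r$events_per_patient, numeric(1))
  loss <- vapply(rows, function(r)
    r$events_per_patient * r$weeks_per_event * abs(r$disutility) / 52,
    numeric(1))
  list(events = setNames(epp, treatments), qaly_loss = setNames(loss,
                                                                treatments))
}

#' @export
print.pdl1_params <- function(x, ...) {
  st <- x$settings
  tumors <- sort(unique(x$population$tumor))
  cat("<pdl1_params> ", st$horizon_years, "-year projection from ",
      st$start_year, "\n", sep = "")
  cat("  tumors: ", paste(tumors, collapse = ", "), "\n", sep = "")
  cat("  discount rate ", st$annual_discount_rate,
      ", retreatment threshold ", st$retreatment_threshold_weeks,
      " weeks\n", sep = "")
  cat("  eligible patients: ",
      format(round(sum(x$population$eligible)), big.mark = ","), "\n",
      sep = "")
  invisible(x)
}
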