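# Minimal single-tumor all-exponential bundles with closed-form behaviour.
# All rates are weekly; anything not supplied is a zero-hazard transition.

zero_life_table <- function() {
  lt <- synth_life_table()
  lt$qx <- 0
  lt$qx[lt$age == max(lt$age)] <- 1
  lt
}

toy_params <- function(tumor = "melanoma",
                       rates = list(),
                       hr_pd = 1,
                       uptake = 0.65,
                       discount = 0,
                       eligible = 52,
                       utilities = rep(1, 4),
                       adjustment = 1,
                       ae_adjuvant_pdl1 = c(0, 0, 0),  # epp, wpe, disutility
                       ae_adjuvant_trad = c(0, 0, 0),
                       ae_m1l = c(0, 0, 0),
                       ae_m2l = c(0, 0, 0),
                       pdl1_mix_same = FALSE,
                       mean_age = 50,
                       settings = list()) {
  r <- utils::modifyList(
    list(rfd = 0, rflr = 0, rfm = 0, lrm = 0, lrd = 0,
         m12 = 0, m1d = 0, m2d = 0),
    rates)
  years <- 2022:2031
  arms <- c("watchful_waiting", "anti_pdl1")
  t1 <- c("alt_1l", "pdl1_1l")
  t2 <- "chemo_2l"

  trow <- function(arm, transition, rate, treatment = NA, hr = 1,
                   lo = NA, up = NA) {
    tibble::tibble(tumor = tumor, arm = arm, transition = transition,
                   treatment = as.character(treatment),
                   family = "exponential", p1 = rate, p2 = NA_real_,
                   p3 = NA_real_, hazard_ratio = hr, hr_lower = lo,
                   hr_upper = up)
  }
  transitions <- dplyr::bind_rows(lapply(arms, function(a) {
    hr <- if (a == "anti_pdl1") hr_pd else 1
    ci <- if (a == "anti_pdl1") c(hr_pd * 0.8, hr_pd * 1.25) else c(NA, NA)
    dplyr::bind_rows(
      trow(a, "rf_to_lr", r$rflr, hr = hr, lo = ci[1], up = ci[2]),
      trow(a, "rf_to_met", r$rfm, hr = hr, lo = ci[1], up = ci[2]),
      trow(a, "rf_to_death", r$rfd),
      trow(a, "lr_to_met", r$lrm),
      trow(a, "lr_to_death", r$lrd),
      trow(a, "m1l_to_m2l", r$m12, treatment = "alt_1l"),
      trow(a, "m1l_to_m2l", r$m12, treatment = "pdl1_1l"),
      trow(a, "m1l_to_death", r$m1d, treatment = "alt_1l"),
      trow(a, "m1l_to_death", r$m1d, treatment = "pdl1_1l"),
      trow(a, "m2l_to_death", r$m2d))
  }))

  mrow <- function(arm, stratum, line, treatment, fraction) {
    tibble::tibble(tumor = tumor, arm = arm, stratum = stratum, line = line,
                   treatment = treatment, fraction = fraction)
  }
  trad_mix <- function(arm) dplyr::bind_rows(
    mrow(arm, "before_threshold", "m1l", t1, c(0.5, 0.5)),
    mrow(arm, "at_or_after_threshold", "m1l", t1, c(0.5, 0.5)),
    mrow(arm, "before_threshold", "m2l", t2, 1),
    mrow(arm, "at_or_after_threshold", "m2l", t2, 1))
  pdl1_mix <- if (pdl1_mix_same) trad_mix("anti_pdl1") else dplyr::bind_rows(
    mrow("anti_pdl1", "before_threshold", "m1l", t1, c(1, 0)),
    mrow("anti_pdl1", "at_or_after_threshold", "m1l", t1, c(0.5, 0.5)),
    mrow("anti_pdl1", "before_threshold", "m2l", t2, 1),
    mrow("anti_pdl1", "at_or_after_threshold", "m2l", t2, 1))

  aerow <- function(setting, treatment, v) {
    tibble::tibble(tumor = tumor, setting = setting, treatment = treatment,
                   events_per_patient = v[1], weeks_per_event = v[2],
                   disutility = v[3])
  }
  ae_profiles <- dplyr::bind_rows(
    aerow("adjuvant", "anti_pdl1", ae_adjuvant_pdl1),
    aerow("adjuvant", "watchful_waiting", ae_adjuvant_trad),
    aerow("m1l", "alt_1l", ae_m1l),
    aerow("m1l", "pdl1_1l", ae_m1l),
    aerow("m2l", "chemo_2l", ae_m2l))

  model_params(
    settings = utils::modifyList(list(annual_discount_rate = discount),
                                 settings),
    population = tibble::tibble(tumor = tumor, year = years,
                                eligible = eligible,
                                treated = eligible * uptake),
    uptake = tibble::tibble(tumor = tumor, year = years, uptake = uptake),
    traditional_shares = tibble::tibble(tumor = tumor,
                                        arm = "watchful_waiting", share = 1),
    transitions = transitions,
    mixes = dplyr::bind_rows(trad_mix("watchful_waiting"), pdl1_mix),
    utilities = tibble::tibble(tumor = tumor,
                               state = setdiff(health_states(), "dead"),
                               utility = utilities),
    age_adjustment = tibble::tibble(age_low = 0, age_high = 120,
                                    female = adjustment, male = adjustment),
    ae_profiles = ae_profiles,
    life_table = zero_life_table(),
    demographics = tibble::tibble(tumor = tumor, mean_age = mean_age,
                                  fraction_female = 0.5, mean_weight = 75))
}

# Cumulative differences of a comparison as a named vector.
impact_vector <- function(cmp) {
  setNames(cmp$cumulative$difference, cmp$cumulative$outcome)
}
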