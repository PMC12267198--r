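test_that("degenerate cohorts behave exactly", {
  p <- toy_params()  # all hazards zero, zero life table
  tr <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = 0)
  expect_true(all(tr$occupancy == 0))
  expect_true(all(tr$deaths == 0))

  # no exits anywhere: the whole cohort stays recurrence-free every cycle
  tr <- run_cohort(p, "melanoma", "watchful_waiting", entry_size = 250)
  expect_true(all(tr$occupancy[, "recurrence_free"] == 250))
  expect_true(all(tr$occupancy[, setdiff(colnames(tr$occupancy),
                                         "recurrence_free")] == 0))
  expect_equal(sum(tr$recurrences), 0)
})

test_that("a single exponential death exit decays in closed form", {
  lam <- 0.005
  p <- toy_params(rates = list(rfd = lam))
  tr <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = 1000)
  k <- 0:(tr$n_cycles - 1)
  expect_equal(tr$occupancy[, "recurrence_free"], 1000 * exp(-lam * k),
               tolerance = 1e-9)
  expect_equal(tr$occupancy[, "dead"], 1000 * (1 - exp(-lam * k)),
               tolerance = 1e-9)
})

test_that("traces conserve persons and absorb deaths monotonically", {
  p <- toy_params(rates = list(rfd = 2e-4, rflr = 0.004, rfm = 0.001,
                               lrm = 0.01, lrd = 0.003, m12 = 0.015,
                               m1d = 0.008, m2d = 0.02),
                  hr_pd = 0.6)
  for (arm in c("watchful_waiting", "anti_pdl1")) {
    tr <- run_cohort(p, "melanoma", arm, entry_size = 1,
                     entry_week = sample(0:519, 1))
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))
    expect_true(all(tr$occupancy >= 0))
    # ledger identities
    expect_equal(sum(tr$deaths),
                 unname(tr$occupancy[tr$n_cycles, "dead"]) +
                   tr$deaths[tr$n_cycles], tolerance = 1e-12)
    expect_lte(sum(tr$recurrences), 1 + 1e-12)
  }
})

test_that("the background-mortality floor binds when trial mortality is low", {
  p <- toy_params(rates = list(rfd = 0), mean_age = 78)
  p$life_table <- synth_life_table()  # real Gompertz shape
  validate_params(p)
  tr <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = 100)
  # with zero trial mortality, deaths follow the life table alone
  q78 <- pdl1impact:::weekly_mortality_pooled(p$life_table, 78, 0.5)
  expect_equal(tr$deaths[1], 100 * q78, tolerance = 1e-12)
  expect_gt(sum(tr$deaths), 0)
})

test_that("retreatment eligibility splits at the threshold cycle", {
  expect_identical(retreatment_stratum(77, 78), "before_threshold")
  expect_identical(retreatment_stratum(78, 78), "at_or_after_threshold")
  expect_identical(retreatment_stratum(0), "before_threshold")

  # in the engine: the anti-PD-(L)1 arm's 1L mix excludes retreatment
  # before the threshold and includes it from the threshold on
  p <- toy_params(rates = list(rflr = 0.004, lrm = 0.01))
  tr <- run_cohort(p, "melanoma", "anti_pdl1")
  thr <- p$settings$retreatment_threshold_weeks
  init <- tr$m1_initiations
  early <- seq_len(thr)
  late <- (thr + 1):tr$n_cycles
  expect_true(all(init[early, "pdl1_1l"] == 0))
  expect_equal(init[late, "pdl1_1l"], init[late, "alt_1l"],
               tolerance = 1e-12)  # 50/50 rechallenge mix

  # with retreatment disabled, every stratum uses the no-retreatment mix
  tr0 <- run_cohort(p, "melanoma", "anti_pdl1", retreatment_allowed = FALSE)
  expect_true(all(tr0$m1_initiations[, "pdl1_1l"] == 0))
})

test_that("identical arms yield identical traces", {
  p <- toy_params(rates = list(rfd = 2e-4, rflr = 0.004, lrm = 0.01,
                               lrd = 0.003, m12 = 0.015, m1d = 0.008,
                               m2d = 0.02),
                  hr_pd = 1, pdl1_mix_same = TRUE)
  tr_a <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = 10)
  tr_b <- run_cohort(p, "melanoma", "watchful_waiting", entry_size = 10)
  expect_identical(tr_a$occupancy, tr_b$occupancy)
  expect_identical(tr_a$m1_initiations, tr_b$m1_initiations)
  expect_identical(tr_a$deaths, tr_b$deaths)
})

test_that("lower recurrence hazards never cost recurrence-free life-years", {
  base <- list(rfd = 2e-4, rflr = 0.004, rfm = 0.001, lrm = 0.01,
               lrd = 0.003, m12 = 0.015, m1d = 0.008, m2d = 0.02)
  rf_ly <- vapply(c(1, 0.8, 0.55, 0.3), function(hr) {
    p <- toy_params(rates = base, hr_pd = hr)
    tr <- run_cohort(p, "melanoma", "anti_pdl1")
    sum(trace_outcomes(tr, p)$per_year$rf_life_years)
  }, numeric(1))
  expect_true(all(diff(rf_ly) > 0))
})

test_that("the tidy trace export is a conserving long table", {
  p <- toy_params(rates = list(rflr = 0.004, lrm = 0.01, m12 = 0.015))
  tr <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = 7)
  td <- tidy(tr)
  expect_identical(names(td), c("cycle", "state", "stratum", "persons"))
  expect_equal(nrow(td), tr$n_cycles * 7L)  # 3 plain states + 2x2 strata
  expect_true(all(td$persons >= 0))
  tot <- tapply(td$persons, td$cycle, sum)
  expect_equal(as.numeric(tot), rep(7, tr$n_cycles), tolerance = 1e-9)
})

test_that("the microsimulation is reproducible and exact in degenerate cases", {
  p <- toy_params()  # zero hazards, zero discounting
  ms1 <- simulate_cohort(p, "melanoma", "anti_pdl1", n = 200, seed = 42)
  ms2 <- simulate_cohort(p, "melanoma", "anti_pdl1", n = 200, seed = 42)
  expect_identical(ms1$outcomes, ms2$outcomes)
  # no hazards: everyone survives recurrence-free for the whole window
  expect_equal(unname(ms1$outcomes["life_years"]), 200 * 10)
  expect_equal(unname(ms1$outcomes["rf_life_years"]), 200 * 10)
  expect_equal(unname(ms1$outcomes["deaths"]), 0)
  expect_true(all(ms1$se == 0))
})

test_that("microsim totals agree with the cohort engine within sampling error", {
  p <- toy_params(rates = list(rfd = 3e-4, rflr = 0.005, rfm = 0.001,
                               lrm = 0.012, lrd = 0.004, m12 = 0.02,
                               m1d = 0.01, m2d = 0.025),
                  hr_pd = 0.6, discount = 0.015)
  n <- 20000
  ms <- simulate_cohort(p, "melanoma", "anti_pdl1", n = n, seed = 7)
  tr <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = n)
  cm <- glance(trace_outcomes(tr, p))
  for (oc in outcome_names()) {
    if (ms$se[[oc]] == 0) next
    expect_lt(abs(ms$outcomes[[oc]] - cm[[oc]]), 3 * ms$se[[oc]],
              label = paste("microsim deviation for", oc))
  }
})
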