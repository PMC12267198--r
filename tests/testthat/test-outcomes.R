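test_that("life-year accumulation matches closed forms", {
  # 100 persons alive recurrence-free all 10 years, no discounting
  p <- toy_params()
  tr <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = 100)
  ly <- accumulate_life_years(tr, p)
  expect_equal(ly$rf_life_years, rep(100, 10))
  expect_equal(ly$life_years, rep(100, 10))

  # exponential decay: weekly sum vs the analytic integral of S
  lam <- 0.005
  p2 <- toy_params(rates = list(rfd = lam))
  tr2 <- run_cohort(p2, "melanoma", "anti_pdl1", entry_size = 1)
  total <- sum(accumulate_life_years(tr2, p2)$life_years)
  analytic <- (1 - exp(-lam * 520)) / lam / 52
  expect_lt(abs(total - analytic) / analytic, 0.005)

  # an empty cohort accrues nothing
  tr0 <- run_cohort(p2, "melanoma", "anti_pdl1", entry_size = 0)
  expect_equal(sum(accumulate_life_years(tr0, p2)$life_years), 0)
})

test_that("QALYs are proportional to life-years in a one-state model", {
  p1 <- toy_params()  # utilities 1, no AEs, no age adjustment
  tr <- run_cohort(p1, "melanoma", "anti_pdl1", entry_size = 50)
  expect_equal(accumulate_qalys(tr, p1)$qalys,
               accumulate_life_years(tr, p1)$life_years, tolerance = 1e-12)

  p0 <- toy_params(utilities = rep(0, 4))
  expect_equal(sum(accumulate_qalys(run_cohort(p0, "melanoma", "anti_pdl1",
                                               entry_size = 50),
                                    p0)$qalys), 0)

  p8 <- toy_params(utilities = rep(0.8, 4))
  tr8 <- run_cohort(p8, "melanoma", "anti_pdl1", entry_size = 50)
  expect_equal(accumulate_qalys(tr8, p8)$qalys,
               0.8 * accumulate_life_years(tr8, p8)$life_years,
               tolerance = 1e-9)
})

test_that("adverse-event burden is the direct product formula", {
  b <- ae_burden(100, 0.5, 4, -0.05)
  expect_equal(b$ae_count, 50)
  expect_equal(b$qaly_loss, 50 * 4 * 0.05 / 52)
  expect_equal(b$qaly_loss, 0.1923077, tolerance = 1e-6)
  expect_error(ae_burden(-1, 0.5, 4, -0.05))
  expect_error(ae_burden(100, 0.5, 4, 0.05))

  # in the engine: adjuvant AEs accrue at entry, and QALYs lose the burden
  p <- toy_params(ae_adjuvant_pdl1 = c(0.5, 4, -0.05))
  tr <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = 100)
  ev <- count_events(tr, p)
  expect_equal(ev$adverse_events, c(50, rep(0, 9)))
  expect_equal(sum(accumulate_qalys(tr, p)$qalys),
               sum(accumulate_life_years(tr, p)$life_years) - 0.1923077,
               tolerance = 1e-6)
})

test_that("event counts follow the ledger identities", {
  # death is the only recurrence-free exit: no recurrences at all
  p <- toy_params(rates = list(rfd = 0.002))
  tr <- run_cohort(p, "melanoma", "anti_pdl1", entry_size = 100)
  ev <- count_events(tr, p)
  expect_equal(sum(ev$recurrences), 0)
  expect_equal(sum(ev$deaths_after_event), 0)
  expect_gt(sum(ev$deaths), 0)

  # sole RF exit to locoregional recurrence: closed-form event total
  lam <- 0.004
  p2 <- toy_params(rates = list(rflr = lam))
  tr2 <- run_cohort(p2, "melanoma", "anti_pdl1", entry_size = 1000)
  ev2 <- count_events(tr2, p2)
  expect_lt(abs(sum(ev2$recurrences) - 1000 * (1 - exp(-lam * 520))) /
              (1000 * (1 - exp(-lam * 520))), 0.005)

  # everyone who recurs eventually starts 1L, and 2L counts add on top
  p3 <- toy_params(rates = list(rflr = 0.01, lrm = 0.05, m12 = 0.05))
  tr3 <- run_cohort(p3, "melanoma", "anti_pdl1", entry_size = 100)
  ev3 <- count_events(tr3, p3)
  expect_equal(sum(ev3$metastatic_treatments),
               sum(tr3$m1_initiations) + sum(tr3$m2_initiations),
               tolerance = 1e-12)
  expect_gte(sum(ev3$metastatic_treatments), sum(tr3$m1_initiations))

  # deaths equal entry size minus survivors at the horizon
  p4 <- toy_params(rates = list(rfd = 0.001, rflr = 0.004, lrd = 0.01))
  tr4 <- run_cohort(p4, "melanoma", "anti_pdl1", entry_size = 100)
  alive_end <- sum(tr4$occupancy[tr4$n_cycles,
                                 setdiff(health_states(), "dead")]) -
    sum(tr4$deaths[tr4$n_cycles])
  expect_equal(sum(count_events(tr4, p4)$deaths), 100 - alive_end,
               tolerance = 1e-6)
})

test_that("discounting shrinks valued outcomes and only them by default", {
  rates <- list(rfd = 0.001, rflr = 0.004, lrm = 0.01, lrd = 0.003,
                m12 = 0.015, m1d = 0.008, m2d = 0.02)
  p0 <- toy_params(rates = rates, discount = 0)
  p1 <- toy_params(rates = rates, discount = 0.015)
  g0 <- glance(trace_outcomes(run_cohort(p0, "melanoma", "anti_pdl1",
                                         entry_size = 100), p0))
  g1 <- glance(trace_outcomes(run_cohort(p1, "melanoma", "anti_pdl1",
                                         entry_size = 100), p1))
  for (oc in c("rf_life_years", "life_years", "qalys")) {
    expect_lt(g1[[oc]], g0[[oc]])
  }
  for (oc in pdl1impact:::count_outcomes()) {
    expect_equal(g1[[oc]], g0[[oc]], tolerance = 1e-12)
  }
  # with count discounting enabled, counts shrink too
  p2 <- toy_params(rates = rates, discount = 0.015,
                   settings = list(discount_event_counts = TRUE))
  g2 <- glance(trace_outcomes(run_cohort(p2, "melanoma", "anti_pdl1",
                                         entry_size = 100), p2))
  expect_lt(g2$deaths, g1$deaths)
})

test_that("outcome sets satisfy the ordering invariants", {
  p <- synth_params(seed = 5)
  os <- run_scenario(p, scenario_definition("scenario_II"))
  g <- glance(os)
  expect_lte(g$rf_life_years, g$life_years)
  expect_lte(g$qalys, g$life_years)
  expect_lte(g$deaths_after_event, g$deaths)
  expect_true(all(as.matrix(os$per_year[-1]) >= 0))
})

test_that("scenario comparison reproduces the reporting arithmetic", {
  oi <- as_outcome_set(tibble::tibble(year = 2022, a = 34755, b = 4555))
  oii <- as_outcome_set(tibble::tibble(year = 2022, a = 38171, b = 2978))
  cmp <- compare_scenarios(oi, oii)
  expect_equal(cmp$cumulative$difference, c(3416, -1577))
  expect_equal(cmp$cumulative$pct_change, c(10, -35))

  # identical scenarios: zero difference, zero percent
  cmp0 <- compare_scenarios(oi, oi)
  expect_equal(cmp0$cumulative$difference, c(0, 0))
  expect_equal(cmp0$cumulative$pct_change, c(0, 0))

  # zero denominator: percent change is reported as absent
  oz <- as_outcome_set(tibble::tibble(year = 2022, a = 0))
  oz2 <- as_outcome_set(tibble::tibble(year = 2022, a = 5))
  expect_true(is.na(compare_scenarios(oz, oz2)$cumulative$pct_change))

  # mismatched years refuse to compare
  oy <- as_outcome_set(tibble::tibble(year = 2023, a = 1, b = 1))
  expect_error(compare_scenarios(oi, oy), "different years")
})

test_that("percent changes use half-away-from-zero rounding", {
  expect_equal(round_half_out(c(2.5, -2.5, 0.5, -0.5)), c(3, -3, 1, -1))
  expect_equal(round_half_out(c(9.83, 3.01, -26.13)), c(10, 3, -26))
  oi <- as_outcome_set(tibble::tibble(year = 2022, x = 200))
  oii <- as_outcome_set(tibble::tibble(year = 2022, x = 205))  # +2.5%
  expect_equal(compare_scenarios(oi, oii)$cumulative$pct_change, 3)
})
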