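test_that("the null toggle reproduces the base case bit-for-bit", {
  p <- synth_params(seed = 6)
  sa <- run_scenario_analysis(p, "none")
  expect_identical(sa$base_impact, sa$varied_impact)
  expect_true(all(sa$pct_change == 0))
})

test_that("population scaling changes every impact by exactly 20%", {
  p <- synth_params(seed = 6)
  up <- run_scenario_analysis(p, "pop_up_20")
  expect_equal(up$varied_impact, 1.2 * up$base_impact, tolerance = 1e-12)
  expect_true(all(up$pct_change == 20))
  dn <- run_scenario_analysis(p, "pop_down_20")
  expect_equal(dn$varied_impact, 0.8 * dn$base_impact, tolerance = 1e-12)
  expect_true(all(dn$pct_change == -20))
})

test_that("full uptake amplifies the life-year and QALY benefit", {
  p <- synth_params(seed = 6)
  sa <- run_scenario_analysis(p, "uptake_100")
  row <- function(oc) sa[sa$outcome == oc, ]
  expect_gte(abs(row("life_years")$varied_impact),
             abs(row("life_years")$base_impact))
  expect_gte(abs(row("qalys")$varied_impact),
             abs(row("qalys")$base_impact))
  # positive percent change = larger benefit under the sign convention
  expect_gt(row("life_years")$pct_change, 0)
})

test_that("disallowing retreatment changes only retreatment-linked flows", {
  p <- synth_params(seed = 6)
  sa <- run_scenario_analysis(p, "no_retreatment")
  expect_false(identical(sa$base_impact, sa$varied_impact))
  # recurrence counts are driven by the adjuvant arm alone, so the
  # recurrence impact is untouched by the metastatic mix change
  expect_equal(sa$varied_impact[sa$outcome == "recurrences"],
               sa$base_impact[sa$outcome == "recurrences"],
               tolerance = 1e-9)
})

test_that("subgroup impacts are additive across tumors", {
  p <- synth_params(seed = 6)
  sg <- run_subgroups(p)
  expect_setequal(unique(sg$subset),
                  c("melanoma", "rcc", "tnbc", "melanoma+rcc",
                    "melanoma+tnbc", "rcc+tnbc", "melanoma+rcc+tnbc"))
  imp <- function(s) {
    v <- sg[sg$subset == s, ]
    setNames(v$impact, v$outcome)
  }
  expect_equal(imp("melanoma+rcc"), imp("melanoma") + imp("rcc"),
               tolerance = 1e-6)
  expect_equal(imp("rcc+tnbc"), imp("rcc") + imp("tnbc"), tolerance = 1e-6)
  expect_equal(imp("melanoma+rcc+tnbc"),
               imp("melanoma") + imp("rcc") + imp("tnbc"),
               tolerance = 1e-6)
  # the all-tumor subset is the base case
  base <- impact_vector(run_comparison(p))
  expect_equal(imp("melanoma+rcc+tnbc")[names(base)], base,
               tolerance = 1e-9)
})

test_that("one-way analysis ranks variables by influence", {
  p <- synth_params(seed = 6)
  tor <- one_way_sa(p, variables = c("mean_weight", "population_size",
                                     "utility_recurrence_free"))
  # weight is inert by design: zero impact range everywhere
  expect_true(all(tor$range[tor$variable == "mean_weight"] == 0))
  # population size scales the life-year impact by exactly +/-10%
  row <- tor[tor$variable == "population_size" &
               tor$outcome == "life_years", ]
  expect_equal(row$low, 0.9 * row$base, tolerance = 1e-9)
  expect_equal(row$high, 1.1 * row$base, tolerance = 1e-9)
  # tornado ordering: most influential variable first
  first_var <- tor$variable[1]
  expect_identical(first_var, "population_size")
  # utilities move QALYs but not life-years
  urow <- tor[tor$variable == "utility_recurrence_free", ]
  expect_equal(urow$range[urow$outcome == "life_years"], 0,
               tolerance = 1e-9)
  expect_gt(urow$range[urow$outcome == "qalys"], 0)
})

test_that("hazard-ratio variables move to their CI bounds", {
  p <- toy_params(rates = list(rflr = 0.005, lrm = 0.02, m12 = 0.02,
                               m1d = 0.01, m2d = 0.02), hr_pd = 0.7)
  # give the 1L OS law an HR with CI so the registered variable finds it
  tr <- p$transitions
  sel <- tr$transition == "m1l_to_death" & tr$treatment == "pdl1_1l"
  tr$hazard_ratio[sel] <- 0.7
  tr$hr_lower[sel] <- 0.5
  tr$hr_upper[sel] <- 0.95
  p$transitions <- tr
  lo <- pdl1impact:::perturb_params(p, "hr_os_melanoma", "low")
  hi <- pdl1impact:::perturb_params(p, "hr_os_melanoma", "high")
  expect_equal(unique(lo$transitions$hazard_ratio[sel]), 0.5)
  expect_equal(unique(hi$transitions$hazard_ratio[sel]), 0.95)
  # a lower OS hazard ratio can flip the sign of a downstream impact;
  # both directions are recorded in the tornado rows
  tor <- one_way_sa(p, variables = "hr_os_melanoma")
  row <- tor[tor$outcome == "deaths", ]
  expect_false(row$low == row$high)

  # without a stored CI the fallback is +/-10% with a warning
  p2 <- toy_params(rates = list(m1d = 0.01))
  expect_warning(
    pdl1impact:::perturb_params(p2, "hr_os_melanoma", "high"),
    "\\+/-10%")
})
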