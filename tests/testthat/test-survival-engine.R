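# Parameter sets spanning all six families, used by the property checks.
family_cases <- list(
  list(family = "exponential", params = 0.01),
  list(family = "weibull", params = c(1.3, 120)),
  list(family = "lognormal", params = c(4.2, 0.8)),
  list(family = "loglogistic", params = c(1.5, 100)),
  list(family = "gompertz", params = c(0.02, 0.003)),
  list(family = "generalized_gamma", params = c(4.5, 0.7, 1.3)))

test_that("survival_spec rejects invalid families, parameters and CIs", {
  expect_error(survival_spec("weibull", c(-1, 10)), "valid domain")
  expect_error(survival_spec("weibull", 1), "needs 2 parameter")
  expect_error(survival_spec("gamma", c(1, 1)))
  expect_error(survival_spec("exponential", 0.01, hazard_ratio = -1),
               "non-negative")
  expect_error(survival_spec("exponential", 0.01, hazard_ratio = 0.7,
                             hr_lower = 0.8, hr_upper = 0.9),
               "lower <= hr <= upper")
  # zero-hazard exponential and the hr = 0 limit are permitted
  expect_s3_class(survival_spec("exponential", 0), "survival_spec")
  expect_s3_class(survival_spec("exponential", 0.01, hazard_ratio = 0),
                  "survival_spec")
})

test_that("surv_prob matches the proportional-hazards closed form", {
  sp <- survival_spec("exponential", 0.01, hazard_ratio = 2)
  expect_equal(surv_prob(sp, 0), 1)
  expect_equal(surv_prob(sp, 100), exp(-2 * 0.01 * 100), tolerance = 1e-12)
  # numerical integration of the scaled hazard gives the same curve
  sp_w <- survival_spec("weibull", c(1.4, 90), hazard_ratio = 0.7)
  h <- function(t) {
    0.7 * (stats::dweibull(t, 1.4, 90) /
             stats::pweibull(t, 1.4, 90, lower.tail = FALSE))
  }
  for (t in c(10, 50, 150)) {
    expect_equal(surv_prob(sp_w, t),
                 exp(-stats::integrate(h, 0, t, rel.tol = 1e-10)$value),
                 tolerance = 1e-7)
  }
})

test_that("weibull with shape 1 degenerates to the exponential", {
  lam <- 0.013
  sp_w <- survival_spec("weibull", c(1, 1 / lam))
  sp_e <- survival_spec("exponential", lam)
  t <- seq(0, 400, by = 7)
  expect_equal(surv_prob(sp_w, t), surv_prob(sp_e, t), tolerance = 1e-12)
})

test_that("survival curves start at 1, stay in [0,1] and are non-increasing", {
  grid <- seq(0, 600, by = 1)
  for (cs in family_cases) {
    for (hr in c(0.5, 1, 1.8)) {
      sp <- survival_spec(cs$family, cs$params, hazard_ratio = hr)
      s <- surv_prob(sp, grid)
      expect_equal(s[1], 1, info = cs$family)
      expect_true(all(s >= 0 & s <= 1), info = cs$family)
      expect_true(all(diff(s) <= 1e-15), info = cs$family)
    }
    # hazard_ratio = 1 is the identity on S
    sp1 <- survival_spec(cs$family, cs$params, hazard_ratio = 1)
    sp0 <- survival_spec(cs$family, cs$params)
    expect_identical(surv_prob(sp1, grid), surv_prob(sp0, grid))
  }
})

test_that("cycle_prob is the exact conditional one-week probability", {
  sp <- survival_spec("exponential", 0.01)
  expect_equal(cycle_prob(sp, c(0, 17, 300)), rep(1 - exp(-0.01), 3),
               tolerance = 1e-12)  # memoryless: constant across cycles
  sp0 <- survival_spec("weibull", c(2, 100), hazard_ratio = 0)
  expect_equal(cycle_prob(sp0, 0:50), rep(0, 51))
  # increasing hazard gives strictly increasing cycle probabilities
  sp2 <- survival_spec("weibull", c(2, 100))
  p <- cycle_prob(sp2, 0:200)
  expect_true(all(diff(p) > 0))
})

test_that("chained cycle probabilities telescope back to S(k)", {
  k <- 300
  for (cs in family_cases) {
    sp <- survival_spec(cs$family, cs$params, hazard_ratio = 0.8)
    q <- cycle_prob(sp, 0:(k - 1))
    expect_equal(cumprod(1 - q), surv_prob(sp, 1:k),
                 tolerance = 1e-10, info = cs$family)
  }
})

test_that("weekly background mortality inverts annual compounding", {
  lt <- synth_life_table()
  lt$qx[lt$age == 50] <- 0.05
  expect_equal(weekly_mortality(lt[lt$age == 50 | lt$age == 100, ], 50.7,
                                "female"),
               1 - 0.95^(1 / 52), tolerance = 1e-12)
  w <- weekly_mortality(lt, 50.2, "female")
  expect_equal(1 - (1 - w)^52, 0.05, tolerance = 1e-12)
  lt$qx[lt$age == 30] <- 0
  expect_equal(weekly_mortality(lt, 30, "male"), 0)
  expect_equal(weekly_mortality(lt, 100, "male"), 1)   # closing row
  expect_equal(weekly_mortality(lt, 130, "male"), 1)   # beyond the table
})

test_that("effective death probability is the max rule", {
  expect_equal(effective_death_prob(0.001, 0.002), 0.002)
  expect_equal(effective_death_prob(0.002, 0.001), 0.002)
  expect_equal(effective_death_prob(0.3, 0.3), 0.3)
  p <- runif(50); q <- runif(50)
  m <- effective_death_prob(p, q)
  expect_identical(m, effective_death_prob(q, p))      # symmetric
  expect_identical(effective_death_prob(m, m), m)      # idempotent
  expect_true(all(m >= p & m >= q))
})

test_that("competing exits are rescaled only in the pathological case", {
  expect_identical(normalize_exit_probs(c(0.01, 0.02)), c(0.01, 0.02))
  expect_warning(out <- normalize_exit_probs(c(0.8, 0.6)), "rescaled")
  expect_equal(out, c(0.8, 0.6) / 1.4)
  expect_identical(normalize_exit_probs(numeric(0)), numeric(0))
})

test_that("discount factors follow weekly-resolution annual compounding", {
  expect_equal(discount_factor(c(0, 52, 520), 0), rep(1, 3))
  expect_equal(discount_factor(52, 0.015), 1 / 1.015, tolerance = 1e-12)
  expect_equal(discount_factor(0, 0.015), 1)
  expect_error(discount_factor(10, -0.01), ">= 0")
})
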