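#' Parametric time-to-event specification for one transition
#'
#' A `survival_spec` describes the time-to-event law governing a single
#' health-state transition for one treatment arm, as a standard parametric
#' family plus an optional proportional-hazards multiplier.  Time is measured
#' in weeks, the model's cycle length.
#'
#' Supported families and their canonical parameter order:
#' \describe{
#'   \item{`exponential`}{`rate` (per week; 0 gives a zero-hazard spec)}
#'   \item{`weibull`}{`shape`, `scale` (as [stats::pweibull()])}
#'   \item{`lognormal`}{`meanlog`, `sdlog`}
#'   \item{`loglogistic`}{`shape`, `scale` (as [flexsurv::pllogis()])}
#'   \item{`gompertz`}{`shape`, `rate` (as [flexsurv::pgompertz()])}
#'   \item{`generalized_gamma`}{`mu`, `sigma`, `Q`
#'     (the stable parameterization of [flexsurv::pgengamma()])}
#' }
#'
#' The hazard ratio acts on the whole hazard curve, so the survival function
#' becomes `S(t)^hazard_ratio`.  A 95% confidence interval may be attached
#' for use by the one-way sensitivity analysis.
#'
#' @param family One of the six family names above.
#' @param params Numeric vector of parameters in canonical order.
#' @param hazard_ratio Non-negative multiplier on the hazard (default 1).
#'   The value 0 is permitted as the no-hazard limit.
#' @param hr_lower,hr_upper Optional 95% CI bounds with
#'   `hr_lower <= hazard_ratio <= hr_upper`.
#' @return An object of class `survival_spec`.
#' @export
#' @examples
#' sp <- survival_spec("exponential", 0.01, hazard_ratio = 2)
#' surv_prob(sp, 100)  # exp(-2)
survival_spec <- function(family, params, hazard_ratio = 1,
                          hr_lower = NA_real_, hr_upper = NA_real_) {
  family <- match.arg(family, surv_families())
  params <- as.numeric(params)
  npar <- surv_family_npar()[[family]]
  if (length(params) != npar) {
    stop("survival_spec: family '", family, "' needs ", npar,
         " parameter(s), got ", length(params), call. = FALSE)
  }
  check <- switch(family,
    exponential = params[1] >= 0,
    weibull = params[1] > 0 && params[2] > 0,
    lognormal = params[2] > 0,
    loglogistic = params[1] > 0 && params[2] > 0,
    gompertz = params[2] > 0,            # shape may be any real
    generalized_gamma = params[2] > 0)
  if (!isTRUE(check)) {
    stop("survival_spec: parameters ", paste(params, collapse = ", "),
         " outside the valid domain of family '", family, "'", call. = FALSE)
  }
  if (!is.finite(hazard_ratio) || hazard_ratio < 0) {
    stop("survival_spec: hazard_ratio must be a non-negative number",
         call. = FALSE)
  }
  if (!is.na(hr_lower) || !is.na(hr_upper)) {
    if (is.na(hr_lower) || is.na(hr_upper) ||
        hr_lower > hazard_ratio || hr_upper < hazard_ratio) {
      stop("survival_spec: hazard-ratio CI must satisfy lower <= hr <= upper",
           call. = FALSE)
    }
  }
  structure(
    list(family = family, params = params, hazard_ratio = hazard_ratio,
         hr_lower = hr_lower, hr_upper = hr_upper),
    class = "survival_spec")
}

surv_families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz",
    "generalized_gamma")
}

surv_family_npar <- function() {
  c(exponential = 1L, weibull = 2L, lognormal = 2L, loglogistic = 2L,
    gompertz = 2L, generalized_gamma = 3L)
}

#' @export
print.survival_spec <- function(x, ...) {
  cat("<survival_spec> ", x$family, "(",
      paste(signif(x$params, 6), collapse = ", "), ")", sep = "")
  if (x$hazard_ratio != 1 || !is.na(x$hr_lower)) {
    cat(", HR =", signif(x$hazard_ratio, 4))
    if (!is.na(x$hr_lower)) {
      cat(" [", signif(x$hr_lower, 4), ", ", signif(x$hr_upper, 4), "]",
          sep = "")
    }
  }
  cat("\n")
  invisible(x)
}

base_surv <- function(family, p, t) {
  switch(family,
    exponential = exp(-p[1] * t),
    weibull = stats::pweibull(t, shape = p[1], scale = p[2],
                              lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = p[1], sdlog = p[2],
                              lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[1], scale = p[2],
                                    lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = p[1], rate = p[2],
                                   lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = p[1], sigma = p[2],
                                            Q = p[3], lower.tail = FALSE),
    stop("unknown survival family: ", family, call. = FALSE))
}

#' Survival probability under a parametric spec
#'
#' Evaluates `S(t)` for a [survival_spec()], with the hazard ratio applied
#' proportionally on the hazard, i.e. the baseline survival raised to the
#' power of the hazard ratio.  `S(0) = 1` and `S` is non-increasing.
#'
#' @param spec A [survival_spec()].
#' @param t Time in weeks (vectorized, `t >= 0`).
#' @return Numeric vector of survival probabilities in `[0, 1]`.
#' @export
surv_prob <- function(spec, t) {
  stopifnot(inherits(spec, "survival_spec"), all(t >= 0))
  s <- base_surv(spec$family, spec$params, t)
  if (spec$hazard_ratio != 1) s <- s^spec$hazard_ratio
  pmin(pmax(s, 0), 1)
}

#' Per-cycle transition probability from a survival law
#'
#' Converts a parametric survival law into the probability of transitioning
#' during one weekly cycle, conditional on occupying the source state at the
#' start of the cycle: `1 - S(cycle + 1) / S(cycle)`.  This conditional form
#' is exact for any family, so chaining cycles telescopes back to the
#' survival function.  When the law is fully depleted (`S(cycle) = 0`) the
#' probability is 1 by convention.
#'
#' @param spec A [survival_spec()].
#' @param cycle Non-negative integer cycle index (vectorized), measured on
#'   the clock of the transition (time since state entry, in weeks).
#' @return Probabilities in `[0, 1]`.
#' @export
#' @examples
#' cycle_prob(survival_spec("exponential", 0.01), 0:3)  # constant, memoryless
cycle_prob <- function(spec, cycle) {
  stopifnot(all(cycle >= 0))
  s0 <- surv_prob(spec, cycle)
  s1 <- surv_prob(spec, cycle + 1)
  p <- ifelse(s0 <= 0, 1, 1 - s1 / s0)
  pmin(pmax(p, 0), 1)
}

# Per-cycle transition probabilities for cycles 0..(n_cycles-1), as a vector.
cycle_prob_vector <- function(spec, n_cycles) {
  s <- surv_prob(spec, 0:n_cycles)
  p <- ifelse(s[-(n_cycles + 1)] <= 0, 1,
              1 - s[-1] / s[-(n_cycles + 1)])
  pmin(pmax(p, 0), 1)
}

#' Weekly background mortality from an annual life table
#'
#' Converts the annual death probability `q(age, sex)` of a life table into
#' the per-week probability `1 - (1 - q)^(1/52)`.  Ages beyond the table are
#' mapped to its closing row.
#'
#' @param life_table Tibble with columns `age`, `sex` (`"female"`/`"male"`)
#'   and `qx` (annual death probability).
#' @param age Age in years (vectorized); the integer part is looked up.
#' @param sex `"female"` or `"male"`.
#' @return Weekly death probabilities in `[0, 1]`.
#' @export
weekly_mortality <- function(life_table, age, sex) {
  sex <- match.arg(sex, c("female", "male"))
  lt <- life_table[life_table$sex == sex, ]
  lt <- lt[order(lt$age), ]
  idx <- pmin(findInterval(floor(age), lt$age), nrow(lt))
  idx[idx < 1L] <- 1L
  1 - (1 - lt$qx[idx])^(1 / 52)
}

# Pooled-cohort weekly mortality: the annual q is mixed across sexes with the
# cohort's fraction female before the weekly conversion (the model tracks a
# single pooled cohort per tumor, not sex strata).
weekly_mortality_pooled <- function(life_table, age, fraction_female) {
  lt_f <- life_table[life_table$sex == "female", ]
  lt_f <- lt_f[order(lt_f$age), ]
  lt_m <- life_table[life_table$sex == "male", ]
  lt_m <- lt_m[order(lt_m$age), ]
  idx <- pmin(findInterval(floor(age), lt_f$age), nrow(lt_f))
  idx[idx < 1L] <- 1L
  q <- fraction_female * lt_f$qx[idx] + (1 - fraction_female) * lt_m$qx[idx]
  1 - (1 - q)^(1 / 52)
}

#' Effective per-cycle death probability
#'
#' The model never lets disease-specific mortality fall below general
#' population mortality: the effective death probability is the maximum of
#' the trial-based estimate and the background estimate.
#'
#' @param trial_p,background_p Per-cycle probabilities in `[0, 1]`
#'   (vectorized, recycled).
#' @return `pmax(trial_p, background_p)`.
#' @export
effective_death_prob <- function(trial_p, background_p) {
  stopifnot(all(trial_p >= 0 & trial_p <= 1),
            all(background_p >= 0 & background_p <= 1))
  pmax(trial_p, background_p)
}

#' Normalize competing per-cycle exit probabilities
#'
#' The transition laws are marginal, one per exit, so in pathological
#' parameter regions the within-cycle exit probabilities of a state can sum
#' above 1.  This helper rescales them proportionally to sum to 1 in that
#' case (with a warning) and returns them unchanged otherwise.
#'
#' @param exit_probs Numeric vector of per-cycle exit probabilities.
#' @return Adjusted vector of the same length.
#' @export
normalize_exit_probs <- function(exit_probs) {
  if (length(exit_probs) == 0) return(exit_probs)
  stopifnot(all(exit_probs >= 0 & exit_probs <= 1))
  s <- sum(exit_probs)
  if (s > 1) {
    warning("competing exit probabilities sum to ", signif(s, 6),
            " > 1; rescaled proportionally", call. = FALSE)
    exit_probs <- exit_probs / s
  }
  exit_probs
}

#' Discount factor for a model cycle
#'
#' Weekly-resolution discounting at an annual rate:
#' `(1 + annual_rate)^(-cycle / 52)`.  Cycles are counted from the start of
#' the projection window, so discounting runs on calendar time.
#'
#' @param cycle Non-negative cycle index (vectorized).
#' @param annual_rate Annual discount rate (default 0.015).
#' @return Discount factors in `(0, 1]`.
#' @export
discount_factor <- function(cycle, annual_rate = 0.015) {
  if (annual_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  stopifnot(all(cycle >= 0))
  (1 + annual_rate)^(-cycle / 52)
}
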