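#' Individual-level microsimulation of one entry cohort
#'
#' Monte-Carlo cross-check of the deterministic cohort engine: `n`
#' individual trajectories are sampled cycle by cycle from the same
#' per-cycle transition probabilities (including the background-mortality
#' floor, the retreatment-eligibility mix assignment and the
#' deaths-before-progressions resolution order), and the same eight
#' outcomes are accumulated with Monte-Carlo standard errors.  In
#' expectation the totals equal the cohort-engine values; agreement within
#' sampling error validates the deterministic propagation independently of
#' its tunnel bookkeeping.
#'
#' Adverse-event counts and QALY losses are applied as their expected
#' values at each sampled treatment initiation, so their standard errors
#' reflect initiation randomness only.
#'
#' @param params A `pdl1_params` bundle.
#' @param tumor,arm Cohort to simulate (as in [run_cohort()]).
#' @param n Number of simulated individuals.
#' @param seed Integer seed; the same seed reproduces the run exactly.
#' @param entry_week Model week of entry (0-based).
#' @param retreatment_allowed Passed through as in [run_cohort()].
#' @return Object of class `microsim_result`: list with `outcomes` (named
#'   cumulative totals over the window), `se` (their Monte-Carlo standard
#'   errors), `n`, and `extras` (undiscounted recurrence-free exit count
#'   and person-weeks, used for rate-recovery checks).
#' @export
#' @examples
#' \donttest{
#' params <- synth_params(seed = 2024)
#' ms <- simulate_cohort(params, "melanoma", "anti_pdl1", n = 2000, seed = 7)
#' ms$outcomes["deaths"] + c(-3, 3) * ms$se["deaths"]
#' }
simulate_cohort <- function(params, tumor, arm, n = 10000L, seed = 1L,
                            entry_week = 0L, retreatment_allowed = TRUE) {
  st <- params$settings
  W <- st$horizon_years * 52L
  entry_week <- as.integer(entry_week)
  n <- as.integer(n)
  stopifnot(n >= 1L, entry_week >= 0L, entry_week < W)
  K <- W - entry_week

  demo <- params$demographics[params$demographics$tumor == tumor, ]
  ages <- demo$mean_age + (seq_len(K) - 1L) / 52
  bg <- weekly_mortality_pooled(params$life_table, ages,
                                demo$fraction_female)
  qv <- function(transition, treatment = NA_character_) {
    cycle_prob_vector(
      get_transition_spec(params, tumor, arm, transition, treatment), K)
  }
  q_rflr <- qv("rf_to_lr"); q_rfm <- qv("rf_to_met")
  q_rfd <- qv("rf_to_death")
  q_lrm <- qv("lr_to_met"); q_lrd <- qv("lr_to_death")
  tr1 <- m1l_treatments(params, tumor)
  tr2 <- m2l_treatments(params, tumor)
  q_m12 <- lapply(tr1, function(t) qv("m1l_to_m2l", t))
  q_m1d <- lapply(tr1, function(t) qv("m1l_to_death", t))
  q_m2d <- qv("m2l_to_death")
  mix1 <- mix_by_stratum(params, tumor, arm, "m1l", tr1, retreatment_allowed)
  mix2 <- mix_by_stratum(params, tumor, arm, "m2l", tr2, retreatment_allowed)
  thr <- st$retreatment_threshold_weeks

  u_state <- c(utility_vector(params, tumor), 0)
  adj <- adjustment_vector(params, ages, demo$fraction_female)
  ae1 <- ae_vectors(params, tumor, "m1l", tr1)
  ae2 <- ae_vectors(params, tumor, "m2l", tr2)
  ae_adj <- ae_profile_row(params, tumor, "adjuvant", arm)

  calendar <- entry_week + seq_len(K) - 1L
  dc <- if (st$discount_from == "model_start")
    discount_factor(calendar, st$annual_discount_rate)
  else discount_factor(seq_len(K) - 1L, st$annual_discount_rate)
  dcnt <- if (st$discount_event_counts) dc else rep(1, K)

  withr::with_seed(seed, {
    state <- rep(1L, n)         # 1 RF, 2 LR, 3 M1, 4 M2, 5 dead
    entry <- integer(n)         # entry cycle of the current state
    treat <- integer(n)         # 1L treatment index while in M1
    ly_rf <- ly <- qaly <- recs <- trts <- aes <- numeric(n)
    death_after <- rep(NA, n)   # NA alive; FALSE death from RF; TRUE after
    rf_exits <- 0; rf_pw <- 0

    burden0 <- ae_burden(1, ae_adj$events_per_patient,
                         ae_adj$weeks_per_event, ae_adj$disutility)
    aes <- aes + burden0$ae_count * dcnt[1L]
    qaly <- qaly - burden0$qaly_loss * dc[1L]

    pick_mix <- function(m, nn) {
      # sample treatment indices from mix fractions m
      findInterval(runif(nn), cumsum(m), left.open = TRUE) + 1L
    }

    for (i in seq_len(K)) {
      k <- i - 1L
      b <- bg[i]
      alive <- state != 5L
      ly[alive] <- ly[alive] + dc[i] / 52
      rf <- state == 1L
      ly_rf[rf] <- ly_rf[rf] + dc[i] / 52
      qaly[alive] <- qaly[alive] +
        u_state[state[alive]] * adj[i] * dc[i] / 52
      rf_pw <- rf_pw + sum(rf)
      s_new <- if (k < thr) 1L else 2L

      new_m1 <- integer(0)
      # recurrence-free exits (deaths first, then progressions)
      idx <- which(rf)
      if (length(idx) > 0) {
        p_d <- min(max(q_rfd[i], b), 1)
        pp <- c(q_rflr[i], q_rfm[i]); sp <- sum(pp)
        if (sp > 1) pp <- pp / sp
        r <- runif(length(idx))
        e_d <- p_d
        e_lr <- p_d + (1 - p_d) * pp[1]
        e_m <- e_lr + (1 - p_d) * pp[2]
        died <- r < e_d
        tolr <- !died & r < e_lr
        tom <- !died & !tolr & r < e_m
        rf_exits <- rf_exits + sum(died | tolr | tom)
        state[idx[died]] <- 5L
        death_after[idx[died]] <- FALSE
        recs[idx[tolr | tom]] <- recs[idx[tolr | tom]] + dcnt[i]
        state[idx[tolr]] <- 2L; entry[idx[tolr]] <- i
        new_m1 <- idx[tom]
      }
      # locoregional recurrence
      idx <- which(state == 2L & entry <= k)
      if (length(idx) > 0) {
        uu <- k - entry[idx] + 1L
        p_d <- pmax(q_lrd[uu], b); p_m <- q_lrm[uu]
        r <- runif(length(idx))
        died <- r < p_d
        tom <- !died & r < p_d + (1 - p_d) * p_m
        state[idx[died]] <- 5L
        death_after[idx[died]] <- TRUE
        new_m1 <- c(new_m1, idx[tom])
      }
      # first-line metastatic, per treatment option
      new_m2 <- integer(0)
      for (t in seq_along(tr1)) {
        idx <- which(state == 3L & treat == t & entry <= k)
        if (length(idx) == 0) next
        uu <- k - entry[idx] + 1L
        p_d <- pmax(q_m1d[[t]][uu], b); p_g <- q_m12[[t]][uu]
        r <- runif(length(idx))
        died <- r < p_d
        prog <- !died & r < p_d + (1 - p_d) * p_g
        state[idx[died]] <- 5L
        death_after[idx[died]] <- TRUE
        new_m2 <- c(new_m2, idx[prog])
      }
      # second-line metastatic
      idx <- which(state == 4L & entry <= k)
      if (length(idx) > 0) {
        uu <- k - entry[idx] + 1L
        p_d <- pmax(q_m2d[uu], b)
        died <- runif(length(idx)) < p_d
        state[idx[died]] <- 5L
        death_after[idx[died]] <- TRUE
      }
      # metastatic treatment initiations during this cycle
      if (length(new_m1) > 0) {
        t_new <- pick_mix(mix1[[s_new]], length(new_m1))
        state[new_m1] <- 3L; entry[new_m1] <- i; treat[new_m1] <- t_new
        trts[new_m1] <- trts[new_m1] + dcnt[i]
        aes[new_m1] <- aes[new_m1] + ae1$events[t_new] * dcnt[i]
        qaly[new_m1] <- qaly[new_m1] - ae1$qaly_loss[t_new] * dc[i]
      }
      if (length(new_m2) > 0) {
        t2_new <- pick_mix(mix2[[s_new]], length(new_m2))
        state[new_m2] <- 4L; entry[new_m2] <- i
        trts[new_m2] <- trts[new_m2] + dcnt[i]
        aes[new_m2] <- aes[new_m2] + ae2$events[t2_new] * dcnt[i]
        qaly[new_m2] <- qaly[new_m2] - ae2$qaly_loss[t2_new] * dc[i]
      }
    }

    dead <- (state == 5L) * 1
    dead_after <- as.numeric(!is.na(death_after) & death_after)
    per_ind <- cbind(rf_life_years = ly_rf, life_years = ly, qalys = qaly,
                     recurrences = recs, metastatic_treatments = trts,
                     adverse_events = aes, deaths = dead,
                     deaths_after_event = dead_after)
    outcomes <- colSums(per_ind)
    se <- apply(per_ind, 2, stats::sd) * sqrt(n)
    structure(list(outcomes = outcomes, se = se, n = n,
                   seed = as.integer(seed), tumor = tumor, arm = arm,
                   extras = list(rf_exits = rf_exits, rf_person_weeks = rf_pw)),
              class = "microsim_result")
  })
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result> ", x$tumor, " / ", x$arm, ", n = ",
      format(x$n, big.mark = ","), ", seed ", x$seed, "\n", sep = "")
  print(tibble::tibble(outcome = names(x$outcomes),
                       total = unname(x$outcomes), se = unname(x$se)),
        n = Inf)
  invisible(x)
}
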