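#' Retreatment-eligibility stratum for a recurrence cycle
#'
#' Anti-PD-(L)1 rechallenge at recurrence is assumed possible only from 18
#' months (78 weeks by default) after adjuvant/neoadjuvant treatment
#' initiation.  A metastatic treatment initiation during a cycle strictly
#' before the threshold falls in the `before_threshold` stratum, whose 1L
#' mix excludes anti-PD-(L)1 retreatment; otherwise `at_or_after_threshold`.
#'
#' @param cycle_of_recurrence Cycle index (weeks since adjuvant initiation,
#'   0-based; vectorized) at which the metastatic treatment is initiated.
#' @param threshold_weeks Retreatment threshold in weeks (default 78).
#' @return Character vector of stratum labels.
#' @export
#' @examples
#' retreatment_stratum(c(77, 78))
retreatment_stratum <- function(cycle_of_recurrence, threshold_weeks = 78L) {
  stopifnot(all(cycle_of_recurrence >= 0), threshold_weeks > 0)
  ifelse(cycle_of_recurrence < threshold_weeks,
         "before_threshold", "at_or_after_threshold")
}

#' Propagate one entry cohort through the five-state model
#'
#' The deterministic engine of the projection: a cohort entering the
#' recurrence-free state in a given model week is propagated over weekly
#' cycles until the end of the reporting window, tracking state occupancy,
#' recurrence events, metastatic treatment initiations (split by 1L/2L
#' treatment option) and deaths.
#'
#' Within a cycle, deaths are resolved first — the per-cycle death
#' probability of every state is the maximum of the trial-based estimate
#' and background mortality — and the survivors then face the progression
#' exits (rescaled proportionally in the pathological case where they sum
#' above 1).  Recurrence-free exits run on the clock since adjuvant
#' initiation; exits from the locoregional and metastatic states run on
#' time since state entry, implemented with entry-cycle tunnels.  Entrants
#' to a metastatic line are assigned a treatment mix conditional on the
#' adjuvant arm and on the retreatment-eligibility stratum of the
#' initiation cycle (see [retreatment_stratum()]).
#'
#' @param params A `pdl1_params` bundle.
#' @param tumor One of [tumor_types()].
#' @param arm Adjuvant arm label (`"anti_pdl1"` or a traditional arm of the
#'   bundle).
#' @param entry_size Cohort size in persons (any non-negative real; the
#'   engine is linear in `entry_size`).
#' @param entry_week Model week of entry, 0-based from the start of the
#'   projection window.
#' @param retreatment_allowed If `FALSE`, all strata use the no-retreatment
#'   1L/2L mixes.
#' @return An object of class `cohort_trace`; see [tidy.cohort_trace()] for
#'   the tidy occupancy export and [accumulate_life_years()],
#'   [accumulate_qalys()], [count_events()] for outcome aggregation.
#' @export
#' @examples
#' params <- synth_params(seed = 2024)
#' tr <- run_cohort(params, "melanoma", "anti_pdl1", entry_size = 100)
#' tr
run_cohort <- function(params, tumor, arm, entry_size = 1,
                       entry_week = 0L, retreatment_allowed = TRUE) {
  st <- params$settings
  W <- st$horizon_years * 52L
  entry_week <- as.integer(entry_week)
  stopifnot(entry_size >= 0, entry_week >= 0, entry_week < W)
  K <- W - entry_week

  demo <- params$demographics[params$demographics$tumor == tumor, ]
  if (nrow(demo) != 1L) stop("unknown tumor: ", tumor, call. = FALSE)
  if (!arm %in% arm_labels(params, tumor)) {
    stop("unknown arm '", arm, "' for tumor ", tumor, call. = FALSE)
  }

  # age advances deterministically from the cohort's mean entry age;
  # background mortality mixes the sexes with the cohort's fraction female
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
  tr1 <- m1l_treatments(params, tumor); n1 <- length(tr1)
  tr2 <- m2l_treatments(params, tumor); n2 <- length(tr2)
  q_m12 <- lapply(tr1, function(t) qv("m1l_to_m2l", t))
  q_m1d <- lapply(tr1, function(t) qv("m1l_to_death", t))
  q_m2d <- qv("m2l_to_death")

  mix1 <- mix_by_stratum(params, tumor, arm, "m1l", tr1, retreatment_allowed)
  mix2 <- mix_by_stratum(params, tumor, arm, "m2l", tr2, retreatment_allowed)
  thr <- st$retreatment_threshold_weeks

  R <- entry_size; D <- 0
  L <- numeric(K + 1L)                       # locoregional tunnels
  M1 <- array(0, dim = c(n1, 2L, K + 1L))    # 1L: treatment x stratum x entry
  M2 <- matrix(0, 2L, K + 1L)                # 2L: stratum x entry

  occ <- matrix(0, K, 5L, dimnames = list(NULL, health_states()))
  occ_strat <- matrix(0, K, 4L, dimnames = list(NULL, c(
    "metastatic_1L.before_threshold", "metastatic_1L.at_or_after_threshold",
    "metastatic_2L.before_threshold", "metastatic_2L.at_or_after_threshold")))
  recurrences <- deaths <- deaths_after <- numeric(K)
  m1_init <- matrix(0, K, n1, dimnames = list(NULL, tr1))
  m2_init <- matrix(0, K, n2, dimnames = list(NULL, tr2))
  rescaled <- FALSE

  for (i in seq_len(K)) {                    # cycle k = i - 1
    jj <- seq_len(i)
    qi <- rev(jj)                            # maps entry index to q index
    b <- bg[i]

    occ[i, 1L] <- R
    occ[i, 2L] <- sum(L[jj])
    occ[i, 3L] <- sum(M1[, , jj])
    occ[i, 4L] <- sum(M2[, jj])
    occ[i, 5L] <- D
    occ_strat[i, 1L] <- sum(M1[, 1L, jj])
    occ_strat[i, 2L] <- sum(M1[, 2L, jj])
    occ_strat[i, 3L] <- sum(M2[1L, jj])
    occ_strat[i, 4L] <- sum(M2[2L, jj])

    # recurrence-free state (clock: weeks since adjuvant initiation)
    p_d <- min(max(q_rfd[i], b), 1)
    pp <- c(q_rflr[i], q_rfm[i]); sp <- sum(pp)
    if (sp > 1) { pp <- pp / sp; rescaled <- TRUE }
    d_rf <- R * p_d
    surv <- R - d_rf
    to_lr <- surv * pp[1]; to_m_rf <- surv * pp[2]
    R <- surv - to_lr - to_m_rf

    # locoregional recurrence tunnels (clock: weeks since state entry)
    Lj <- L[jj]
    pd <- pmax(q_lrd[qi], b); pm <- q_lrm[qi]
    d_lr <- sum(Lj * pd)
    lr_surv <- Lj * (1 - pd)
    to_m_lr <- sum(lr_surv * pm)
    L[jj] <- lr_surv * (1 - pm)

    # first-line metastatic tunnels, per treatment option
    d_m1 <- 0; to_m2 <- 0
    for (t in seq_len(n1)) {
      Wt <- matrix(M1[t, , jj], nrow = 2L)
      if (!any(Wt != 0)) next
      pd <- pmax(q_m1d[[t]][qi], b); pg <- q_m12[[t]][qi]
      d_m1 <- d_m1 + sum(Wt %*% pd)
      keep_d <- rep(1 - pd, each = 2L)
      Wt <- Wt * keep_d
      to_m2 <- to_m2 + sum(Wt %*% pg)
      M1[t, , jj] <- Wt * rep(1 - pg, each = 2L)
    }

    # second-line metastatic tunnels
    d_m2 <- 0
    if (any(M2[, jj] != 0)) {
      V <- matrix(M2[, jj], nrow = 2L)
      pd <- pmax(q_m2d[qi], b)
      d_m2 <- sum(V %*% pd)
      M2[, jj] <- V * rep(1 - pd, each = 2L)
    }

    # entrants occupy the next cycle; eligibility judged at the event cycle
    s_new <- if ((i - 1L) < thr) 1L else 2L
    e1 <- to_m_rf + to_m_lr
    if (e1 > 0) {
      frac <- mix1[[s_new]]
      M1[, s_new, i + 1L] <- M1[, s_new, i + 1L] + e1 * frac
      m1_init[i, ] <- e1 * frac
    }
    if (to_m2 > 0) {
      M2[s_new, i + 1L] <- M2[s_new, i + 1L] + to_m2
      m2_init[i, ] <- to_m2 * mix2[[s_new]]
    }
    L[i + 1L] <- L[i + 1L] + to_lr

    recurrences[i] <- to_lr + to_m_rf
    deaths[i] <- d_rf + d_lr + d_m1 + d_m2
    deaths_after[i] <- d_lr + d_m1 + d_m2
    D <- D + deaths[i]
  }

  if (rescaled) {
    warning("competing exit probabilities exceeded 1 in at least one ",
            "cycle and were rescaled proportionally", call. = FALSE)
  }
  cons_err <- max(abs(rowSums(occ) - entry_size))
  if (cons_err > 1e-9 * max(1, entry_size)) {
    warning("cohort conservation error ", signif(cons_err, 4),
            " exceeds tolerance", call. = FALSE)
  }

  structure(
    list(tumor = tumor, arm = arm, entry_week = entry_week,
         entry_size = entry_size, n_cycles = K,
         retreatment_allowed = retreatment_allowed,
         occupancy = occ, occupancy_stratum = occ_strat,
         recurrences = recurrences,
         m1_initiations = m1_init, m2_initiations = m2_init,
         deaths = deaths, deaths_after_event = deaths_after,
         conservation_error = cons_err),
    class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", x$tumor, " / ", x$arm, ", entry week ",
      x$entry_week, ", ", format(x$entry_size, big.mark = ","),
      " person(s), ", x$n_cycles, " cycles\n", sep = "")
  cat("  recurrences ", signif(sum(x$recurrences), 5), ", deaths ",
      signif(sum(x$deaths), 5), ", conservation error ",
      signif(x$conservation_error, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy export of a cohort trace
#'
#' One row per cycle and health state, with the metastatic states further
#' split by retreatment-eligibility stratum.
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Tibble `cycle, state, stratum, persons` (`stratum` is `NA` for
#'   the non-metastatic states).
#' @export
tidy.cohort_trace <- function(x, ...) {
  K <- x$n_cycles
  base <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(cycle = 0:(K - 1)),
                     tibble::as_tibble(x$occupancy)),
    -"cycle", names_to = "state", values_to = "persons")
  base <- dplyr::filter(base, !.data$state %in%
                          c("metastatic_1L", "metastatic_2L"))
  base$stratum <- NA_character_
  strat <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(cycle = 0:(K - 1)),
                     tibble::as_tibble(x$occupancy_stratum)),
    -"cycle", names_to = "key", values_to = "persons")
  strat <- tidyr::separate_wider_delim(strat, "key", delim = ".",
                                       names = c("state", "stratum"))
  dplyr::arrange(
    dplyr::bind_rows(base[, c("cycle", "state", "stratum", "persons")],
                     strat[, c("cycle", "state", "stratum", "persons")]),
    .data$cycle, .data$state, .data$stratum)
}
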