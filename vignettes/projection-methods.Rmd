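---
title: "Projection methods: early-stage anti-PD-(L)1 adoption and national health outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdl1impact)
```

## The question the model answers

Anti-PD-(L)1 immune checkpoint inhibitors (pembrolizumab, nivolumab) are
standard therapy for many advanced cancers and are approved in Europe for
the neoadjuvant/adjuvant treatment of three early-stage cancers: resected
stage III melanoma, renal cell carcinoma (RCC) at increased risk of
recurrence after nephrectomy, and early-stage triple-negative breast
cancer (TNBC) at high risk of recurrence.  `pdl1impact` projects, at the
national population level and over a 10-year window, the difference in
health outcomes between two treatment policies:

* **Scenario I** — anti-PD-(L)1 agents are reserved for the
  advanced/metastatic setting; every early-stage patient receives a
  traditional strategy (watchful waiting or dabrafenib + trametinib for
  melanoma, watchful waiting for RCC, chemotherapy for TNBC);
* **Scenario II** — anti-PD-(L)1 agents are additionally available in the
  neoadjuvant/adjuvant setting, taken up by an increasing fraction of the
  eligible population each year.

The difference (scenario II − scenario I) in eight outcomes —
recurrence-free life-years, total life-years, QALYs, recurrences,
metastatic treatment initiations, adverse events, total deaths, and
deaths after a first event — quantifies the population health impact of
early adoption.

## Model structure

### States, cycles and entry

The model is a deterministic multi-state cohort model with weekly cycles.
Patients occupy one of five states: recurrence-free (the entry state),
locoregional recurrence, first-line (1L) metastatic treatment, second-line
(2L) metastatic treatment, and death (absorbing).  The metastatic phase is
split into 1L/2L because treatment initiations and adverse events are
counted per line.  A direct recurrence-free → metastatic transition is
supported alongside the route through locoregional recurrence; either can
be switched off by giving it a zero-hazard law, so both topologies (all
metastasis passing through locoregional recurrence, or some arising as
distant recurrence) are expressible.

Each calendar year's eligible incident patients are divided evenly over
the year's 52 model weeks (`weekly_cohorts()`); one model year is exactly
52 weeks, so the 10-year window is 520 cycles and the ~1.25-day annual
drift relative to the civil calendar is ignored.  Every cohort is
propagated from its entry week to the end of the window — a 2031 entrant
contributes at most 52 cycles — because all reporting is confined to the
2022–2031 window.

### Transition laws and clocks

Each transition is governed by a parametric time-to-event law
(`survival_spec()`): exponential, Weibull, log-normal, log-logistic,
Gompertz, or generalized gamma (in the stable `mu`/`sigma`/`Q`
parameterization), with time in weeks.  Treatment effects enter as
proportional hazards: the survival curve is raised to the power of the
hazard ratio, the convention of the network-meta-analysis-based models
this class of projection draws on.  Continuous laws are discretized with
the exact conditional probability
\[
p_k \;=\; 1 - S(k+1)/S(k),
\]
which telescopes — chaining cycles reproduces \(S\) exactly for every
family — rather than with a rate approximation.

Exits from the recurrence-free state run on the clock since adjuvant
initiation.  Exits from the locoregional and metastatic states run on time
since state entry, implemented with entry-cycle tunnels (a semi-Markov
structure): the engine tracks, for each cycle, how many persons entered
the state at each earlier cycle, at quadratic cost in the horizon, which
at 520 cycles is a few hundredths of a second per cohort.  Post-recurrence
laws are identical across adjuvant arms within a tumor — the adjuvant
choice changes who recurs, not what happens afterwards — and this is
validated at load (`validate_shared_transitions()`).

### Mortality floor

No state's weekly death probability may fall below general-population
mortality: the effective probability is the maximum of the trial-based
estimate and the background estimate, `effective_death_prob()`.
Background mortality comes from an annual life table converted to weekly
resolution, \(1-(1-q)^{1/52}\).  The cohort ages deterministically by
1/52 year per cycle from its mean entry age, and the annual \(q\) is mixed
across sexes with the cohort's fraction female before conversion, because
the model tracks a single pooled cohort per tumor rather than sex strata.

### Within-cycle resolution and competing exits

The transition laws are marginal, one per exit.  Within a cycle, deaths
are resolved first (the floored death probability applies to the full
state occupancy) and survivors then face the progression exits; if the
progression probabilities of a state ever sum above 1 — possible only in
pathological parameter regions, never under the shipped generator — they
are rescaled proportionally with a warning.  With weekly cycles the
within-cycle interaction terms this ignores are of order \(p^2\) and
negligible.  No half-cycle correction is applied, for the same reason.

### Retreatment eligibility

Rechallenge with an anti-PD-(L)1 agent at recurrence is assumed possible
only from 18 months (78 weeks, configurable) after adjuvant initiation.
Eligibility is evaluated at each metastatic treatment initiation (1L and
2L) against that clock, since the rule is defined on time since adjuvant
initiation: an initiation during a cycle before the threshold uses the
`before_threshold` mix, which for the anti-PD-(L)1 adjuvant arm excludes
retreatment; from the threshold cycle on, the `at_or_after_threshold` mix
applies.  The no-retreatment sensitivity scenario maps every stratum to
the no-retreatment mix.

### Metastatic treatment mixes

1L and 2L treatment mixes are conditional on the adjuvant arm and the
eligibility stratum.  1L progression and death laws are keyed by 1L
treatment option, and the 1L→2L transition is governed by the 1L
progression law (equivalence with progression-free survival).  The 2L mix
affects adverse-event accounting at initiation; 2L survival is a single
shared law.

## Outcomes, discounting and reporting

Life-years accrue as start-of-cycle occupancy × 1/52 year.  QALYs weight
occupancy by tumor/state utility and a multiplicative sex-weighted
age-band adjustment, and subtract adverse-event losses.  Adverse events
are one-time events at treatment initiation: expected count =
initiations × events per patient; QALY loss = count × weeks per event ×
|disutility| / 52 (`ae_burden()`), incurred and discounted at the
initiation cycle.

Discounting uses \((1+r)^{-c/52}\) at annual rate \(r\) (default 1.5%)
with \(c\) counted from the start of the window: a population-level,
budget-impact-style horizon discounts calendar time, not each patient's
own clock.  This is switchable (`settings$discount_from = "entry"`).
Event counts — recurrences, treatment initiations, adverse events, deaths
— are reported undiscounted by default: they are counts of occurrences,
and fractional discounted deaths are not meaningful in a reporting table.
Discounting them too is available via `settings$discount_event_counts`,
since reporting conventions differ across agencies.

Per-year attribution assigns each cycle's accrual to the calendar year
containing that cycle.  Percent changes are reported as integers under
half-away-from-zero rounding (`round_half_out()`), the convention that
reproduces standard reporting tables; a zero denominator yields an absent
percent.  In the scenario sensitivity table the percent change of an
impact is computed against the *signed* base-case impact,
\(\mathrm{round}(100\,(v-b)/b)\), so a positive sign always means a
larger benefit — also when the impact is a negative avoided count.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `horizon_years` | 10 | years | projection window (2022–2031) |
| `annual_discount_rate` | 0.015 | – | outcome discounting |
| `retreatment_threshold_weeks` | 78 | weeks | anti-PD-(L)1 rechallenge rule (18 months) |
| `discount_event_counts` | `FALSE` | – | whether counts are discounted |
| `discount_from` | `"model_start"` | – | calendar vs entry clock discounting |
| `launch_delay_years` | 2 | years | delayed-launch sensitivity scenario |

The launch delay of the sensitivity scenario is not standardised anywhere;
2 years is the package's default and is configurable.

## The synthetic parameter generator

The real projection's transition parameters were fitted to patient-level
data from the pivotal trials (KEYNOTE-054/-564/-522), its market shares
come from proprietary market research, and its utilities from trial EQ-5D
mappings; none of these are published.  `synth_params()` therefore
generates complete synthetic bundles that emulate the *structure* of
those inputs:

* arm-dependent recurrence-free survival: Weibull baselines under
  traditional management with medians anchored to the magnitude of the
  pivotal-trial control arms (about 110 weeks for stage III melanoma,
  260 for high-risk RCC, 420 for early TNBC), and anti-PD-(L)1 hazard
  ratios drawn in [0.55, 0.80] with symmetric log-scale 95% CIs —
  treatment benefit is built in, matching the direction of the trial
  evidence;
* arm-independent post-recurrence transitions, line-specific metastatic
  survival with an anti-PD-(L)1 OS/PFS advantage in 1L, and a shared 2L
  law;
* adverse-event profiles per setting and treatment, with the published
  per-tumor disutilities (−0.05/−0.13/−0.14 for melanoma,
  −0.06/−0.05/−0.05 for RCC, −0.02/−0.03/−0.03 for TNBC) and synthetic
  event rates and durations;
* utilities ordered recurrence-free > locoregional > 1L > 2L > 0, with an
  age-decreasing adjustment table;
* a Gompertz life table closed at age 100 (`synth_life_table()`);
* the shipped national population totals for 2022–2031 and the uptake
  schedule they imply (63.3% rising to 88.7%).

Two population quantities deserve emphasis.  The annual totals are shipped
exactly as published; their per-tumor split is **synthetic** (default
35/25/40% melanoma/RCC/TNBC), because only the three-tumor totals are
public.  And the single pooled fraction female (50.37%) is applied to all
three tumors; a per-tumor split would be invented detail with no public
anchor, and it only enters through background mortality and the utility
adjustment.

What the generator does **not** emulate: the actual KEYNOTE survival
curves (no fitting to reconstructed data), treatment switching within a
line, cure fractions, covariate heterogeneity beyond age/sex means, or
registry-based incidence forecasting (annual eligible counts are inputs).
Passing tests on synthetic bundles therefore validates the machinery —
conservation, linearity, discounting, the comparison layer, agreement
with an independent microsimulation — not the published impact numbers,
which depend on the unpublished inputs and are deliberately not
calibration targets.  Mean body weight is carried as a demographic input
and registered in the one-way sensitivity analysis but is inert: it
affected dosing and costs in the source model, and this package reports
health outcomes only.

## Validation design

Three independent layers check the engine:

1. **Closed forms** — all-exponential configurations have analytic
   occupancy (\(e^{-\lambda k}\)) and life-year integrals; the weekly sum
   overestimates \(\int S\) by a factor \(\lambda/(1-e^{-\lambda})\approx
   1+\lambda/2\), so toy rates are kept at or below 0.005/week where the
   discrepancy is under 0.25%.
2. **Telescoping** — chained conditional cycle probabilities reproduce
   \(S(k)\) to \(10^{-10}\) for all six families.
3. **Microsimulation** — `simulate_cohort()` samples individual
   trajectories from the same per-cycle probabilities (same floor, same
   resolution order, same mix assignment) and must agree with the
   deterministic totals within 3 Monte-Carlo standard errors at
   n = 50,000.  It shares only the one-step transition probabilities with
   the engine, not its tunnel bookkeeping, aggregation or discounting
   code paths.

Structural invariants are tested directly: per-cycle conservation of the
entry size to \(10^{-9}\), monotone absorption in death, exact linearity
of every outcome in the entry counts, exact additivity of impacts across
tumors (tumors are computed as independent strata and summed), and exact
scenario equivalence when uptake is identically zero.

Problem sizes in the shipped tests were chosen to exercise the full
520-cycle horizon everywhere while keeping the default suite around two
minutes: 20 seeded bundles for the conservation sweep, three seeded
n = 50,000 microsimulation configurations, and single-bundle runs for the
scenario and sensitivity properties.

## Numerical choices and degenerate inputs

* `S(cycle) = 0` maps to a transition probability of 1 (state depleted).
* Zero-hazard transitions are expressed as `exponential(0)`; the hazard
  ratio 0 limit is likewise permitted.
* Ages beyond the life table use its closing row (`q = 1`).
* Cohort traces warn if conservation error exceeds \(10^{-9}\) relative
  to the entry size; in practice it stays near \(10^{-13}\).
* The engine is run once per tumor/arm on a unit cohort and reused for
  all 520 entry weeks (the dynamics depend only on time since entry);
  this makes linearity in the population exact by construction and keeps
  a full two-scenario projection under a second.
* Configuration files are JSON written at 17 significant digits, so a
  write/read round trip reproduces a bundle bit-for-bit.

## Limitations

The projection inherits the limitations of its class: a 10-year window
truncates benefits that accrue later (adjuvant benefit compounds over
decades); transition laws extrapolate trial follow-up parametrically; the
pooled-cohort treatment of age and sex ignores heterogeneity; and every
numeric conclusion drawn from the synthetic generator characterises the
model, not Swiss reality.  The package is a tested re-implementation of
the projection *machinery*; feeding it real fitted parameters is what
would make its outputs decision-relevant.
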