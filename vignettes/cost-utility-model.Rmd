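---
title: "The sequential-treatment cost-utility model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sequential-treatment cost-utility model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seqcea` implements a cohort state-transition (Markov) model for the
cost-utility of sequential rheumatoid-arthritis treatment: a first-line
TNF inhibitor, a cascade of conventional DMARDs after discontinuation,
and palliation. This vignette is the package's account of the model, its
assumptions, the choices made where the design was genuinely open, and
what the synthetic defaults do and do not represent.

## Cohort, cycles and states

The cohort enters at a mean age of 52.2 years, 82.7 % female, with a
baseline HAQ-DI of 1.624 and a baseline EQ-5D utility of 0.38 —
characteristics of an RA population with inadequate response to
methotrexate that is eligible for biologic therapy.

The first cycle runs to the response assessment (6 months in the base
case, 3 months as a scenario); cycles within year one keep the
assessment length, and all later cycles are 6 months, out to a 45-year
(lifetime) horizon. At the end of the first cycle the cohort is split
into exclusive response categories obtained by successive differences of
the cumulative ACR fractions (`p70 = acr70`, `p50 = acr50 − acr70`,
`p20 = acr20 − acr50`, `p_none = 1 − max(·)`), clamped at zero with a
warning when a published row is non-monotone. Non-responders (no ACR20)
leave first-line therapy immediately for the first follow-up line.

Responders stay on first-line therapy with a per-cycle discontinuation
probability `1 − 0.5^(cycle_months / 37)` — the constant-hazard reading
of the 37-month median duration on TNF inhibitors. Each follow-up line
has an assessment state (one cycle; non-responders move to the next
line) and a continuing state with its own median-duration hazard. The
last exit is palliation, which only death leaves. Responders keep their
cycle-1 ACR category for their whole time on first-line treatment; no
re-classification rule exists in this model family, so none is invented.

Within a cycle, death and discontinuation compete *sequentially*: death
is applied first, then discontinuation among survivors, so
`stay = (1 − p_death)(1 − p_disc)` and every row of every transition
matrix sums to one without renormalisation. This is the standard way to
keep a multi-risk cohort model stochastic; simultaneous (independent)
application would need explicit overlap handling.

## Disability, utility and QALYs

HAQ-DI is the tracked attribute that drives utilities, resource costs
and mortality. The engine tracks, per state and cycle, the occupancy and
the occupancy-weighted mean HAQ; transitions carry HAQ jumps:

- entering a response category applies its HAQ change (defaults
  0 / −0.32 / −0.55 / −0.80 for none/ACR20/ACR50/ACR70, magnitudes
  ordered by response depth);
- remaining on first-line therapy adds a continuation improvement of
  10 % of the first-cycle gain, accrued linearly over the year after the
  first assessment (the continued improvement is described
  qualitatively as much smaller than the initial response, so the
  fraction is an explicit, overridable default);
- discontinuation applies a rebound of 100 % of the accumulated
  treatment-attributable gain (50 % as a scenario), and entry to the
  next line applies that line's own expected gain, so the model does not
  penalise high-discontinuation strategies beyond their efficacy;
- conventional-therapy and palliation states drift upward at 0.045 and
  0.06 HAQ units/year, capped at HAQ = 3.

Utility is anchored to HAQ through the linear mapping
ΔEQ-5D = −0.2102·ΔHAQ. Explicit regression-derived utility gains per
response category can be configured
(`utility$response_gain_explicit`); when they are, the engine converts
them to HAQ-equivalents through the same mapping, which keeps a single
internally consistent pathway (and makes the HAQ-DI-instrument scenario
the identity under the defaults). The rebound applies to the *total*
on-treatment gain, including the continuation phase — that is the
reading of "back to baseline" consistent with a 100 % rebound.

Within the first cycle the utility of responders rises piecewise
linearly: 80 % of the first-cycle gain by week 4, the rest by cycle end.
The first cycle's QALY contribution integrates this profile exactly
(trapezoid areas); later cycles use the start-of-cycle state value.
Curvature matters only during the initial response, which is the only
period for which a shape is specified.

QALYs are the occupancy-weighted utilities times cycle length,
discounted at 3.5 %/year at cycle start; with
`half_cycle_correction = TRUE` discounting moves to cycle midpoints,
which also credits within-cycle deaths with half a cycle. The base case
leaves it off; both behaviours are exposed because the convention is
genuinely ambiguous in this model family.

## Mortality

A life table supplies annual death probabilities by age and sex; the
cohort's mean age advances by the cycle length each cycle and mortality
is evaluated at the rounded integer age with a fixed female/male mixture
weight (a single cohort, not separate sex traces). The mortality
adjustment for disability multiplies the *hazard*, not the probability:
`q → 1 − exp(−(−ln(1 − q))·1.330^HAQ·cycle_years)`. On the probability
scale a relative risk of 1.33 per HAQ unit would exceed 1 at high ages;
the hazard scale is the standard interpretation. First-cycle deaths are
applied at baseline HAQ simultaneously with response classification —
the ordering does not affect any downstream quantity because both
responders and non-responders share the baseline mortality rate in that
cycle.

## Costs

Drug acquisition follows each regimen's dosing calendar on a week grid
(1 year = 52 weeks = 12 months; cycle windows are half-open in weeks).
Under the base-case per-unit method the smallest whole number of
vials/syringes covering each dose is dispensed and the remainder wasted;
per-mg costing (exact fractional units) is a scenario. Weight-based
infliximab doses use the fixed 81.4 kg average weight in the base case;
under the weight-distribution mode the expected vial count is
`Σ_j P(W > j·vial_mg/mg_per_kg)`, the exact expectation of the ceiling
under the weight CDF. Methotrexate co-therapy is costed at zero in the
base case (the price is retained in the cost table behind
`mtx_cost_zero = FALSE`, because the published unit-cost table and the
stated assumption disagree and both must be expressible).

IV strategies add €232.80 per infusion (day-hospital administration).
The ±20 % administration-cost scenarios pivot on the €214.54
day-hospital value used in published sensitivity analyses (giving 257.45
and 171.63); the base case keeps the resource-table price — the two
printed values cannot both be the base case, and this is recorded as an
interpretation. Monitoring is a fixed panel (rheumatologist visit,
complete blood count, sedimentation rate, clinical chemistry,
urinalysis) twice per cycle in year one and once per cycle thereafter,
identical across strategies — monitoring recommendations name
frequencies, not schedules, and identical schedules cancel in
incremental results. Oral follow-up DMARDs are costed per mg from pack
prices at standard maintenance doses; HAQ-band resource costs add an
annual cost per 0.5-band of current HAQ. Costs inflate at 3 %/year from
2009 and discount at 3.5 %/year, both applied at the cycle's start-time
offset (net factor ≈ 0.9952/year); the combination rule is a documented
convention, not a published one.

The societal-perspective toggle exists but adds no cost components by
default: indirect costs are excluded from this model family, so the
toggle is a configuration hook.

## What the synthetic defaults emulate

Several inputs that published analyses rely on are cited from external
sources without printed values. They live in a defaults registry
(`defaults_registry()`), every entry flagged `provenance = "default"`
with a rationale:

- **Life table** — Gompertz–Makeham hazard
  `h(a) = 2·10⁻⁴ + 3·10⁻⁵·e^{0.1a}` (female factor 0.55), roughly
  Southern-European adult mortality, closed at age 100. Mortality enters
  only as a background hazard later adjusted for HAQ, so results do not
  hinge on its exact values — but absolute life expectancy, and hence
  absolute QALY totals, do shift with it.
- **Follow-up DMARD efficacy** — 6-month ACR rows near the printed
  methotrexate row, strictly below every biologic strategy (weakest
  printed biologic-combination ACR20 is 0.482), with median durations of
  15–24 months tapering down the sequence.
- **HAQ changes by response category, HAQ-band costs, continuation
  fraction, progression rates** — explicit values of realistic
  magnitude, monotone where monotonicity is the only implied constraint.
- **Weight distribution** — log-normal with median 81.4 kg and
  coefficient of variation ≈ 0.2 (the mean is `81.4·e^{σ²/2}`, slightly
  above the median, as for right-skewed weight data).
- **PSA response uncertainty** — the log-odds standard error of the
  response fractions is not derivable from printed material; the default
  is 0.15 on the log-odds scale. Prior-DMARD count, disease duration and
  antibody status are drawn (they belong to the published PSA design)
  but do not propagate: they were covariates of an unpublished utility
  regression that is out of scope.

Consequently, *incremental* quantities — cost and QALY differences,
dominance, ICERs, CEAC orderings — are the meaningful outputs of the
default configuration; absolute lifetime costs and QALYs depend on the
defaulted inputs and should be read as internally consistent magnitudes,
not reproductions of any published absolute figure. Passing tests show
the machinery is exact (arithmetic, conservation, oracles) and the
qualitative structure is right; they cannot show that unpublished inputs
were recovered.

## Numerical choices

- Cycle grids and dose windows are half-open (`[start, end)`), so dose
  events are counted exactly once.
- Exclusive response probabilities clamp negative successive differences
  to zero with a warning; the PSA suppresses the warning because
  independently drawn cumulative fractions cross routinely.
- Transition-matrix rows are checked to sum to 1 within 1e−12 in the
  test suite; the engine keeps them stochastic by construction.
- Occupancy below 1e−300 is treated as empty when updating state-mean
  HAQ, avoiding 0/0; unoccupied states carry their deterministic HAQ
  forward.
- Utility is clamped to `[utility_floor, 1]` (floor 0 by default; the
  baseline 0.38 minus the maximal HAQ excursion stays positive anyway);
  HAQ is clamped to `[0, 3]`.
- The degenerate one-cycle model, empty dose windows, and the
  no-follow-up sequence (first line → palliation) are all exercised in
  tests.

## Problem sizes used in the tests

The full default model is 20 states × 90 cycles and evaluates in well
under a second per strategy; unit tests mostly use 5–10-year horizons
for speed. The acceptance suite runs the probabilistic sensitivity
analysis at its full design size — 1000 draws across the seven
combination-therapy strategies — and checks seed reproducibility and
CEAC propriety at that size. Cohort-sampling checks use n = 100,000
draws against 3-standard-error bands.

## Known limitations

- A cohort model with tracked mean HAQ is not a microsimulation:
  within-state HAQ heterogeneity is collapsed to the mean, and the
  rebound applied to follow-up-line leavers uses the line's expected
  entry gain rather than individual histories (exact in expectation
  under full rebound).
- Follow-up lines carry one on-line state, not full ACR sub-states; no
  downstream quantity in this model family distinguishes them.
- Adverse-event costs and consequences are excluded by design, as are
  indirect/productivity costs; treatment re-challenge is not modelled.
- The 3-month assessment scenario uses imputed ACR50/70 fractions for
  the adalimumab combination (scaled from its 6-month ratios), flagged
  as defaults.
- Absolute outputs are conditional on the synthetic defaults registry,
  as discussed above.
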