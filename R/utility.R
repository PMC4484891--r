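#' Map a HAQ-DI change to an EQ-5D utility change
#'
#' Linear mapping `delta_utility = coefficient * delta_haq` with the
#' published conversion coefficient -0.2102 (a one-unit HAQ-DI worsening
#' costs 0.2102 utility).
#'
#' @param delta_haq Change in HAQ-DI (|delta| <= 3).
#' @param coefficient Utility change per unit HAQ-DI change.
#' @return Utility change(s).
#' @export
#' @examples
#' haq_to_utility_delta(1) # -0.2102
haq_to_utility_delta <- function(delta_haq, coefficient = -0.2102) {
  if (any(abs(delta_haq) > 3)) abort("|delta_haq| must be <= 3")
  coefficient * delta_haq
}

#' First-cycle utility gain by ACR response category
#'
#' Returns the utility gained over the first treatment cycle for each
#' response category. If explicit regression-derived gains are configured
#' (`utility$response_gain_explicit`, a named vector over
#' none/acr20/acr50/acr70), they are used; otherwise the registry's HAQ-DI
#' changes by category are mapped through [haq_to_utility_delta()].
#'
#' @param category One of `"none"`, `"acr20"`, `"acr50"`, `"acr70"`.
#' @param utility Utility inputs (see [default_parameter_set()]`$utility`).
#' @param defaults Defaults registry (see [defaults_registry()]).
#' @return Utility gain (>= 0 for the default monotone HAQ changes).
#' @export
response_gain <- function(category = c("none", "acr20", "acr50", "acr70"),
                          utility, defaults) {
  category <- match.arg(category)
  if (!is.null(utility$response_gain_explicit)) {
    return(unname(utility$response_gain_explicit[[category]]))
  }
  dhaq <- defaults$haq_change_by_acr_category[[category]]
  unname(haq_to_utility_delta(dhaq, utility$bansback_coefficient))
}

#' Within-first-cycle utility profile
#'
#' Piecewise-linear utility over the first treatment cycle: utility rises
#' from the baseline to `baseline + front_load_fraction * gain` at the
#' front-load week (base: 80% of the 6-month change achieved by week 4),
#' then linearly to `baseline + gain` at cycle end. Returns the profile
#' function and its exact time-average over the cycle (trapezoid areas of
#' the two linear segments).
#'
#' @param baseline_u Utility at cycle start.
#' @param gain Total utility gain over the cycle.
#' @param cycle_months Cycle length in months.
#' @param utility Utility inputs (front-load fraction/week, ceiling).
#' @return List with `value_at(week)`, `mean_utility` (time-average) and
#'   `qaly_area` (utility integrated over the cycle, in QALYs).
#' @export
first_cycle_utility_profile <- function(baseline_u, gain, cycle_months, utility) {
  ceiling_u <- utility$utility_ceiling %||% 1
  if (baseline_u + gain > ceiling_u) {
    warn("utility gain clamped at ceiling")
    gain <- ceiling_u - baseline_u
  }
  f <- utility$front_load_fraction
  wk_f <- utility$front_load_week
  wk_end <- cycle_months * WEEKS_PER_MONTH
  value_at <- function(week) {
    week <- pmin(pmax(week, 0), wk_end)
    ifelse(week <= wk_f,
      baseline_u + f * gain * week / wk_f,
      baseline_u + gain * (f + (1 - f) * (week - wk_f) / (wk_end - wk_f))
    )
  }
  # trapezoid areas (years): segment means times segment lengths
  seg1 <- (wk_f / WEEKS_PER_YEAR) * (baseline_u + f * gain / 2)
  seg2 <- ((wk_end - wk_f) / WEEKS_PER_YEAR) * (baseline_u + gain * (f + 1) / 2)
  qaly_area <- seg1 + seg2
  list(
    value_at = value_at,
    mean_utility = qaly_area / (cycle_months / 12),
    qaly_area = qaly_area
  )
}

#' Continuation-phase improvement while remaining on treatment
#'
#' Patients who remain on treatment continue to improve over the year
#' following the first on-treatment period, at a much smaller rate:
#' `continuation_gain_fraction * gain_first_cycle`, accrued linearly over
#' the following two cycles, zero thereafter.
#'
#' @param gain_first_cycle First-cycle utility gain.
#' @param utility Utility inputs.
#' @return Additional utility gained over the continuation window.
#' @export
continuation_improvement <- function(gain_first_cycle, utility) {
  utility$continuation_gain_fraction * gain_first_cycle
}

#' Utility change at treatment discontinuation (rebound)
#'
#' On discontinuation a fraction of the accumulated on-treatment gain is
#' lost: `-rebound_fraction * total_on_treatment_gain` (100% rebound is
#' "back to baseline"). The next line's own response gain is applied
#' separately on entry to that line.
#'
#' @param total_on_treatment_gain Accumulated treatment-attributable gain.
#' @param rebound_fraction Fraction in \[0, 1\].
#' @return Utility change (<= 0 for positive gains).
#' @export
rebound_utility_change <- function(total_on_treatment_gain, rebound_fraction) {
  if (rebound_fraction < 0 || rebound_fraction > 1) {
    abort("rebound_fraction must be in [0, 1]")
  }
  -rebound_fraction * total_on_treatment_gain
}

#' Off-treatment HAQ-DI drift
#'
#' Disability worsens linearly at `annual_rate` HAQ-DI units per year on
#' conventional therapy or palliation, capped at the HAQ ceiling of 3.
#'
#' @param haq_now Current HAQ-DI.
#' @param annual_rate HAQ-DI units per year (>= 0).
#' @param months Elapsed months.
#' @return New HAQ-DI value.
#' @export
offtreatment_haq_drift <- function(haq_now, annual_rate, months) {
  if (annual_rate < 0) abort("annual_rate must be non-negative")
  pmin(3, haq_now + annual_rate * months / 12)
}

#' Discounted quality-adjusted life years from a cohort trace
#'
#' Sums occupancy-weighted mean utility over cycles, each cycle's
#' contribution being `occupancy * utility * cycle_years` discounted at
#' the cycle start (or midpoint under the half-cycle correction). The
#' death state contributes zero.
#'
#' @param trace A cohort trace from [run_cohort()] (long tibble with
#'   `cycle`, `time_years`, `cycle_years`, `state`, `occupancy`,
#'   `utility`).
#' @param rate Annual discount rate for outcomes.
#' @param settings Model settings (for the half-cycle flag).
#' @return Total discounted QALYs.
#' @export
discounted_qalys <- function(trace, rate, settings) {
  t_disc <- trace$time_years +
    if (isTRUE(settings$half_cycle_correction)) trace$cycle_years / 2 else 0
  u <- ifelse(trace$state == "death", 0, trace$utility)
  sum(trace$occupancy * u * trace$cycle_years * (1 + rate)^(-t_disc))
}
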