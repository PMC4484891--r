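#' HAQ-adjusted mortality hazard multiplier
#'
#' Disability raises background mortality log-linearly: the hazard
#' multiplier is `rr_per_unit ^ haq`, so each additional HAQ-DI unit
#' multiplies the mortality hazard by the relative risk (base 1.330).
#'
#' @param haq HAQ-DI value(s) in \[0, 3\].
#' @param rr_per_unit Relative risk of death per HAQ-DI unit (> 0).
#' @return Hazard multiplier(s).
#' @export
#' @examples
#' haq_mortality_multiplier(1, 1.330) # 1.330
haq_mortality_multiplier <- function(haq, rr_per_unit) {
  if (any(haq < 0 | haq > 3)) abort("haq must be in [0, 3]")
  if (rr_per_unit <= 0) abort("rr_per_unit must be positive")
  rr_per_unit^haq
}

#' Convert an annual probability to a cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p_annual)^(months / 12)`. An
#' annual probability of 1 is absorbing and maps to 1 for any cycle
#' length.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param months Cycle length in months (> 0).
#' @return Cycle probability.
#' @export
annual_to_cycle_probability <- function(p_annual, months) {
  if (any(p_annual < 0 | p_annual > 1)) abort("p_annual must be in [0, 1]")
  if (months <= 0) abort("months must be positive")
  ifelse(p_annual >= 1, 1, 1 - (1 - p_annual)^(months / 12))
}

# Sex-mix-weighted annual death probability at the integer age nearest
# `age`. Errors when the life table does not cover the age.
weighted_annual_qx <- function(age, proportion_female, life_table) {
  a <- round(age)
  rows <- life_table[life_table$age == a, ]
  if (nrow(rows) == 0) abort(sprintf("life table does not cover age %s", a))
  qm <- rows$qx[rows$sex == "male"]
  qf <- rows$qx[rows$sex == "female"]
  (1 - proportion_female) * qm + proportion_female * qf
}

#' Per-cycle death probability adjusted for age, sex mix and disability
#'
#' Looks up the sex-mix-weighted annual death probability at the cohort's
#' (rounded) current age, converts it to a hazard, multiplies the hazard
#' by the HAQ multiplier (relative risks act on the hazard scale, so
#' probabilities can never exceed 1), and converts back to a probability
#' over the cycle length. When the HAQ-mortality association is disabled
#' the unadjusted probability is returned.
#'
#' @param ctx List with `current_mean_age` (years), `proportion_female`,
#'   `current_haq` (HAQ-DI), `cycle_length_months`.
#' @param mortality Mortality inputs: `life_table`, `rr_per_haq_unit`,
#'   `enabled` (see [default_parameter_set()]`$mortality`).
#' @return Death probability over the cycle.
#' @export
cycle_death_probability <- function(ctx, mortality) {
  qx <- weighted_annual_qx(ctx$current_mean_age, ctx$proportion_female,
                           mortality$life_table)
  hazard <- -log(1 - min(qx, 1 - 1e-15))
  mult <- if (isTRUE(mortality$enabled)) {
    haq_mortality_multiplier(ctx$current_haq, mortality$rr_per_haq_unit)
  } else {
    1
  }
  min(1, 1 - exp(-hazard * mult * ctx$cycle_length_months / 12))
}
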