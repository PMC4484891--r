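#' Registered one-way sensitivity scenarios
#'
#' The named scenario set for one-way sensitivity analysis: time horizon
#' (5/10 years), crossed discount rates (1.5%/6% for costs and outcomes),
#' zero inflation, 3-month response assessment, alternative baseline
#' HAQ-DI (1.61, 2.5), 50% rebound, per-mg drug costing, the HAQ-DI
#' quality-of-life pathway, no HAQ-mortality association, the societal
#' perspective hook, and +/-20% IV administration cost around the
#' published day-hospital pivot (214.54, giving 257.44 and 171.63).
#'
#' @return Named list of override lists usable with [resolve_scenario()].
#' @export
owsa_scenarios <- function() {
  list(
    horizon_5y = list(settings = list(horizon_years = 5)),
    horizon_10y = list(settings = list(horizon_years = 10)),
    discount_1.5_1.5 = list(settings = list(discount_rate_costs = 0.015, discount_rate_outcomes = 0.015)),
    discount_1.5_6 = list(settings = list(discount_rate_costs = 0.015, discount_rate_outcomes = 0.06)),
    discount_6_1.5 = list(settings = list(discount_rate_costs = 0.06, discount_rate_outcomes = 0.015)),
    discount_6_6 = list(settings = list(discount_rate_costs = 0.06, discount_rate_outcomes = 0.06)),
    inflation_0 = list(settings = list(inflation_rate = 0)),
    acr_3mo = list(settings = list(response_assessment_months = 3)),
    haq_baseline_1.61 = list(population = list(baseline_haq = 1.61)),
    haq_baseline_2.5 = list(population = list(baseline_haq = 2.5)),
    rebound_50 = list(utility = list(rebound_fraction = 0.5)),
    costing_per_mg = list(settings = list(costing_method = "per_mg")),
    qol_haq_di = list(utility = list(response_gain_explicit = NULL)),
    mortality_off = list(mortality = list(enabled = FALSE)),
    societal = list(settings = list(perspective = "societal")),
    iv_admin_plus20 = list(costs = list(iv_administration_cost = 214.54 * 1.2)),
    iv_admin_minus20 = list(costs = list(iv_administration_cost = 214.54 * 0.8))
  )
}

deep_modify <- function(base, overrides) {
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (is.list(ov) && !is.data.frame(ov) && nm %in% names(base) &&
        is.list(base[[nm]]) && !is.data.frame(base[[nm]])) {
      base[[nm]] <- deep_modify(base[[nm]], ov)
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

#' Apply a scenario to a base configuration
#'
#' Returns a new configuration differing from `base` only in the
#' overridden fields; the base configuration is unchanged. `scenario` is
#' either the name of a registered scenario (see [owsa_scenarios()]) or an
#' explicit nested override list such as
#' `list(settings = list(horizon_years = 5))`. Applying the same scenario
#' twice is idempotent.
#'
#' @param base A `cea_config`.
#' @param scenario Scenario name or override list.
#' @return A validated `cea_config`.
#' @export
#' @examples
#' cfg5 <- resolve_scenario(default_parameter_set(), "horizon_5y")
#' cfg5$settings$horizon_years
resolve_scenario <- function(base, scenario) {
  stopifnot(inherits(base, "cea_config"))
  if (is.character(scenario)) {
    reg <- owsa_scenarios()
    if (!scenario %in% names(reg)) {
      abort(sprintf(
        "unknown scenario '%s'; registered scenarios: %s",
        scenario, paste(names(reg), collapse = ", ")
      ))
    }
    overrides <- reg[[scenario]]
  } else {
    overrides <- scenario
  }
  out <- deep_modify(base, overrides)
  class(out) <- "cea_config"
  out$provenance <- build_provenance(out)
  validate_config(out)
  out
}
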