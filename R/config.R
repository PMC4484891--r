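#' Model settings
#'
#' Global settings of the cost-utility model: horizon, cycle structure,
#' discounting/inflation, willingness-to-pay, costing method and
#' perspective.
#'
#' @param horizon_years Time horizon in years (0, 100]; base 45 (lifetime).
#' @param response_assessment_months Months until the first response
#'   assessment, 3 or 6; sets the year-1 cycle length. Base 6.
#' @param cycle_months_after_year1 Cycle length after month 12 (fixed 6).
#' @param discount_rate_costs,discount_rate_outcomes Annual discount rates
#'   (base 0.035 each).
#' @param inflation_rate Annual cost inflation from the cost year onwards
#'   (base 0.03).
#' @param cost_year Calendar year the unit costs refer to (2009).
#' @param wtp_threshold Willingness-to-pay in euro per QALY (base 30000).
#' @param costing_method `"per_unit"` (unused drug wasted) or `"per_mg"`.
#' @param perspective `"payer"` or `"societal"` (societal adds no cost
#'   components by default; it is a configuration hook).
#' @param half_cycle_correction Discount at cycle midpoints and credit
#'   half a cycle of utility to within-cycle deaths (base `FALSE`).
#'
#' @return A validated settings list.
#' @export
model_settings <- function(horizon_years = 45,
                           response_assessment_months = 6,
                           cycle_months_after_year1 = 6,
                           discount_rate_costs = 0.035,
                           discount_rate_outcomes = 0.035,
                           inflation_rate = 0.03,
                           cost_year = 2009,
                           wtp_threshold = 30000,
                           costing_method = c("per_unit", "per_mg"),
                           perspective = c("payer", "societal"),
                           half_cycle_correction = FALSE) {
  s <- list(
    horizon_years = horizon_years,
    response_assessment_months = response_assessment_months,
    cycle_months_after_year1 = cycle_months_after_year1,
    discount_rate_costs = discount_rate_costs,
    discount_rate_outcomes = discount_rate_outcomes,
    inflation_rate = inflation_rate,
    cost_year = cost_year,
    wtp_threshold = wtp_threshold,
    costing_method = match.arg(costing_method),
    perspective = match.arg(perspective),
    half_cycle_correction = half_cycle_correction
  )
  validate_settings(s)
  s
}

validate_settings <- function(s) {
  if (!(s$horizon_years > 0 && s$horizon_years <= 100)) {
    abort(sprintf("horizon_years must be in (0, 100], got %s", s$horizon_years))
  }
  for (r in c("discount_rate_costs", "discount_rate_outcomes", "inflation_rate")) {
    if (s[[r]] < 0 || s[[r]] > 0.2) {
      abort(sprintf("%s must be in [0, 0.2], got %s", r, s[[r]]))
    }
  }
  if (!s$response_assessment_months %in% c(3, 6)) {
    abort("response_assessment_months must be 3 or 6")
  }
  if (12 %% s$response_assessment_months != 0) {
    abort("response_assessment_months must divide 12")
  }
  invisible(s)
}

#' Treatment and resource unit costs (euro, cost year 2009)
#'
#' @return Tibble with columns `drug`, `cost`, `presentation`,
#'   `unit_strength_mg`, `units_per_pack`.
#' @export
default_drug_costs <- function() {
  tibble::tribble(
    ~drug, ~cost, ~presentation, ~unit_strength_mg, ~units_per_pack,
    "CZP", 474, "pre-filled syringe", 200, 1,
    "IFX", 536.28, "vial", 100, 1,
    "ADA", 514.15, "pre-filled syringe", 40, 1,
    "ETA", 118.40, "pre-filled syringe", 25, 1,
    "MTX", 2.11, "tablets", 3, 50,
    "azathioprine", 5.78, "tablets", 50, 50,
    "cyclosporine", 65.90, "tablets", 100, 30,
    "gold sodium thiomalate", 6.73, "vial", 50, 1,
    "hydroxychloroquine", 7.33, "tablets", 200, 30,
    "leflunomide", 57.59, "tablets", 20, 30,
    "penicillamine", 6.75, "tablets", 250, 30,
    "sulfasalazine", 2.38, "tablets", 500, 50,
    "palliation", 0, NA, NA, NA,
    "methylprednisolone", 1.59, "vial", 40, 1
  )
}

default_monitoring_costs <- function() {
  tibble::tribble(
    ~item, ~cost,
    "primary care physician", 26.78,
    "nurse outpatient", 23.77,
    "hospital nurse hour", 13.19,
    "rheumatologist", 99.94,
    "hospital pharmacist", 105.66,
    "iv administration day hospital", 232.80,
    "complete blood count", 6.37,
    "sedimentation rate", 3.56,
    "clinical chemistry profile", 6.31,
    "urinalysis", 4.00,
    "chest x-ray", 11.61
  )
}

#' The base-case parameter set
#'
#' Assembles the full model configuration: settings, strategies, response
#' probabilities, unit costs, utility and mortality parameters, the
#' population profile, PSA distributions, and the registry of documented
#' synthetic defaults for unpublished inputs. Every numeric value carries
#' a provenance flag (`"paper"` for values printed in the source tables,
#' `"default"` for the registry's synthetic stand-ins), exposed in
#' `config$provenance`.
#'
#' @return A list of class `cea_config`.
#' @export
#' @examples
#' cfg <- default_parameter_set()
#' cfg$mortality$rr_per_haq_unit
default_parameter_set <- function() {
  registry <- defaults_registry()
  response <- default_response_table()
  cfg <- structure(
    list(
      settings = model_settings(),
      strategies = default_strategies(),
      response = response,
      costs = list(
        drug_unit_costs = default_drug_costs(),
        iv_administration_cost = 232.80,
        iv_administration_owsa_pivot = 214.54,
        monitoring_item_costs = default_monitoring_costs(),
        monitoring_schedule = list(
          year1_panels_per_cycle = 2, # quarterly visits in year 1
          later_panels_per_cycle = 1,
          baseline_chest_xray = TRUE,
          palliation_gp_visits_per_cycle = 1
        ),
        haq_band_costs = registry$haq_band_costs,
        mtx_cost_zero = TRUE
      ),
      utility = list(
        baseline_utility = 0.38,
        front_load_fraction = 0.8,
        front_load_week = 4,
        continuation_gain_fraction = registry$continuation_gain_fraction,
        bansback_coefficient = -0.2102,
        rebound_fraction = 1.0,
        haq_progression_on_biologic = registry$haq_progression[["biologic"]],
        haq_progression_conventional = registry$haq_progression[["conventional"]],
        haq_progression_palliative = registry$haq_progression[["palliative"]],
        haq_max = 3,
        utility_floor = 0,
        utility_ceiling = 1,
        response_gain_explicit = NULL # derived from HAQ changes when NULL
      ),
      mortality = list(
        life_table = make_synthetic_life_table(),
        rr_per_haq_unit = 1.330,
        rr_ci = c(1.099, 1.610),
        enabled = TRUE
      ),
      population = list(
        mean_age = 52.165,
        proportion_female = 1506 / 1821,
        mean_weight_kg = 81.4,
        weight_model = "fixed", # or "cdf" for expected-vials costing
        weight_cdf = make_weight_cdf(),
        baseline_haq = 1.624,
        n_prior_dmards = 2.258,
        disease_duration = 6.557
      ),
      psa = list(
        n_draws = 1000,
        response_logodds_sd = 0.15,
        parameters = default_psa_parameters()
      ),
      defaults = registry
    ),
    class = "cea_config"
  )
  cfg$provenance <- build_provenance(cfg)
  validate_config(cfg)
  cfg
}

# PSA distributions: normal parameters are (mean, SE) with SE derived
# from printed 95% CIs as (upper - lower) / (2 * 1.96); the mortality RR
# is log-normal with location ln(point estimate) and scale from the CI.
default_psa_parameters <- function() {
  ci_se <- function(lo, hi) (hi - lo) / (2 * 1.96)
  tibble::tribble(
    ~parameter, ~family, ~p1, ~p2,
    "mortality_rr", "lognormal", log(1.330), (log(1.610) - log(1.099)) / (2 * 1.96),
    "age", "normal", 52.165, ci_se(51.893, 52.4378),
    "gender_female", "beta", 1506, 1821 - 1506,
    "baseline_haq", "normal", 1.624, ci_se(1.610, 1.638),
    "n_prior_dmards", "normal", 2.258, ci_se(2.207, 2.308),
    "disease_duration", "normal", 6.557, ci_se(6.351, 6.763),
    "anti_ccp_positive", "normal", 1.676, ci_se(1.611, 1.741),
    "anti_ccp_negative", "normal", 1.621, ci_se(1.606, 1.635),
    "utility_weight", "normal", 0.380, ci_se(0.372, 0.388),
    "weight", "empirical_cdf", NA, NA
  )
}

build_provenance <- function(cfg) {
  prov <- list()
  add <- function(parameter, value, source) {
    prov[[length(prov) + 1]] <<- tibble(
      parameter = parameter, value = as.numeric(value), source = source
    )
  }
  r <- cfg$response
  for (i in seq_len(nrow(r))) {
    for (cat in c("acr20", "acr50", "acr70")) {
      add(
        sprintf("response/%s/%dmo/%s", r$strategy[i], r$timepoint_months[i], cat),
        r[[cat]][i], r$source[i]
      )
    }
  }
  d <- cfg$costs$drug_unit_costs
  for (i in seq_len(nrow(d))) add(sprintf("costs/drug/%s", d$drug[i]), d$cost[i], "paper")
  m <- cfg$costs$monitoring_item_costs
  for (i in seq_len(nrow(m))) add(sprintf("costs/monitoring/%s", m$item[i]), m$cost[i], "paper")
  add("costs/iv_administration", cfg$costs$iv_administration_cost, "paper")
  add("mortality/rr_per_haq_unit", cfg$mortality$rr_per_haq_unit, "paper")
  add("mortality/rr_ci_lower", cfg$mortality$rr_ci[1], "paper")
  add("mortality/rr_ci_upper", cfg$mortality$rr_ci[2], "paper")
  add("utility/baseline_utility", cfg$utility$baseline_utility, "paper")
  add("utility/bansback_coefficient", cfg$utility$bansback_coefficient, "paper")
  add("utility/front_load_fraction", cfg$utility$front_load_fraction, "paper")
  add("utility/front_load_week", cfg$utility$front_load_week, "paper")
  add("utility/rebound_fraction", cfg$utility$rebound_fraction, "paper")
  for (p in c("mean_age", "proportion_female", "mean_weight_kg", "baseline_haq",
              "n_prior_dmards", "disease_duration")) {
    add(sprintf("population/%s", p), cfg$population[[p]], "paper")
  }
  for (p in c("horizon_years", "response_assessment_months",
              "discount_rate_costs", "discount_rate_outcomes",
              "inflation_rate", "cost_year", "wtp_threshold")) {
    add(sprintf("settings/%s", p), cfg$settings[[p]], "paper")
  }
  add("strategy/median_duration_months", 37, "paper")
  add("psa/n_draws", cfg$psa$n_draws, "paper")
  # registry defaults
  reg <- cfg$defaults
  fr <- reg$followup_response_tables
  for (i in seq_len(nrow(fr))) {
    for (cat in c("acr20", "acr50", "acr70")) {
      add(sprintf("defaults/followup_response/%s/%s", fr$drug[i], cat), fr[[cat]][i], "default")
    }
  }
  fd <- reg$followup_median_duration_months
  for (i in seq_len(nrow(fd))) {
    add(sprintf("defaults/followup_duration/%s", fd$drug[i]), fd$median_months[i], "default")
  }
  for (nm in names(reg$haq_change_by_acr_category)) {
    add(sprintf("defaults/haq_change/%s", nm), reg$haq_change_by_acr_category[[nm]], "default")
  }
  hb <- reg$haq_band_costs
  for (i in seq_len(nrow(hb))) {
    add(sprintf("defaults/haq_band_cost/%g-%g", hb$band_lower[i], hb$band_upper[i]),
        hb$cost_per_year[i], "default")
  }
  add("defaults/continuation_gain_fraction", reg$continuation_gain_fraction, "default")
  add("defaults/discontinuation_split", reg$discontinuation_split, "default")
  for (nm in names(reg$haq_progression)) {
    add(sprintf("defaults/haq_progression/%s", nm), reg$haq_progression[[nm]], "default")
  }
  add("psa/response_logodds_sd", cfg$psa$response_logodds_sd, "default")
  dplyr::bind_rows(prov)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration: settings
#' bounds, response fractions in \[0, 1\] (with a warning, not an error,
#' for non-monotone cumulative ACR rows, which occur in published tables
#' and are clamped downstream), non-negative costs, utility and HAQ
#' bounds, life-table validity, and follow-up sequences ending in
#' palliation.
#'
#' @param config A `cea_config`.
#' @return `config`, invisibly; errors describe the offending value.
#' @export
validate_config <- function(config) {
  required <- c("settings", "strategies", "response", "costs", "utility",
                "mortality", "population", "psa", "defaults")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort(sprintf("configuration is missing required section(s): %s",
                  paste(missing, collapse = ", ")))
  }
  validate_settings(config$settings)
  r <- config$response
  vals <- unlist(r[c("acr20", "acr50", "acr70")])
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    abort("response fractions must be in [0, 1]")
  }
  bad <- r$acr70 > r$acr50 | r$acr50 > r$acr20
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf(
      "non-monotone cumulative ACR fractions for: %s (will be clamped downstream)",
      paste(unique(r$strategy[which(bad)]), collapse = ", ")
    ))
  }
  for (s in config$strategies) {
    if (utils::tail(s$followup_sequence, 1) != "palliation") {
      abort(sprintf("strategy '%s': followup_sequence must end with 'palliation'", s$name))
    }
    if (s$median_duration_months <= 0) {
      abort(sprintf("strategy '%s': median_duration_months must be positive", s$name))
    }
  }
  if (any(config$costs$drug_unit_costs$cost < 0)) abort("drug costs must be non-negative")
  if (config$costs$iv_administration_cost < 0) abort("iv_administration_cost must be non-negative")
  u <- config$utility
  for (f in c("front_load_fraction", "continuation_gain_fraction", "rebound_fraction")) {
    if (u[[f]] < 0 || u[[f]] > 1) abort(sprintf("%s must be in [0, 1], got %s", f, u[[f]]))
  }
  if (u$baseline_utility > u$utility_ceiling) abort("baseline_utility above utility ceiling")
  mt <- config$mortality
  if (any(mt$life_table$qx < 0 | mt$life_table$qx > 1)) {
    abort("life-table probabilities must be in [0, 1]")
  }
  if (mt$rr_per_haq_unit <= 0) abort("rr_per_haq_unit must be positive")
  p <- config$population
  if (p$proportion_female < 0 || p$proportion_female > 1) {
    abort("proportion_female must be in [0, 1]")
  }
  if (p$baseline_haq < 0 || p$baseline_haq > 3) abort("baseline_haq must be in [0, 3]")
  psa <- config$psa$parameters
  if (any(psa$p2[psa$family %in% c("normal", "lognormal")] <= 0, na.rm = TRUE)) {
    abort("normal/lognormal PSA scale parameters must be positive")
  }
  if (any(psa$p1[psa$family == "beta"] <= 0) || any(psa$p2[psa$family == "beta"] <= 0)) {
    abort("beta PSA shape parameters must be positive")
  }
  invisible(config)
}

#' @export
print.cea_config <- function(x, ...) {
  cat("<cea_config>\n")
  cat(sprintf("  horizon: %g years, assessment at %d months, discount %g%%/%g%% (costs/outcomes)\n",
              x$settings$horizon_years, x$settings$response_assessment_months,
              100 * x$settings$discount_rate_costs, 100 * x$settings$discount_rate_outcomes))
  cat(sprintf("  strategies: %s\n", paste(names(x$strategies), collapse = ", ")))
  cat(sprintf("  provenance: %d paper-flagged, %d default-flagged values\n",
              sum(x$provenance$source == "paper"), sum(x$provenance$source == "default")))
  invisible(x)
}
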