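# Structured-config (YAML) serialization of a cea_config. Tibbles are
# written column-wise; the weight distribution is written parametrically
# (its quantile/cdf closures are rebuilt on load); the provenance table is
# derived, so it is recomputed on load rather than stored.

tbl_to_list <- function(tb) lapply(as.list(tb), function(col) unname(col))
list_to_tbl <- function(lst) as_tibble(lapply(lst, unlist_preserving_na))

unlist_preserving_na <- function(x) {
  if (is.list(x)) x <- unlist(lapply(x, function(v) if (is.null(v)) NA else v))
  x
}

config_schema <- function() {
  list(
    settings = c(
      "horizon_years", "response_assessment_months", "cycle_months_after_year1",
      "discount_rate_costs", "discount_rate_outcomes", "inflation_rate",
      "cost_year", "wtp_threshold", "costing_method", "perspective",
      "half_cycle_correction"
    ),
    strategies = NULL, # named list, validated via constructor
    response = c("strategy", "timepoint_months", "acr20", "acr50", "acr70", "source"),
    costs = c(
      "drug_unit_costs", "iv_administration_cost", "iv_administration_owsa_pivot",
      "monitoring_item_costs", "monitoring_schedule", "haq_band_costs", "mtx_cost_zero"
    ),
    utility = c(
      "baseline_utility", "response_gain_explicit", "front_load_fraction",
      "front_load_week", "continuation_gain_fraction", "bansback_coefficient",
      "rebound_fraction", "haq_progression_on_biologic",
      "haq_progression_conventional", "haq_progression_palliative",
      "haq_max", "utility_floor", "utility_ceiling"
    ),
    mortality = c("life_table", "rr_per_haq_unit", "rr_ci", "enabled"),
    population = c(
      "mean_age", "proportion_female", "mean_weight_kg", "weight_model",
      "weight_cdf", "baseline_haq", "n_prior_dmards", "disease_duration"
    ),
    psa = c("n_draws", "response_logodds_sd", "parameters"),
    defaults = c(
      "followup_response_tables", "followup_median_duration_months",
      "followup_daily_dose_mg", "discontinuation_split",
      "haq_change_by_acr_category", "haq_band_costs",
      "continuation_gain_fraction", "haq_progression", "provenance", "rationale"
    )
  )
}

strategy_to_list <- function(s) {
  r <- s$regimen
  list(
    name = s$name, drug = s$drug,
    with_methotrexate = s$with_methotrexate,
    median_duration_months = s$median_duration_months,
    followup_sequence = s$followup_sequence,
    regimen = list(
      loading_weeks = unname(r$loading_doses$week),
      loading_doses_mg = unname(r$loading_doses$dose_mg),
      maintenance_dose_mg = r$maintenance_dose_mg,
      mg_per_kg = r$mg_per_kg,
      maintenance_interval_weeks = r$maintenance_interval_weeks,
      maintenance_start_week = r$maintenance_start_week,
      route = r$route
    )
  )
}

list_to_strategy <- function(l) {
  rg <- l$regimen
  loading <- NULL
  if (length(rg$loading_weeks) > 0) {
    loading <- tibble(
      week = unlist_preserving_na(rg$loading_weeks),
      dose_mg = as.numeric(unlist_preserving_na(rg$loading_doses_mg))
    )
  }
  treatment_strategy(
    name = l$name, drug = l$drug,
    regimen = regimen(
      loading_doses = loading,
      maintenance_dose_mg = rg$maintenance_dose_mg,
      mg_per_kg = rg$mg_per_kg,
      maintenance_interval_weeks = rg$maintenance_interval_weeks,
      maintenance_start_week = rg$maintenance_start_week,
      route = rg$route
    ),
    with_methotrexate = l$with_methotrexate,
    median_duration_months = l$median_duration_months,
    followup_sequence = unlist(l$followup_sequence)
  )
}

#' Write a model configuration to a structured text file
#'
#' @param config A `cea_config`.
#' @param path Output YAML file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  out <- list(
    settings = config$settings,
    strategies = lapply(config$strategies, strategy_to_list),
    response = tbl_to_list(config$response),
    costs = list(
      drug_unit_costs = tbl_to_list(config$costs$drug_unit_costs),
      iv_administration_cost = config$costs$iv_administration_cost,
      iv_administration_owsa_pivot = config$costs$iv_administration_owsa_pivot,
      monitoring_item_costs = tbl_to_list(config$costs$monitoring_item_costs),
      monitoring_schedule = config$costs$monitoring_schedule,
      haq_band_costs = tbl_to_list(config$costs$haq_band_costs),
      mtx_cost_zero = config$costs$mtx_cost_zero
    ),
    utility = config$utility,
    mortality = list(
      life_table = tbl_to_list(config$mortality$life_table),
      rr_per_haq_unit = config$mortality$rr_per_haq_unit,
      rr_ci = config$mortality$rr_ci,
      enabled = config$mortality$enabled
    ),
    population = local({
      p <- config$population
      p$weight_cdf <- list(
        median_kg = p$weight_cdf$median_kg,
        spread_kg = p$weight_cdf$spread_kg
      )
      p
    }),
    psa = list(
      n_draws = config$psa$n_draws,
      response_logodds_sd = config$psa$response_logodds_sd,
      parameters = tbl_to_list(config$psa$parameters)
    ),
    defaults = list(
      followup_response_tables = tbl_to_list(config$defaults$followup_response_tables),
      followup_median_duration_months = tbl_to_list(config$defaults$followup_median_duration_months),
      followup_daily_dose_mg = tbl_to_list(config$defaults$followup_daily_dose_mg),
      discontinuation_split = config$defaults$discontinuation_split,
      haq_change_by_acr_category = as.list(config$defaults$haq_change_by_acr_category),
      haq_band_costs = tbl_to_list(config$defaults$haq_band_costs),
      continuation_gain_fraction = config$defaults$continuation_gain_fraction,
      haq_progression = as.list(config$defaults$haq_progression),
      provenance = config$defaults$provenance,
      rationale = as.list(config$defaults$rationale)
    )
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Load and validate a model configuration
#'
#' Reads a structured configuration written by [write_model_config()] (or
#' edited by hand), rejects unknown keys, rebuilds derived objects (weight
#' distribution closures, provenance table) and validates every
#' invariant.
#'
#' @param path YAML configuration file.
#' @return A validated `cea_config`.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  missing <- setdiff(names(schema), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("schema error: missing required section(s): %s",
                  paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0) {
    abort(sprintf("schema error: unknown section(s): %s", paste(unknown, collapse = ", ")))
  }
  for (sec in names(schema)) {
    keys <- schema[[sec]]
    if (is.null(keys)) next
    miss <- setdiff(keys, c(names(raw[[sec]]), "response_gain_explicit",
                            "iv_administration_owsa_pivot"))
    if (length(miss) > 0) {
      abort(sprintf("schema error in section '%s': missing field(s): %s",
                    sec, paste(miss, collapse = ", ")))
    }
    unk <- setdiff(names(raw[[sec]]), keys)
    if (length(unk) > 0) {
      abort(sprintf("schema error in section '%s': unknown field(s): %s",
                    sec, paste(unk, collapse = ", ")))
    }
  }
  for (s in raw$strategies) {
    need <- c("name", "drug", "with_methotrexate", "median_duration_months",
              "followup_sequence", "regimen")
    miss <- setdiff(need, names(s))
    if (length(miss) > 0) {
      abort(sprintf("schema error in strategy '%s': missing field(s): %s",
                    s$name %||% "?", paste(miss, collapse = ", ")))
    }
  }
  settings <- raw$settings
  settings$costing_method <- match.arg(settings$costing_method, c("per_unit", "per_mg"))
  settings$perspective <- match.arg(settings$perspective, c("payer", "societal"))
  cfg <- structure(
    list(
      settings = settings,
      strategies = lapply(raw$strategies, list_to_strategy),
      response = list_to_tbl(raw$response),
      costs = list(
        drug_unit_costs = list_to_tbl(raw$costs$drug_unit_costs),
        iv_administration_cost = raw$costs$iv_administration_cost,
        iv_administration_owsa_pivot = raw$costs$iv_administration_owsa_pivot %||% 214.54,
        monitoring_item_costs = list_to_tbl(raw$costs$monitoring_item_costs),
        monitoring_schedule = raw$costs$monitoring_schedule,
        haq_band_costs = list_to_tbl(raw$costs$haq_band_costs),
        mtx_cost_zero = raw$costs$mtx_cost_zero
      ),
      utility = local({
        u <- raw$utility
        if (!"response_gain_explicit" %in% names(u)) {
          u <- c(u, list(response_gain_explicit = NULL))
        }
        u
      }),
      mortality = list(
        life_table = list_to_tbl(raw$mortality$life_table),
        rr_per_haq_unit = raw$mortality$rr_per_haq_unit,
        rr_ci = unlist(raw$mortality$rr_ci),
        enabled = raw$mortality$enabled
      ),
      population = local({
        p <- raw$population
        p$weight_cdf <- make_weight_cdf(
          median_kg = p$weight_cdf$median_kg,
          spread_kg = p$weight_cdf$spread_kg
        )
        p
      }),
      psa = list(
        n_draws = raw$psa$n_draws,
        response_logodds_sd = raw$psa$response_logodds_sd,
        parameters = list_to_tbl(raw$psa$parameters)
      ),
      defaults = structure(
        list(
          followup_response_tables = list_to_tbl(raw$defaults$followup_response_tables),
          followup_median_duration_months = list_to_tbl(raw$defaults$followup_median_duration_months),
          followup_daily_dose_mg = list_to_tbl(raw$defaults$followup_daily_dose_mg),
          discontinuation_split = raw$defaults$discontinuation_split,
          haq_change_by_acr_category = unlist(raw$defaults$haq_change_by_acr_category),
          haq_band_costs = list_to_tbl(raw$defaults$haq_band_costs),
          continuation_gain_fraction = raw$defaults$continuation_gain_fraction,
          haq_progression = unlist(raw$defaults$haq_progression),
          provenance = raw$defaults$provenance,
          rationale = unlist(raw$defaults$rationale)
        ),
        class = "cea_defaults_registry"
      )
    ),
    class = "cea_config"
  )
  names(cfg$strategies) <- vapply(cfg$strategies, function(s) s$name, character(1))
  cfg$provenance <- build_provenance(cfg)
  validate_config(cfg)
  cfg
}
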