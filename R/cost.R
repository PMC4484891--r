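#' Dose events of a regimen inside a week window
#'
#' Enumerates the loading doses and the maintenance doses
#' (`maintenance_start_week + k * interval`) that fall in the half-open
#' window `[start_week, end_week)`. Weight-based regimens return
#' `dose_mg = NA` for events whose dose is `mg_per_kg * weight`; the
#' costing layer resolves them.
#'
#' @param regimen A [regimen()].
#' @param start_week,end_week Window bounds in weeks, `start < end`.
#' @return Tibble with `week`, `dose_mg`, `type` (`"loading"`/
#'   `"maintenance"`).
#' @export
#' @examples
#' r <- default_strategies()[["CZP+MTX"]]$regimen
#' nrow(doses_in_window(r, 0, 26)) # 13
doses_in_window <- function(regimen, start_week, end_week) {
  mk <- function(week, dose_mg, type) {
    tibble::new_tibble(
      list(week = week, dose_mg = dose_mg, type = type), nrow = length(week)
    )
  }
  if (start_week >= end_week) return(mk(numeric(), numeric(), character()))
  keep <- regimen$loading_doses$week >= start_week & regimen$loading_doses$week < end_week
  lw <- regimen$loading_doses$week[keep]
  ldose <- regimen$loading_doses$dose_mg[keep]
  s0 <- regimen$maintenance_start_week
  iv <- regimen$maintenance_interval_weeks
  k_min <- max(0, ceiling((start_week - s0) / iv))
  k_max <- floor((end_week - s0) / iv - 1e-9)
  weeks <- if (k_max >= k_min) s0 + (k_min:k_max) * iv else numeric()
  weeks <- weeks[weeks >= start_week & weeks < end_week]
  week <- c(lw, weeks)
  dose <- c(ldose, rep(regimen$maintenance_dose_mg %||% NA_real_, length(weeks)))
  type <- c(rep("loading", length(lw)), rep("maintenance", length(weeks)))
  o <- order(week)
  mk(week[o], dose[o], type[o])
}

#' Weight-based dose
#'
#' @param mg_per_kg Dose per kilogram (> 0).
#' @param weight_kg Body weight in kg (> 0).
#' @return Dose in mg.
#' @export
weight_based_dose <- function(mg_per_kg, weight_kg) {
  if (mg_per_kg <= 0) abort("mg_per_kg must be positive")
  if (weight_kg <= 0) abort("weight_kg must be positive")
  mg_per_kg * weight_kg
}

#' Units dispensed for a dose
#'
#' Under per-unit costing the smallest whole number of vials/syringes
#' covering the dose is dispensed and the remainder wasted; under per-mg
#' costing the exact fractional unit count is charged.
#'
#' @param dose_mg Dose in mg.
#' @param unit_strength_mg Strength of one unit in mg (> 0).
#' @param method `"per_unit"` or `"per_mg"`.
#' @return Unit count (integer under `per_unit`).
#' @export
units_dispensed <- function(dose_mg, unit_strength_mg,
                            method = c("per_unit", "per_mg")) {
  method <- match.arg(method)
  if (unit_strength_mg <= 0) abort("unit_strength_mg must be positive")
  if (method == "per_unit") ceiling(dose_mg / unit_strength_mg) else dose_mg / unit_strength_mg
}

# Expected units dispensed for a weight-based dose under a weight CDF:
# E[ceil(mg_per_kg * W / strength)] = sum_{j >= 0} P(W > j * strength / mg_per_kg).
expected_units_weight_cdf <- function(mg_per_kg, unit_strength_mg, weight_cdf,
                                      method = "per_unit") {
  if (method == "per_mg") {
    mean_w <- weight_cdf$median_kg * exp(weight_cdf$sdlog^2 / 2)
    return(mg_per_kg * mean_w / unit_strength_mg)
  }
  j <- 0:199 # covers weights up to ~200 units; tail mass is negligible
  sum(1 - weight_cdf$cdf(j * unit_strength_mg / mg_per_kg))
}

drug_unit_price <- function(drug, costs) {
  row <- costs$drug_unit_costs[costs$drug_unit_costs$drug == drug, ]
  if (nrow(row) == 0) abort(sprintf("unknown drug '%s' in cost table", drug))
  row
}

#' Drug acquisition cost of a strategy over a cycle window
#'
#' Sums dispensed-unit costs over the regimen's dose events in the
#' half-open week window. Weight-based doses use either the fixed cohort
#' weight or the expected unit count under the weight distribution
#' (probability mass of patients needing each vial count). Background
#' methotrexate is costed at zero under the base-case assumption
#' (`mtx_cost_zero`), or at its pack price otherwise.
#'
#' @param strategy A [treatment_strategy()].
#' @param start_week,end_week Cycle window in weeks.
#' @param costs Cost inputs (see [default_parameter_set()]`$costs`).
#' @param weight_model List: `list(type = "fixed", weight_kg = 81.4)` or
#'   `list(type = "cdf", cdf = make_weight_cdf())`.
#' @param settings Model settings (costing method).
#' @return Cost in euro.
#' @export
cycle_drug_cost <- function(strategy, start_week, end_week, costs,
                            weight_model, settings) {
  events <- doses_in_window(strategy$regimen, start_week, end_week)
  price <- drug_unit_price(strategy$drug, costs)
  unit_cost <- price$cost / (price$units_per_pack %||% 1)
  mgkg <- strategy$regimen$mg_per_kg
  total <- 0
  if (nrow(events) > 0) {
    dose <- events$dose_mg
    wb <- is.na(dose) # weight-based events
    if (any(wb)) {
      if (weight_model$type == "cdf") {
        u_wb <- expected_units_weight_cdf(
          mgkg, price$unit_strength_mg, weight_model$cdf, settings$costing_method
        )
        total <- total + sum(wb) * u_wb * unit_cost
        dose <- dose[!wb]
      } else {
        dose[wb] <- weight_based_dose(mgkg, weight_model$weight_kg)
      }
    }
    if (length(dose) > 0) {
      units <- if (settings$costing_method == "per_unit") {
        ceiling(dose / price$unit_strength_mg)
      } else {
        dose / price$unit_strength_mg
      }
      total <- total + sum(units) * unit_cost
    }
  }
  total + mtx_cotherapy_cost(strategy, start_week, end_week, costs)
}

# Background methotrexate cost over a window: zero under the base-case
# assumption, otherwise 15 mg weekly = 5 x 3 mg tablets per week.
mtx_cotherapy_cost <- function(strategy, start_week, end_week, costs) {
  if (!isTRUE(strategy$with_methotrexate) || isTRUE(costs$mtx_cost_zero)) {
    return(0)
  }
  mtx <- drug_unit_price("MTX", costs)
  (end_week - start_week) * 5 * mtx$cost / mtx$units_per_pack
}

#' Administration and monitoring cost over a cycle window
#'
#' Intravenous strategies incur the day-hospital administration cost per
#' infusion event in the window; subcutaneous and oral routes add no
#' administration cost. Monitoring follows the configured schedule: a
#' panel (rheumatologist visit, complete blood count, sedimentation rate,
#' clinical chemistry, urinalysis) repeated per cycle — twice per cycle in
#' year one (quarterly visits), once thereafter — plus a baseline chest
#' X-ray. The schedule is identical across strategies, so it cancels in
#' incremental comparisons.
#'
#' @param strategy A [treatment_strategy()].
#' @param start_week,end_week Cycle window in weeks.
#' @param costs Cost inputs.
#' @return Cost in euro.
#' @export
administration_and_monitoring_cost <- function(strategy, start_week, end_week, costs) {
  admin <- 0
  if (strategy$regimen$route == "intravenous") {
    n_inf <- nrow(doses_in_window(strategy$regimen, start_week, end_week))
    admin <- n_inf * costs$iv_administration_cost
  }
  admin + monitoring_cost_window(start_week, end_week, costs)
}

monitoring_panel_cost <- function(costs) {
  items <- c(
    "rheumatologist", "complete blood count", "sedimentation rate",
    "clinical chemistry profile", "urinalysis"
  )
  m <- costs$monitoring_item_costs
  sum(m$cost[match(items, m$item)])
}

monitoring_cost_window <- function(start_week, end_week, costs) {
  sched <- costs$monitoring_schedule
  panels <- if (start_week < WEEKS_PER_YEAR) {
    sched$year1_panels_per_cycle
  } else {
    sched$later_panels_per_cycle
  }
  total <- panels * monitoring_panel_cost(costs)
  if (start_week == 0 && isTRUE(sched$baseline_chest_xray)) {
    m <- costs$monitoring_item_costs
    total <- total + m$cost[m$item == "chest x-ray"]
  }
  total
}

# Per-cycle drug cost of a follow-up conventional DMARD line: steady-state
# daily dosing costed per mg from pack prices (pack-to-regimen conversion;
# oral packs are consumed over time so unit wastage is negligible).
followup_line_cycle_cost <- function(drug, cycle_months, costs, defaults) {
  if (drug == "palliation") {
    m <- costs$monitoring_item_costs
    gp <- costs$monitoring_schedule$palliation_gp_visits_per_cycle %||% 0
    return(gp * m$cost[m$item == "primary care physician"])
  }
  price <- drug_unit_price(drug, costs)
  dd <- defaults$followup_daily_dose_mg
  daily <- dd$daily_dose_mg[dd$drug == drug]
  if (length(daily) == 0) abort(sprintf("no daily dose configured for '%s'", drug))
  cost_per_mg <- price$cost / (price$units_per_pack * price$unit_strength_mg)
  days <- cycle_months * WEEKS_PER_MONTH * 7
  # monitoring for follow-up lines is added by the engine via the shared
  # schedule; only drug cost is returned here
  daily * cost_per_mg * days
}

#' Inflate then discount a cost
#'
#' Costs incurred `years_from_start` into the model are inflated from the
#' cost year at the annual inflation rate and discounted back at the cost
#' discount rate: `cost * (1 + inflation)^t * (1 + discount)^(-t)`.
#'
#' @param cost Cost in euro at the cost year.
#' @param years_from_start Years since model start (>= 0).
#' @param settings Model settings.
#' @return Present-value cost in euro.
#' @export
inflate_then_discount <- function(cost, years_from_start, settings) {
  if (any(years_from_start < 0)) abort("years_from_start must be non-negative")
  cost * (1 + settings$inflation_rate)^years_from_start *
    (1 + settings$discount_rate_costs)^(-years_from_start)
}

#' Accumulate discounted costs over a cohort trace
#'
#' Occupancy-weighted sum of per-state per-cycle costs with inflation and
#' discounting applied at each cycle's start time (midpoint under the
#' half-cycle correction). The death state costs zero. When a HAQ-band
#' cost table is supplied, each living state additionally accrues the
#' annual resource cost of its current mean HAQ band, scaled by cycle
#' length.
#'
#' @param trace Cohort trace (long tibble with `cycle`, `time_years`,
#'   `cycle_years`, `state`, `occupancy`, `haq`).
#' @param cost_table Tibble `cycle`, `state`, `cost` (undiscounted euro
#'   per cycle per occupant).
#' @param settings Model settings.
#' @param haq_band_costs Optional HAQ-band cost tibble
#'   (see [defaults_registry()]).
#' @return Total discounted cost in euro.
#' @export
accumulate_costs <- function(trace, cost_table, settings, haq_band_costs = NULL) {
  joined <- left_join(trace, cost_table, by = c("cycle", "state"))
  if (any(is.na(joined$cost) & joined$state != "death")) {
    abort("cost table does not cover every living (cycle, state) pair in the trace")
  }
  cost <- ifelse(joined$state == "death", 0, joined$cost)
  if (!is.null(haq_band_costs)) {
    band <- ifelse(joined$state == "death", 0,
      haq_band_cost(joined$haq, haq_band_costs) * joined$cycle_years
    )
    cost <- cost + band
  }
  t_disc <- joined$time_years +
    if (isTRUE(settings$half_cycle_correction)) joined$cycle_years / 2 else 0
  sum(joined$occupancy * inflate_then_discount(cost, t_disc, settings))
}
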