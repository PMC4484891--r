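# Per-(cycle, state) undiscounted cost table for a strategy: drug
# acquisition, administration and monitoring. HAQ-band resource costs are
# added at accumulation time from the trace's mean HAQ.
strategy_cost_table <- function(config, strategy, space = state_space(strategy),
                                grid = cycle_grid(config$settings)) {
  cost <- strategy_cost_matrix(config, strategy, space, grid)
  tibble(
    cycle = rep(grid$cycle, times = ncol(cost)),
    state = rep(space$state, each = nrow(grid)),
    cost = as.numeric(cost)
  )
}

# Matrix form (cycles x states) of the undiscounted per-cycle cost table.
strategy_cost_matrix <- function(config, strategy, space = state_space(strategy),
                                 grid = cycle_grid(config$settings)) {
  prep <- strategy_cost_prep(config, strategy, space, grid)
  strategy_cost_apply(prep, config)
}

# Splits the cost table into a part that is invariant to the patient
# weight (monitoring, administration, follow-up lines, fixed-dose drug
# acquisition) and the weight-based first-line dose events, so PSA draws
# only refresh the latter.
strategy_cost_prep <- function(config, strategy, space = state_space(strategy),
                               grid = cycle_grid(config$settings)) {
  S <- nrow(space)
  n_cycles <- nrow(grid)
  static <- matrix(0, n_cycles, S, dimnames = list(NULL, space$state))
  price <- drug_unit_price(strategy$drug, config$costs)
  wb <- !is.null(strategy$regimen$mg_per_kg)
  n_wb_events <- numeric(n_cycles)
  weight_model_fixed <- list(type = "fixed", weight_kg = 1) # placeholder
  firstline_static <- vapply(seq_len(n_cycles), function(ci) {
    adm <- administration_and_monitoring_cost(
      strategy, grid$start_week[ci], grid$end_week[ci], config$costs
    )
    if (wb) {
      n_wb_events[ci] <<- nrow(doses_in_window(
        strategy$regimen, grid$start_week[ci], grid$end_week[ci]
      ))
      adm + mtx_cotherapy_cost(strategy, grid$start_week[ci], grid$end_week[ci],
                               config$costs)
    } else {
      adm + cycle_drug_cost(
        strategy, grid$start_week[ci], grid$end_week[ci],
        config$costs, weight_model_fixed, config$settings
      )
    }
  }, numeric(1))
  static[1, space$type == "entry"] <- firstline_static[1]
  if (n_cycles > 1) {
    for (ci in 2:n_cycles) static[ci, space$type == "responder"] <- firstline_static[ci]
  }
  # follow-up lines: steady-state per-cycle cost by cycle length, plus
  # the shared monitoring schedule; both depend only on the cycle length
  # and window position, so compute per distinct cycle
  fl <- space[space$type %in% c("assess", "cont"), ]
  for (drug in unique(fl$drug)) {
    cols <- space$state[space$drug %in% drug & space$type %in% c("assess", "cont")]
    line_cost <- vapply(seq_len(n_cycles), function(ci) {
      followup_line_cycle_cost(drug, grid$months[ci], config$costs, config$defaults) +
        monitoring_cost_window(max(grid$start_week[ci], 1), grid$end_week[ci],
                               config$costs)
    }, numeric(1))
    for (col in cols) static[, col] <- line_cost
  }
  pall_col <- space$state[space$type == "palliation"]
  static[, pall_col] <- vapply(seq_len(n_cycles), function(ci) {
    followup_line_cycle_cost("palliation", grid$months[ci], config$costs,
                             config$defaults)
  }, numeric(1))
  list(
    static = static, space = space, n_wb_events = n_wb_events,
    weight_based = wb, mg_per_kg = strategy$regimen$mg_per_kg,
    unit_strength_mg = price$unit_strength_mg,
    unit_cost = price$cost / (price$units_per_pack %||% 1)
  )
}

strategy_cost_apply <- function(prep, config) {
  cost <- prep$static
  if (prep$weight_based) {
    units <- if (config$population$weight_model == "cdf") {
      expected_units_weight_cdf(
        prep$mg_per_kg, prep$unit_strength_mg, config$population$weight_cdf,
        config$settings$costing_method
      )
    } else {
      units_dispensed(
        weight_based_dose(prep$mg_per_kg, config$population$mean_weight_kg),
        prep$unit_strength_mg, config$settings$costing_method
      )
    }
    per_event <- units * prep$unit_cost
    cost[1, prep$space$type == "entry"] <-
      cost[1, prep$space$type == "entry"] + prep$n_wb_events[1] * per_event
    resp <- prep$space$type == "responder"
    if (nrow(cost) > 1) {
      for (ci in 2:nrow(cost)) {
        cost[ci, resp] <- cost[ci, resp] + prep$n_wb_events[ci] * per_event
      }
    }
  }
  cost
}

#' Evaluate a strategy: discounted lifetime cost and QALYs
#'
#' Runs the cohort engine for the strategy, integrates discounted QALYs
#' from the utility trajectory and discounted costs from drug,
#' administration, monitoring and HAQ-band components.
#'
#' @param config A `cea_config`.
#' @param strategy A [treatment_strategy()] or its name.
#' @return One-row tibble: `strategy`, `cost`, `qalys`.
#' @export
evaluate_strategy <- function(config, strategy, engine = NULL, cost_matrix = NULL) {
  if (is.character(strategy)) strategy <- config$strategies[[strategy]]
  ev <- evaluate_strategy_core(config, strategy, engine, cost_matrix)
  tibble(strategy = strategy$name, cost = ev[["cost"]], qalys = ev[["qalys"]])
}

evaluate_strategy_core <- function(config, strategy, engine = NULL,
                                   cost_matrix = NULL) {
  if (is.null(engine)) engine <- make_engine(config, strategy)
  core <- run_cohort_core(engine)
  grid <- engine$grid
  space <- engine$space
  if (is.null(cost_matrix)) {
    cost_matrix <- strategy_cost_matrix(config, strategy, space, grid)
  }
  s <- config$settings
  t_disc <- grid$time_years +
    if (isTRUE(s$half_cycle_correction)) grid$cycle_years / 2 else 0
  # QALYs: occupancy-weighted utility per cycle, discounted at cycle start
  qalys <- sum(
    rowSums(core$occ * core$utility) * grid$cycle_years *
      (1 + s$discount_rate_outcomes)^(-t_disc)
  )
  # costs: explicit per-cycle components plus HAQ-band resource use
  band <- matrix(
    haq_band_cost(core$haq, config$costs$haq_band_costs),
    nrow = nrow(core$haq)
  ) * grid$cycle_years
  band[, space$type == "death"] <- 0
  cost_cycle <- rowSums(core$occ * (cost_matrix + band))
  cost <- sum(
    cost_cycle * (1 + s$inflation_rate)^t_disc *
      (1 + s$discount_rate_costs)^(-t_disc)
  )
  c(cost = cost, qalys = qalys)
}

#' Evaluate several strategies
#'
#' @param config A `cea_config`.
#' @param strategies Character vector of strategy names (default: all in
#'   the configuration) or a list of [treatment_strategy()] objects.
#' @return Tibble with one row per strategy: `strategy`, `cost`, `qalys`.
#' @export
evaluate_strategies <- function(config, strategies = names(config$strategies)) {
  if (is.character(strategies)) strategies <- config$strategies[strategies]
  out <- bind_rows(lapply(strategies, function(s) evaluate_strategy(config, s)))
  class(out) <- c("cea_results", class(out))
  out
}

#' Classify the dominance quadrant of an incremental comparison
#'
#' Signs of (delta cost, delta QALY) of the reference minus the
#' comparator: cheaper and at least as effective (or equally costly and
#' more effective) means the reference dominates; the mirror image means
#' the comparator dominates; equal signs admit an ICER; both zero is
#' equality. Boundary zeros resolve toward weak dominance.
#'
#' @param delta_cost Reference cost minus comparator cost.
#' @param delta_qaly Reference QALYs minus comparator QALYs.
#' @return One of `"reference_dominant"`, `"comparator_dominant"`,
#'   `"icer_defined"`, `"equal"`.
#' @export
classify_dominance <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("equal")
  if (delta_cost <= 0 && delta_qaly >= 0) return("reference_dominant")
  if (delta_cost >= 0 && delta_qaly <= 0) return("comparator_dominant")
  "icer_defined"
}

#' Incremental cost-effectiveness analysis between two strategies
#'
#' @param reference One-row result tibble (or list) with `strategy`,
#'   `cost`, `qalys` for the reference strategy.
#' @param comparator The same for the comparator.
#' @return One-row tibble: `reference`, `comparator`, `delta_cost`,
#'   `delta_qaly`, `icer` (`NA` when dominance applies), `dominance`.
#' @export
#' @examples
#' incremental_analysis(
#'   list(strategy = "A", cost = 140971, qalys = 6.578),
#'   list(strategy = "B", cost = 139148, qalys = 6.430)
#' )
incremental_analysis <- function(reference, comparator) {
  dc <- reference$cost - comparator$cost
  dq <- reference$qalys - comparator$qalys
  dom <- classify_dominance(dc, dq)
  tibble(
    reference = reference$strategy,
    comparator = comparator$strategy,
    delta_cost = dc,
    delta_qaly = dq,
    icer = if (dom == "icer_defined") dc / dq else NA_real_,
    dominance = dom
  )
}

#' Incremental table versus a reference strategy
#'
#' @param results A tibble from [evaluate_strategies()].
#' @param reference Name of the reference strategy (default: first row).
#' @return Tibble with one row per comparator.
#' @export
incremental_table <- function(results, reference = results$strategy[1]) {
  ref <- results[results$strategy == reference, ]
  comps <- results[results$strategy != reference, ]
  out <- bind_rows(lapply(seq_len(nrow(comps)), function(i) {
    incremental_analysis(ref, comps[i, ])
  }))
  class(out) <- c("cea_incremental", class(out))
  out
}

#' One-way sensitivity analysis
#'
#' Re-evaluates the strategies under each named scenario (see
#' [owsa_scenarios()]) and tabulates the incremental results versus the
#' reference strategy.
#'
#' @param config Base `cea_config`.
#' @param scenarios Character vector of registered scenario names.
#' @param strategies Strategy names to evaluate.
#' @param reference Reference strategy name (default: first of
#'   `strategies`).
#' @return Tibble with `scenario` plus the incremental columns.
#' @export
run_owsa <- function(config, scenarios, strategies, reference = strategies[1]) {
  out <- lapply(scenarios, function(sc) {
    cfg <- resolve_scenario(config, sc)
    res <- evaluate_strategies(cfg, strategies)
    mutate(incremental_table(res, reference), scenario = sc, .before = 1)
  })
  out <- bind_rows(out)
  class(out) <- c("cea_owsa", class(out))
  out
}
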