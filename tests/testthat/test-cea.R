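test_that("incremental analysis reproduces printed-mean arithmetic", {
  ref <- list(strategy = "CZP+MTX", cost = 140971, qalys = 6.578)
  comp <- list(strategy = "ADA+MTX q2w", cost = 139148, qalys = 6.430)
  inc <- incremental_analysis(ref, comp)
  expect_equal(inc$delta_cost, 1823)
  expect_equal(inc$delta_qaly, 0.148)
  expect_equal(inc$dominance, "icer_defined")
  expect_equal(inc$icer, 1823 / 0.148, tolerance = 1e-12)

  comp2 <- list(strategy = "ADA+MTX weekly", cost = 164741, qalys = 6.430)
  inc2 <- incremental_analysis(ref, comp2)
  expect_equal(inc2$delta_cost, -23770)
  expect_equal(inc2$delta_qaly, 0.148)
  expect_equal(inc2$dominance, "reference_dominant")
  expect_true(is.na(inc2$icer))

  inc3 <- incremental_analysis(ref, ref)
  expect_equal(inc3$delta_cost, 0)
  expect_equal(inc3$delta_qaly, 0)
  expect_equal(inc3$dominance, "equal")
})

test_that("incremental analysis is antisymmetric", {
  set.seed(3)
  mirror <- c(
    reference_dominant = "comparator_dominant",
    comparator_dominant = "reference_dominant",
    icer_defined = "icer_defined", equal = "equal"
  )
  for (i in 1:20) {
    a <- list(strategy = "A", cost = runif(1, 1e5, 2e5), qalys = runif(1, 4, 8))
    b <- list(strategy = "B", cost = runif(1, 1e5, 2e5), qalys = runif(1, 4, 8))
    ab <- incremental_analysis(a, b)
    ba <- incremental_analysis(b, a)
    expect_equal(ab$delta_cost, -ba$delta_cost)
    expect_equal(ab$delta_qaly, -ba$delta_qaly)
    expect_equal(unname(mirror[ab$dominance]), ba$dominance)
    if (!is.na(ab$icer)) expect_equal(ab$icer, ba$icer)
  }
})

test_that("dominance classification follows the sign quadrants", {
  expect_equal(classify_dominance(-23770, 0.148), "reference_dominant")
  expect_equal(classify_dominance(1823, 0.148), "icer_defined")
  expect_equal(classify_dominance(5, -0.1), "comparator_dominant")
  expect_equal(classify_dominance(0, 0), "equal")
  # boundary zeros resolve toward weak dominance
  expect_equal(classify_dominance(0, 0.1), "reference_dominant")
  expect_equal(classify_dominance(-5, 0), "reference_dominant")
})

test_that("strategy evaluation behaves linearly and degenerately as expected", {
  cfg <- toy_config(horizon_years = 2, mortality_enabled = FALSE)
  # zero gains, zero rebound effect: QALYs = 0.38 x discounted person-time
  cfg0 <- resolve_scenario(cfg, list(utility = list(
    continuation_gain_fraction = 0,
    haq_progression_conventional = 0, haq_progression_palliative = 0,
    response_gain_explicit = NULL
  )))
  cfg0$defaults$haq_change_by_acr_category[] <- 0
  r0 <- evaluate_strategy(cfg0, "CZP+MTX")
  disc_time <- sum(0.5 * 1.035^(-(0:3) / 2))
  expect_equal(r0$qalys, 0.38 * disc_time, tolerance = 1e-10)

  # doubling all unit costs doubles the total cost exactly
  cfg2 <- cfg
  cfg2$costs$drug_unit_costs$cost <- cfg2$costs$drug_unit_costs$cost * 2
  cfg2$costs$iv_administration_cost <- cfg2$costs$iv_administration_cost * 2
  cfg2$costs$monitoring_item_costs$cost <- cfg2$costs$monitoring_item_costs$cost * 2
  cfg2$costs$haq_band_costs$cost_per_year <- cfg2$costs$haq_band_costs$cost_per_year * 2
  r1 <- evaluate_strategy(cfg, "CZP+MTX")
  r2 <- evaluate_strategy(cfg2, "CZP+MTX")
  expect_equal(r2$cost, 2 * r1$cost, tolerance = 1e-10)
  expect_equal(r2$qalys, r1$qalys)
})

test_that("the fast evaluation path agrees with the trace accumulators", {
  cfg <- short_config(10)
  for (nm in c("CZP+MTX", "IFX3+MTX")) {
    fast <- evaluate_strategy(cfg, nm)
    trace <- run_cohort(cfg, nm)
    ct <- seqcea:::strategy_cost_table(cfg, cfg$strategies[[nm]])
    expect_equal(
      fast$cost,
      accumulate_costs(trace, ct, cfg$settings,
                       haq_band_costs = cfg$costs$haq_band_costs),
      tolerance = 1e-10
    )
    expect_equal(
      fast$qalys,
      discounted_qalys(trace, cfg$settings$discount_rate_outcomes, cfg$settings),
      tolerance = 1e-10
    )
  }
})

test_that("response-dominant strategies never lose QALYs, all else equal", {
  cfg <- short_config(10)
  base_row <- cfg$response$strategy == "CZP+MTX" & cfg$response$timepoint_months == 6
  worse <- cfg
  worse$response[base_row, c("acr20", "acr50", "acr70")] <-
    list(0.60, 0.35, 0.15) # dominated by the original (0.772, 0.492, 0.282)
  q_better <- evaluate_strategy(cfg, "CZP+MTX")$qalys
  q_worse <- evaluate_strategy(worse, "CZP+MTX")$qalys
  expect_gte(q_better, q_worse)
})

test_that("with zero gains everywhere all strategies earn identical QALYs", {
  cfg <- short_config(5)
  cfg$defaults$haq_change_by_acr_category[] <- 0
  cfg <- resolve_scenario(cfg, list(utility = list(
    continuation_gain_fraction = 0,
    haq_progression_conventional = 0, haq_progression_palliative = 0
  )))
  # discontinuation timing differs per strategy but utility is flat, and
  # mortality then acts identically on every strategy
  res <- evaluate_strategies(cfg, c("CZP+MTX", "ETA+MTX", "IFX5+MTX"))
  expect_lt(max(res$qalys) - min(res$qalys), 1e-10)
})

test_that("one-way scenarios change only what they claim to change", {
  cfg <- short_config(5)
  strategies <- c("CZP+MTX", "IFX3+MTX")
  tab <- run_owsa(cfg, c("mortality_off", "rebound_50"), strategies)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$scenario, c("mortality_off", "rebound_50"))
  expect_error(run_owsa(cfg, "bogus", strategies), "registered")

  # the mortality scenario differs from base only in the mortality flag
  cfg_m <- resolve_scenario(cfg, "mortality_off")
  expect_false(cfg_m$mortality$enabled)
  expect_equal(cfg_m$response, cfg$response)
  expect_equal(cfg_m$settings, cfg$settings)

  # the 3-month scenario consumes the 3-month response columns
  cfg3 <- resolve_scenario(cfg, "acr_3mo")
  tr3 <- run_cohort(cfg3, "CZP+MTX")
  p3 <- exclusive_response_probabilities(0.711, 0.359, 0.216)
  got <- tr3$occupancy[tr3$cycle == 1 & tr3$state == "acr70"]
  pd <- tr3$occupancy[tr3$cycle == 1 & tr3$state == "death"]
  expect_equal(got, (1 - pd) * p3[["acr70"]], tolerance = 1e-12)

  # IV administration scenarios leave subcutaneous strategies unchanged
  up <- resolve_scenario(cfg, "iv_admin_plus20")
  expect_equal(evaluate_strategy(up, "CZP+MTX"),
               evaluate_strategy(cfg, "CZP+MTX"))
  expect_false(isTRUE(all.equal(evaluate_strategy(up, "IFX3+MTX")$cost,
                                evaluate_strategy(cfg, "IFX3+MTX")$cost)))
})
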