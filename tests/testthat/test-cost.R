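test_that("dose events enumerate loading and maintenance schedules", {
  strat <- base_config()$strategies
  # certolizumab pegol: 400 mg weeks 0/2/4 then 200 mg q2w -> 13 events
  # in the first 26 weeks
  czp <- doses_in_window(strat[["CZP+MTX"]]$regimen, 0, 26)
  expect_equal(nrow(czp), 13)
  expect_equal(czp$week, c(0, 2, 4, seq(6, 24, by = 2)))
  expect_equal(czp$dose_mg, c(400, 400, 400, rep(200, 10)))
  # infliximab: weeks 0, 2, 6, then every 8 weeks -> 0, 2, 6, 14, 22
  ifx <- doses_in_window(strat[["IFX3+MTX"]]$regimen, 0, 26)
  expect_equal(ifx$week, c(0, 2, 6, 14, 22))
  # empty window
  expect_equal(nrow(doses_in_window(strat[["CZP+MTX"]]$regimen, 10, 10)), 0)
  # later windows contain only maintenance doses
  czp2 <- doses_in_window(strat[["CZP+MTX"]]$regimen, 26, 52)
  expect_equal(czp2$week, seq(26, 50, by = 2))
  # etanercept twice weekly: 52 events per 26 weeks
  expect_equal(nrow(doses_in_window(strat[["ETA+MTX"]]$regimen, 0, 26)), 52)
})

test_that("weight-based dosing and unit dispensing follow the costing method", {
  expect_equal(weight_based_dose(3, 81.4), 244.2)
  expect_equal(weight_based_dose(5, 81.4), 407.0)
  expect_error(weight_based_dose(3, 0), "positive")
  expect_equal(units_dispensed(244.2, 100, "per_unit"), 3)
  expect_equal(units_dispensed(244.2, 100, "per_mg"), 2.442)
  expect_equal(units_dispensed(200, 200, "per_unit"), 1)
})

test_that("cycle drug costs reproduce hand-computed unit sums", {
  cfg <- base_config()
  fixed <- list(type = "fixed", weight_kg = 81.4)
  # CZP first 26 weeks: 3 loading x 2 syringes + 10 maintenance x 1 = 16
  czp_cost <- cycle_drug_cost(cfg$strategies[["CZP+MTX"]], 0, 26, cfg$costs,
                              fixed, cfg$settings)
  expect_equal(czp_cost, 16 * 474)
  # one IFX 3 mg/kg infusion at 81.4 kg: 3 vials
  one_inf <- cycle_drug_cost(cfg$strategies[["IFX3+MTX"]], 0, 1, cfg$costs,
                             fixed, cfg$settings)
  expect_equal(one_inf, 3 * 536.28)
  # methotrexate co-therapy adds nothing under the base-case assumption
  mono <- cycle_drug_cost(cfg$strategies[["CZP mono"]], 0, 26, cfg$costs,
                          fixed, cfg$settings)
  expect_equal(czp_cost, mono)
  # ... but is priced when the flag is off
  costs2 <- cfg$costs; costs2$mtx_cost_zero <- FALSE
  with_mtx <- cycle_drug_cost(cfg$strategies[["CZP+MTX"]], 0, 26, costs2,
                              fixed, cfg$settings)
  expect_gt(with_mtx, czp_cost)
  expect_error(
    cycle_drug_cost(
      treatment_strategy("x", "nosuchdrug",
                         cfg$strategies[["CZP+MTX"]]$regimen, FALSE),
      0, 26, cfg$costs, fixed, cfg$settings
    ),
    "unknown drug"
  )
})

test_that("administration costs apply to IV infusions only", {
  cfg <- base_config()
  ifx <- administration_and_monitoring_cost(cfg$strategies[["IFX3+MTX"]],
                                            0, 26, cfg$costs)
  czp <- administration_and_monitoring_cost(cfg$strategies[["CZP+MTX"]],
                                            0, 26, cfg$costs)
  # 5 infusions at the day-hospital price; monitoring is shared
  expect_equal(ifx - czp, 5 * 232.80)
  # one rheumatologist visit plus one complete blood count
  m <- cfg$costs$monitoring_item_costs
  expect_equal(
    m$cost[m$item == "rheumatologist"] + m$cost[m$item == "complete blood count"],
    106.31
  )
})

test_that("inflation and discounting combine multiplicatively", {
  cfg <- base_config()
  expect_equal(inflate_then_discount(100, 0, cfg$settings), 100)
  expect_equal(inflate_then_discount(100, 1, cfg$settings), 100 * 1.03 / 1.035,
               tolerance = 1e-12)
  s0 <- cfg$settings; s0$inflation_rate <- 0
  expect_equal(inflate_then_discount(100, 10, s0), 100 * 1.035^(-10),
               tolerance = 1e-12)
  expect_equal(100 * 1.035^(-10), 70.8919, tolerance = 1e-4)
})

test_that("cost accumulation is occupancy-weighted and geometric in time", {
  cfg <- base_config()
  tr <- tibble::tibble(
    cycle = 0:3, time_years = (0:3) / 2, cycle_years = 0.5,
    state = "acr20", occupancy = 1, haq = 1.624, utility = 0.5
  )
  ct <- tibble::tibble(cycle = 0:3, state = "acr20", cost = 100)
  s0 <- cfg$settings; s0$inflation_rate <- 0; s0$discount_rate_costs <- 0
  expect_equal(accumulate_costs(tr[1:2, ], ct, s0), 200)
  ct0 <- ct; ct0$cost <- 0
  expect_equal(accumulate_costs(tr, ct0, cfg$settings), 0)
  # geometric sum under base rates
  expected <- sum(100 * (1.03 / 1.035)^((0:3) / 2))
  expect_equal(accumulate_costs(tr, ct, cfg$settings), expected, tolerance = 1e-10)
  # HAQ-band costs add the annual band cost scaled by cycle length
  bands <- cfg$costs$haq_band_costs
  with_band <- accumulate_costs(tr, ct, s0, haq_band_costs = bands)
  expect_equal(with_band, 400 + 4 * 0.5 * haq_band_cost(1.624, bands))
  # grid mismatch errors
  expect_error(accumulate_costs(tr, ct[1:2, ], s0), "cover")
})

test_that("per-unit costing never undercuts per-mg costing", {
  cfg <- base_config()
  cfg_mg <- resolve_scenario(cfg, "costing_per_mg")
  fixed <- list(type = "fixed", weight_kg = 81.4)
  grid <- cycle_grid(cfg$settings)
  for (nm in combo_strategies) {
    s <- cfg$strategies[[nm]]
    for (ci in c(1, 2, 5)) {
      pu <- cycle_drug_cost(s, grid$start_week[ci], grid$end_week[ci],
                            cfg$costs, fixed, cfg$settings)
      pm <- cycle_drug_cost(s, grid$start_week[ci], grid$end_week[ci],
                            cfg$costs, fixed, cfg_mg$settings)
      expect_gte(pu, pm - 1e-9)
    }
  }
})

test_that("expected vials under the weight CDF bracket the fixed-weight count", {
  cfg <- base_config()
  w <- cfg$population$weight_cdf
  e_units <- seqcea:::expected_units_weight_cdf(3, 100, w, "per_unit")
  # between the minimum and maximum vial counts over the weight support
  expect_gt(e_units, 1)
  expect_lt(e_units, 10)
  # degenerate distribution at 81.4 kg equals the fixed-weight result
  degenerate <- list(
    median_kg = 81.4, sdlog = 0,
    cdf = function(x) as.numeric(x >= 81.4),
    quantile = function(p) 81.4
  )
  expect_equal(
    seqcea:::expected_units_weight_cdf(3, 100, degenerate, "per_unit"),
    units_dispensed(weight_based_dose(3, 81.4), 100, "per_unit")
  )
  # per-mg expectation uses the distribution mean
  e_mg <- seqcea:::expected_units_weight_cdf(3, 100, w, "per_mg")
  expect_equal(e_mg, 3 * 81.4 * exp(w$sdlog^2 / 2) / 100, tolerance = 1e-9)
})

test_that("discounted total cost is monotone in discount and inflation rates", {
  cfg <- short_config(5)
  s <- cfg$strategies[["CZP+MTX"]]
  cost_at <- function(disc, infl) {
    cfg2 <- resolve_scenario(cfg, list(settings = list(
      discount_rate_costs = disc, inflation_rate = infl
    )))
    evaluate_strategy(cfg2, s)$cost
  }
  expect_gt(cost_at(0, 0.03), cost_at(0.035, 0.03))
  expect_gt(cost_at(0.035, 0.03), cost_at(0.06, 0.03))
  expect_lt(cost_at(0.035, 0), cost_at(0.035, 0.03))
})
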