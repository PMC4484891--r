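test_that("exclusive response probabilities are successive differences", {
  p <- exclusive_response_probabilities(0.772, 0.492, 0.282)
  expect_equal(unname(p), c(0.228, 0.280, 0.210, 0.282), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_equal(
    unname(exclusive_response_probabilities(1, 1, 1)), c(0, 0, 0, 1)
  )
  # non-monotone inputs clamp to zero mass with a warning
  expect_warning(
    pc <- exclusive_response_probabilities(0.5, 0.61, 0.3),
    "clamping"
  )
  expect_true(all(pc >= 0))
  expect_equal(sum(pc), 1)
  expect_equal(pc[["acr20"]], 0)
  # quiet mode suppresses the warning
  expect_silent(exclusive_response_probabilities(0.5, 0.61, 0.3, quiet = TRUE))
})

test_that("median duration maps to a constant-hazard cycle probability", {
  expect_equal(median_to_cycle_discontinuation(37, 37), 0.5)
  expect_equal(median_to_cycle_discontinuation(37, 6), 1 - 2^(-6 / 37),
               tolerance = 1e-12)
  expect_equal(median_to_cycle_discontinuation(37, 6), 0.106315, tolerance = 1e-5)
  expect_lt(median_to_cycle_discontinuation(37, 0.001), 1e-4)
})

test_that("state space is ordered with a single absorbing death state", {
  sp <- state_space(base_config()$strategies[["CZP+MTX"]])
  expect_equal(sp$state[1:4], c("entry", "acr20", "acr50", "acr70"))
  expect_equal(sum(sp$type == "death"), 1)
  expect_equal(sp$state[nrow(sp)], "death")
  expect_equal(nrow(sp), 6 + 2 * 7) # 7 follow-up lines
})

test_that("cycle grid has assessment-length cycles in year one, then 6 months", {
  cfg <- base_config()
  g6 <- cycle_grid(cfg$settings)
  expect_equal(nrow(g6), 90)
  expect_true(all(g6$months == 6))
  s3 <- cfg$settings; s3$response_assessment_months <- 3
  g3 <- cycle_grid(s3)
  expect_equal(nrow(g3), 92)
  expect_equal(g3$months[1:4], rep(3, 4))
  expect_true(all(g3$months[-(1:4)] == 6))
  expect_equal(max(g3$time_years + g3$cycle_years), 45)
})

test_that("transition matrices are row-stochastic with an absorbing death row", {
  cfg <- base_config()
  for (nm in c("CZP+MTX", "IFX3+MTX")) {
    strat <- cfg$strategies[[nm]]
    sp <- state_space(strat)
    for (ci in c(0, 1, 2, 50, 89)) {
      P <- build_transition_matrix(sp, cfg, strat, ci)
      expect_true(all(abs(rowSums(P) - 1) < 1e-12))
      expect_true(all(P >= 0 & P <= 1))
      expect_equal(unname(P["death", "death"]), 1)
      # death is reachable from every living state
      expect_true(all(P[sp$type != "death", "death"] > 0))
    }
  }
})

test_that("zero mortality and zero discontinuation make responder rows identity", {
  cfg <- zero_mortality_config(toy_config())
  strat <- treatment_strategy(
    "CZP+MTX", "CZP", cfg$strategies[["CZP+MTX"]]$regimen,
    with_methotrexate = TRUE, median_duration_months = 1e9,
    followup_sequence = "palliation"
  )
  cfg$strategies <- list("CZP+MTX" = strat)
  sp <- state_space(strat)
  P <- build_transition_matrix(sp, cfg, strat, 1)
  for (st in c("acr20", "acr50", "acr70")) {
    expect_equal(unname(P[st, st]), 1, tolerance = 1e-7)
  }
})

test_that("death and discontinuation compete sequentially", {
  # stay = (1 - p_death) * (1 - p_disc) with p_death = 0.004, p_disc from
  # the 37-month median
  p_disc <- 1 - 2^(-6 / 37)
  expect_equal((1 - 0.004) * (1 - p_disc), 0.8901100, tolerance = 1e-6)
  # in the engine: the responder diagonal equals (1 - p_death)(1 - p_disc)
  cfg <- base_config()
  strat <- cfg$strategies[["CZP+MTX"]]
  sp <- state_space(strat)
  P <- build_transition_matrix(sp, cfg, strat, 1)
  pd <- P["acr50", "death"]
  expect_equal(unname(P["acr50", "acr50"]), unname((1 - pd) * (1 - p_disc)),
               tolerance = 1e-12)
})

test_that("the cohort trace conserves mass and death is monotone", {
  cfg <- short_config(10)
  tr <- run_cohort(cfg, "CZP+MTX")
  sums <- tapply(tr$occupancy, tr$cycle, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  death <- tr$occupancy[tr$state == "death"]
  expect_true(all(diff(death) >= -1e-15))
  # with zero background mortality the living mass stays exactly 1
  cfg0 <- zero_mortality_config(cfg)
  tr0 <- run_cohort(cfg0, "CZP+MTX")
  expect_true(all(tr0$occupancy[tr0$state == "death"] == 0))
  living <- tapply(
    tr0$occupancy[tr0$state != "death"], tr0$cycle[tr0$state != "death"], sum
  )
  expect_true(all(abs(living - 1) < 1e-12))
})

test_that("cycle counts follow the horizon and assessment timing", {
  cfg <- base_config()
  tr <- run_cohort(cfg, "CZP+MTX")
  expect_equal(length(unique(tr$cycle)), 90)
  cfg3 <- resolve_scenario(cfg, "acr_3mo")
  tr3 <- run_cohort(cfg3, "CZP+MTX")
  expect_equal(length(unique(tr3$cycle)), 92)
})

test_that("run_cohort matches a hand-unrolled matrix product on a toy sequence", {
  # first line -> palliation only, no mortality: 6 states whose dynamics
  # can be written down directly from the configured probabilities
  cfg <- toy_config(horizon_years = 3, mortality_enabled = FALSE)
  tr <- run_cohort(cfg, "CZP+MTX")
  p <- exclusive_response_probabilities(0.772, 0.492, 0.282)
  p_disc <- 1 - 2^(-6 / 37)
  # states: entry, acr20, acr50, acr70, palliation, death
  P0 <- rbind(
    c(0, p[["acr20"]], p[["acr50"]], p[["acr70"]], p[["none"]], 0),
    c(0, 1, 0, 0, 0, 0),
    c(0, 0, 1, 0, 0, 0),
    c(0, 0, 0, 1, 0, 0),
    c(0, 0, 0, 0, 1, 0),
    c(0, 0, 0, 0, 0, 1)
  )
  Pt <- rbind(
    c(1, 0, 0, 0, 0, 0),
    c(0, 1 - p_disc, 0, 0, p_disc, 0),
    c(0, 0, 1 - p_disc, 0, p_disc, 0),
    c(0, 0, 0, 1 - p_disc, p_disc, 0),
    c(0, 0, 0, 0, 1, 0),
    c(0, 0, 0, 0, 0, 1)
  )
  occ <- c(1, 0, 0, 0, 0, 0)
  states <- c("entry", "acr20", "acr50", "acr70", "palliation", "death")
  for (ci in 0:5) {
    got <- tr$occupancy[tr$cycle == ci]
    names(got) <- tr$state[tr$cycle == ci]
    expect_equal(unname(got[states]), occ, tolerance = 1e-12)
    occ <- as.numeric(occ %*% (if (ci == 0) P0 else Pt))
  }
})

test_that("propagate_occupancy equals an explicit matrix-product oracle", {
  set.seed(42)
  mk <- function() {
    m <- matrix(runif(9), 3, 3)
    m / rowSums(m)
  }
  mats <- replicate(5, mk(), simplify = FALSE)
  init <- c(1, 0, 0)
  out <- propagate_occupancy(mats, init)
  oracle <- init %*% Reduce(`%*%`, mats)
  expect_equal(out[6, ], as.numeric(oracle), tolerance = 1e-14)
  expect_true(all(abs(rowSums(out) - 1) < 1e-12))
})

test_that("responders return exactly to baseline under full rebound", {
  # full rebound, no follow-up gains, no drift: utility in palliation is
  # back at the baseline 0.38
  cfg <- toy_config(horizon_years = 5, mortality_enabled = FALSE)
  cfg <- resolve_scenario(cfg, list(utility = list(
    haq_progression_conventional = 0, haq_progression_palliative = 0,
    continuation_gain_fraction = 0
  )))
  tr <- run_cohort(cfg, "CZP+MTX")
  pall <- tr[tr$state == "palliation" & tr$occupancy > 1e-9, ]
  expect_true(all(abs(pall$haq - cfg$population$baseline_haq) < 1e-10))
  expect_true(all(abs(pall$utility - 0.38) < 1e-10))
})

test_that("the discontinuation-cause split does not affect results", {
  cfg <- short_config(10)
  cfg2 <- cfg
  cfg2$defaults$discontinuation_split <- 0.9
  expect_equal(evaluate_strategy(cfg, "CZP+MTX"),
               evaluate_strategy(cfg2, "CZP+MTX"))
})

test_that("HAQ stays within bounds and utility below the ceiling everywhere", {
  cfg <- short_config(20)
  for (nm in c("CZP+MTX", "IFX5+MTX")) {
    tr <- run_cohort(cfg, nm)
    expect_true(all(tr$haq >= 0 & tr$haq <= 3))
    expect_true(all(tr$utility <= 1))
    expect_true(all(tr$utility[tr$state == "death"] == 0))
  }
})
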