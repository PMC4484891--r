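test_that("PSA distribution parameters derive from the printed intervals", {
  cfg <- base_config()
  par <- cfg$psa$parameters
  # log-normal scale for the mortality RR: (ln 1.610 - ln 1.099) / 3.92
  rr <- par[par$parameter == "mortality_rr", ]
  expect_equal(rr$p1, log(1.330))
  expect_equal(rr$p2, (log(1.610) - log(1.099)) / (2 * 1.96), tolerance = 1e-12)
  expect_equal(rr$p2, 0.09741, tolerance = 1e-4)
  # beta for the female proportion: shapes n and N - n
  g <- par[par$parameter == "gender_female", ]
  expect_equal(c(g$p1, g$p2), c(1506, 315))
  expect_equal(g$p1 / (g$p1 + g$p2), 1506 / 1821, tolerance = 1e-12)
  expect_equal(cfg$psa$n_draws, 1000)
})

test_that("a PSA draw keeps fractions in (0,1) and is RNG-state reproducible", {
  cfg <- base_config()
  set.seed(99)
  d1 <- sample_psa_draw(cfg)
  set.seed(99)
  d2 <- sample_psa_draw(cfg)
  expect_identical(d1, d2)
  r <- d1$response
  vals <- unlist(r[c("acr20", "acr50", "acr70")])
  expect_true(all(vals > 0 & vals < 1))
  expect_gt(d1$params$mortality_rr, 0)
  expect_true(d1$params$gender_female > 0 && d1$params$gender_female < 1)
  expect_true(d1$params$baseline_haq >= 0 && d1$params$baseline_haq <= 3)
})

test_that("run_psa is seed-reproducible and distinct across seeds", {
  cfg <- short_config(5)
  strategies <- c("CZP+MTX", "ADA+MTX q2w")
  p1 <- run_psa(cfg, strategies, n_draws = 3, seed = 11)
  p2 <- run_psa(cfg, strategies, n_draws = 3, seed = 11)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- run_psa(cfg, strategies, n_draws = 3, seed = 12)
  expect_false(identical(p1$delta_cost, p3$delta_cost))
})

test_that("degenerate PSA distributions reproduce the base case", {
  cfg <- short_config(5)
  cfg$psa$response_logodds_sd <- 1e-12
  par <- cfg$psa$parameters
  par$p2[par$family %in% c("normal", "lognormal")] <- 1e-12
  # a beta cannot be made degenerate; scale its shapes up hugely
  par$p1[par$family == "beta"] <- 1506e7
  par$p2[par$family == "beta"] <- 315e7
  cfg$psa$parameters <- par
  cfg$population$weight_cdf <- list(
    median_kg = 81.4, spread_kg = 1e-9, sdlog = 1e-9 / 81.4,
    cdf = function(w) as.numeric(w >= 81.4), quantile = function(p) 81.4
  )
  class(cfg$population$weight_cdf) <- "cea_weight_cdf"
  psa <- run_psa(cfg, c("CZP+MTX", "IFX3+MTX"), n_draws = 3, seed = 5)
  base <- evaluate_strategies(cfg, c("CZP+MTX", "IFX3+MTX"))
  expect_equal(psa$ref_cost, rep(base$cost[1], 3), tolerance = 1e-4)
  expect_equal(psa$comp_qalys, rep(base$qalys[2], 3), tolerance = 1e-4)
})

test_that("CEAC counts net-monetary-benefit wins and stays in [0, 1]", {
  fake <- tibble::tibble(
    draw = 1:4, comparator = "B",
    ref_cost = 0, ref_qalys = 0, comp_cost = 0, comp_qalys = 0,
    delta_cost = c(-1, -1, -1, -1), delta_qaly = c(0.1, 0.1, 0.1, 0.1)
  )
  class(fake) <- c("cea_psa", class(fake))
  curve <- ceac(fake, wtp_grid = c(0, 30000))
  expect_equal(curve$probability_ce, c(1, 1))

  fake2 <- fake
  fake2$delta_cost <- 1e6
  fake2$delta_qaly <- 0.001
  expect_equal(ceac(fake2, wtp_grid = 30000)$probability_ce, 0)

  # half the draws favourable at 30,000
  fake3 <- fake
  fake3$delta_cost <- c(-1, -1, 1e6, 1e6)
  expect_equal(ceac(fake3, wtp_grid = 30000)$probability_ce, 0.5)

  # invariant to draw order
  fake4 <- fake3[c(3, 1, 4, 2), ]
  expect_equal(ceac(fake4, wtp_grid = 30000), ceac(fake3, wtp_grid = 30000))
  expect_error(ceac(fake[0, ]), "no draws")
})

test_that("a deterministically dominant reference has a flat CEAC of 1", {
  cfg <- short_config(5)
  # comparator with doubled drug price and dominated response
  cfg$strategies <- cfg$strategies[c("CZP+MTX", "ADA+MTX weekly")]
  psa <- run_psa(cfg, names(cfg$strategies), n_draws = 25, seed = 2)
  curve <- ceac(psa, wtp_grid = seq(0, 1e5, by = 2e4))
  expect_true(all(curve$probability_ce >= 0 & curve$probability_ce <= 1))
  expect_true(all(curve$probability_ce[curve$wtp == 0] > 0.9))
})

test_that("tidiers summarise results and PSA objects", {
  cfg <- short_config(5)
  res <- evaluate_strategies(cfg, c("CZP+MTX", "IFX3+MTX"))
  expect_s3_class(tidy(res), "tbl_df")
  gl <- glance(res)
  expect_equal(gl$n_strategies, 2)
  psa <- run_psa(cfg, c("CZP+MTX", "IFX3+MTX"), n_draws = 4, seed = 1)
  g <- glance(psa)
  expect_equal(g$n_draws, 4)
  expect_true(all(g$prob_ce_at_wtp >= 0 & g$prob_ce_at_wtp <= 1))
  expect_s3_class(autoplot(psa), "ggplot")
  expect_s3_class(autoplot(ceac(psa)), "ggplot")
  expect_s3_class(autoplot(run_cohort(cfg, "CZP+MTX")), "ggplot")
})
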