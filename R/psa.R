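#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Samples the varied parameters from their configured distributions:
#' cumulative ACR response fractions on the log-odds scale (normal with
#' the configured log-odds standard error, then inverse-logit, so every
#' drawn fraction lies in (0, 1)); the HAQ-mortality relative risk from a
#' log-normal; mean age, baseline HAQ-DI, utility weight, prior DMARD
#' count, disease duration and antibody status from normals; the female
#' proportion from a beta; and weight from the empirical weight
#' distribution. Uses the current RNG state — seed outside (or via
#' [run_psa()]).
#'
#' @param config A `cea_config` (supplies `psa`, `response`, population).
#' @return List with `response` (tibble like `config$response`) and
#'   `params` (named list of drawn scalars).
#' @export
sample_psa_draw <- function(config) {
  psa <- config$psa
  par <- psa$parameters
  draw1 <- function(name) {
    row <- par[par$parameter == name, ]
    switch(row$family,
      normal = rnorm(1, row$p1, row$p2),
      lognormal = rlnorm(1, row$p1, row$p2),
      beta = rbeta(1, row$p1, row$p2),
      empirical_cdf = config$population$weight_cdf$quantile(runif(1)),
      abort(sprintf("unknown PSA family '%s'", row$family))
    )
  }
  resp <- config$response
  sd_lo <- psa$response_logodds_sd
  for (cat in c("acr20", "acr50", "acr70")) {
    lo <- qlogis(pmin(pmax(resp[[cat]], 1e-6), 1 - 1e-6))
    resp[[cat]] <- plogis(rnorm(length(lo), lo, sd_lo))
  }
  list(
    response = resp,
    params = list(
      mortality_rr = draw1("mortality_rr"),
      age = draw1("age"),
      gender_female = draw1("gender_female"),
      baseline_haq = min(3, max(0, draw1("baseline_haq"))),
      utility_weight = min(1, draw1("utility_weight")),
      weight = draw1("weight"),
      n_prior_dmards = draw1("n_prior_dmards"),
      disease_duration = draw1("disease_duration"),
      anti_ccp_positive = draw1("anti_ccp_positive"),
      anti_ccp_negative = draw1("anti_ccp_negative")
    )
  )
}

apply_psa_draw <- function(config, draw) {
  config$response <- draw$response
  p <- draw$params
  config$mortality$rr_per_haq_unit <- p$mortality_rr
  config$population$mean_age <- p$age
  config$population$proportion_female <- p$gender_female
  config$population$baseline_haq <- p$baseline_haq
  config$population$mean_weight_kg <- p$weight
  config$utility$baseline_utility <- p$utility_weight
  config
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter sets, re-evaluates every strategy per
#' draw, and records the incremental cost and QALY differences of the
#' reference versus each comparator. Reproducible under `seed`. Costs are
#' held at their base-case values except where parameters (patient
#' weight, baseline HAQ) enter the costing; only the configured PSA
#' parameters vary.
#'
#' @param config A `cea_config`.
#' @param strategies Strategy names to evaluate.
#' @param n_draws Number of simulations (default from the configuration).
#' @param seed Integer RNG seed.
#' @param reference Reference strategy name (default: first of
#'   `strategies`).
#' @return A tibble of class `cea_psa`: one row per (draw, comparator)
#'   with `draw`, `comparator`, `ref_cost`, `ref_qalys`, `comp_cost`,
#'   `comp_qalys`, `delta_cost`, `delta_qaly`; attributes `seed`,
#'   `reference`, `wtp_threshold`.
#' @export
run_psa <- function(config, strategies, n_draws = config$psa$n_draws, seed = 1,
                    reference = strategies[1]) {
  if (n_draws < 1) abort("n_draws must be >= 1")
  set.seed(as.integer(seed))
  # drug/administration/monitoring costs are held at base case across
  # draws; only weight-based regimens need their cost tables refreshed
  # when the drawn patient weight changes
  strat_objs <- config$strategies[strategies]
  n_s <- length(strat_objs)
  preps <- lapply(strat_objs, function(s) strategy_cost_prep(config, s))
  cost_mat <- matrix(NA_real_, n_draws, n_s, dimnames = list(NULL, strategies))
  qaly_mat <- matrix(NA_real_, n_draws, n_s, dimnames = list(NULL, strategies))
  for (d in seq_len(n_draws)) {
    draw <- sample_psa_draw(config)
    cfg_d <- apply_psa_draw(config, draw)
    for (i in seq_len(n_s)) {
      ev <- evaluate_strategy_core(
        cfg_d, strat_objs[[i]],
        cost_matrix = strategy_cost_apply(preps[[i]], cfg_d)
      )
      cost_mat[d, i] <- ev[["cost"]]
      qaly_mat[d, i] <- ev[["qalys"]]
    }
  }
  comparators <- setdiff(strategies, reference)
  out <- bind_rows(lapply(comparators, function(cp) {
    tibble(
      draw = seq_len(n_draws),
      comparator = cp,
      ref_cost = cost_mat[, reference], ref_qalys = qaly_mat[, reference],
      comp_cost = cost_mat[, cp], comp_qalys = qaly_mat[, cp],
      delta_cost = cost_mat[, reference] - cost_mat[, cp],
      delta_qaly = qaly_mat[, reference] - qaly_mat[, cp]
    )
  })) |> arrange(.data$draw, .data$comparator)
  class(out) <- c("cea_psa", class(out))
  attr(out, "seed") <- seed
  attr(out, "reference") <- reference
  attr(out, "wtp_threshold") <- config$settings$wtp_threshold
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' the reference strategy has positive incremental net monetary benefit
#' (`wtp * delta_qaly - delta_cost > 0`) against each comparator.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param wtp_grid Willingness-to-pay values in euro per QALY; the default
#'   runs 0 to 100,000 in 1,000 steps (which includes the 30,000
#'   threshold).
#' @return Tibble of class `cea_ceac` with `comparator`, `wtp`,
#'   `probability_ce`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  if (nrow(psa) == 0) abort("PSA result has no draws")
  out <- tidyr::crossing(
    comparator = unique(psa$comparator), wtp = wtp_grid
  )
  out$probability_ce <- purrr::map2_dbl(out$comparator, out$wtp, function(cp, l) {
    d <- psa[psa$comparator == cp, ]
    mean(l * d$delta_qaly - d$delta_cost > 0)
  })
  class(out) <- c("cea_ceac", class(out))
  attr(out, "reference") <- attr(psa, "reference")
  out
}
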