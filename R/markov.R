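#' Exclusive response-category probabilities from cumulative ACR fractions
#'
#' ACR categories are cumulative (ACR70 within ACR50 within ACR20); the
#' transition engine needs exclusive categories. Successive differences
#' are clamped at zero (with a warning) for non-monotone published rows,
#' and the non-responder mass completes the distribution:
#' `p_none = 1 - max(acr20, acr50, acr70)`.
#'
#' @param acr20,acr50,acr70 Cumulative response fractions in \[0, 1\].
#' @param quiet Suppress the clamping warning (used inside the PSA, where
#'   independently drawn cumulative fractions can cross).
#' @return Named vector `(none, acr20, acr50, acr70)` summing to 1.
#' @export
#' @examples
#' exclusive_response_probabilities(0.772, 0.492, 0.282)
exclusive_response_probabilities <- function(acr20, acr50, acr70, quiet = FALSE) {
  stopifnot(all(c(acr20, acr50, acr70) >= 0), all(c(acr20, acr50, acr70) <= 1))
  p70 <- acr70
  p50 <- acr50 - acr70
  p20 <- acr20 - acr50
  if ((p50 < 0 || p20 < 0) && !quiet) {
    warn("non-monotone cumulative ACR fractions: clamping negative exclusive mass to 0")
  }
  p50 <- max(0, p50)
  p20 <- max(0, p20)
  p_any <- max(acr20, acr50, acr70)
  c(none = 1 - p_any, acr20 = p20, acr50 = p50, acr70 = p70)
}

#' Per-cycle discontinuation probability from a median treatment duration
#'
#' Under a constant discontinuation hazard, a median time on treatment of
#' `median_months` implies a per-cycle probability
#' `1 - 0.5^(cycle_months / median_months)`.
#'
#' @param median_months Median treatment duration in months (> 0).
#' @param cycle_months Cycle length in months (> 0).
#' @return Discontinuation probability per cycle.
#' @export
#' @examples
#' median_to_cycle_discontinuation(37, 6) # 0.10632
median_to_cycle_discontinuation <- function(median_months, cycle_months) {
  if (median_months <= 0 || cycle_months <= 0) abort("durations must be positive")
  1 - 0.5^(cycle_months / median_months)
}

#' State space of a treatment-sequence model
#'
#' Ordered states: the pre-response entry state; the three first-line
#' response states; per follow-up therapy an assessment state (first
#' cycle on the line) and a continuing state; palliation; and the
#' absorbing death state.
#'
#' @param strategy A [treatment_strategy()].
#' @return Tibble with `state`, `type`, `line` (follow-up line index or
#'   `NA`), `drug`.
#' @export
state_space <- function(strategy) {
  fl_drugs <- setdiff(strategy$followup_sequence, "palliation")
  nf <- length(fl_drugs)
  fl_states <- if (nf > 0) {
    as.character(rbind(paste0("assess:", fl_drugs), paste0("cont:", fl_drugs)))
  } else {
    character(0)
  }
  tibble::new_tibble(
    list(
      state = c("entry", "acr20", "acr50", "acr70", fl_states, "palliation", "death"),
      type = c("entry", rep("responder", 3), rep(c("assess", "cont"), nf),
               "palliation", "death"),
      line = c(rep(NA_integer_, 4), rep(seq_len(nf), each = 2), NA_integer_, NA_integer_),
      drug = c(rep(strategy$drug, 4), rep(fl_drugs, each = 2), "palliation", NA)
    ),
    nrow = 6 + 2 * nf
  )
}

#' Cycle grid of the model
#'
#' Year one is divided into cycles of the response-assessment length
#' (3 or 6 months); all later cycles are 6 months, out to the horizon.
#'
#' @param settings Model settings.
#' @return Tibble with `cycle` (0-based), `months`, `time_years` (cycle
#'   start), `cycle_years`, `start_week`, `end_week`.
#' @export
cycle_grid <- function(settings) {
  m1 <- settings$response_assessment_months
  m2 <- settings$cycle_months_after_year1
  total_months <- settings$horizon_years * 12
  months <- rep(m1, min(12, total_months) / m1)
  if (total_months > 12) months <- c(months, rep(m2, (total_months - 12) / m2))
  starts <- cumsum(c(0, months[-length(months)]))
  tibble(
    cycle = seq_along(months) - 1L,
    months = months,
    time_years = starts / 12,
    cycle_years = months / 12,
    start_week = starts * WEEKS_PER_MONTH,
    end_week = (starts + months) * WEEKS_PER_MONTH
  )
}

# Model quantities shared by the matrix builder and the cohort engine.
engine_params <- function(config, strategy) {
  m1 <- config$settings$response_assessment_months
  resp <- config$response
  row <- resp[resp$strategy == strategy$name & resp$timepoint_months == m1, ]
  if (nrow(row) == 0) {
    abort(sprintf("no response row for strategy '%s' at %d months", strategy$name, m1))
  }
  p_first <- exclusive_response_probabilities(row$acr20, row$acr50, row$acr70,
                                              quiet = TRUE)
  dhaq <- effective_haq_changes(config)
  fl_drugs <- setdiff(strategy$followup_sequence, "palliation")
  reg <- config$defaults
  fr <- reg$followup_response_tables
  fd <- reg$followup_median_duration_months
  line_resp <- numeric(length(fl_drugs))
  line_gain <- numeric(length(fl_drugs)) # expected HAQ improvement on entry
  line_median <- numeric(length(fl_drugs))
  for (k in seq_along(fl_drugs)) {
    r <- fr[fr$drug == fl_drugs[k], ]
    if (nrow(r) == 0) abort(sprintf("no follow-up response row for '%s'", fl_drugs[k]))
    pk <- exclusive_response_probabilities(r$acr20, r$acr50, r$acr70, quiet = TRUE)
    line_resp[k] <- r$acr20
    line_gain[k] <- -sum(pk * dhaq[names(pk)])
    line_median[k] <- fd$median_months[fd$drug == fl_drugs[k]]
  }
  list(
    p_first = p_first, dhaq = dhaq, fl_drugs = fl_drugs,
    line_resp = line_resp, line_gain = line_gain, line_median = line_median
  )
}

# HAQ change by response category actually used by the model: the
# registry defaults, or — when explicit utility gains are configured —
# their HAQ-equivalents through the utility mapping.
effective_haq_changes <- function(config) {
  expl <- config$utility$response_gain_explicit
  if (is.null(expl)) {
    return(config$defaults$haq_change_by_acr_category)
  }
  vapply(expl, function(g) g / config$utility$bansback_coefficient, numeric(1))
}

# Precomputed engine context: state space, cycle grid, response/line
# parameters, and the sex-mix-weighted annual death probability by
# integer age (so the inner loop avoids data-frame lookups).
make_engine <- function(config, strategy) {
  space <- state_space(strategy)
  grid <- cycle_grid(config$settings)
  par <- engine_params(config, strategy)
  lt <- config$mortality$life_table
  ages <- sort(unique(lt$age))
  pf <- config$population$proportion_female
  qm <- lt$qx[lt$sex == "male"][match(ages, lt$age[lt$sex == "male"])]
  qf <- lt$qx[lt$sex == "female"][match(ages, lt$age[lt$sex == "female"])]
  qx_mix <- setNames((1 - pf) * qm + pf * qf, ages)
  states <- space$state
  idx <- setNames(seq_along(states), states)
  n_lines <- length(par$fl_drugs)
  i_assess <- if (n_lines > 0) unname(idx[paste0("assess:", par$fl_drugs)]) else integer()
  i_cont <- if (n_lines > 0) unname(idx[paste0("cont:", par$fl_drugs)]) else integer()
  i_next <- if (n_lines > 0) c(i_assess[-1], unname(idx["palliation"])) else integer()
  # per-cycle-length discontinuation probabilities (at most two lengths)
  disc <- lapply(unique(grid$months), function(m) {
    list(
      months = m,
      first = median_to_cycle_discontinuation(strategy$median_duration_months, m),
      lines = if (n_lines > 0) {
        vapply(par$line_median, median_to_cycle_discontinuation,
               numeric(1), cycle_months = m)
      } else {
        numeric()
      }
    )
  })
  names(disc) <- as.character(unique(grid$months))
  list(
    space = space, grid = grid, par = par, qx_mix = qx_mix, ages = ages,
    config = config, strategy = strategy,
    idx = idx,
    i_entry = unname(idx["entry"]),
    i_cat = unname(idx[c("acr20", "acr50", "acr70")]),
    i_assess = i_assess, i_cont = i_cont, i_next = i_next,
    i_pall = unname(idx["palliation"]), i_death = unname(idx["death"]),
    i_first_exit = if (n_lines > 0) i_assess[1] else unname(idx["palliation"]),
    disc = disc
  )
}

engine_death_prob <- function(engine, cycle_index, state_haq) {
  config <- engine$config
  grid <- engine$grid
  months <- grid$months[cycle_index + 1]
  age <- round(config$population$mean_age + grid$time_years[cycle_index + 1])
  pos <- match(age, engine$ages)
  if (is.na(pos)) abort(sprintf("life table does not cover age %s", age))
  qx <- unname(engine$qx_mix[pos])
  hazard <- -log(1 - min(qx, 1 - 1e-15))
  mult <- if (isTRUE(config$mortality$enabled)) {
    config$mortality$rr_per_haq_unit^pmin(3, pmax(0, state_haq))
  } else {
    rep(1, length(state_haq))
  }
  pd <- pmin(1, 1 - exp(-hazard * mult * months / 12))
  pd[engine$i_death] <- 0
  pd
}

engine_transition_matrix <- function(engine, cycle_index, state_haq) {
  S <- length(engine$idx)
  months <- engine$grid$months[cycle_index + 1]
  dc <- engine$disc[[as.character(months)]]
  pd <- engine_death_prob(engine, cycle_index, state_haq)
  surv <- 1 - pd
  states <- names(engine$idx)
  P <- matrix(0, S, S, dimnames = list(states, states))
  P[cbind(seq_len(S), engine$i_death)] <- pd
  P[engine$i_death, engine$i_death] <- 1
  ie <- engine$i_entry
  ic <- engine$i_cat
  if (cycle_index == 0) {
    p <- engine$par$p_first
    P[ie, ic] <- surv[ie] * p[c("acr20", "acr50", "acr70")]
    P[ie, engine$i_first_exit] <- P[ie, engine$i_first_exit] + surv[ie] * p[["none"]]
    P[cbind(ic, ic)] <- surv[ic]
  } else {
    P[ie, ie] <- surv[ie]
    P[ic, engine$i_first_exit] <- surv[ic] * dc$first
    P[cbind(ic, ic)] <- surv[ic] * (1 - dc$first)
  }
  if (length(engine$i_assess) > 0) {
    sa <- surv[engine$i_assess]
    P[cbind(engine$i_assess, engine$i_cont)] <- sa * engine$par$line_resp
    P[cbind(engine$i_assess, engine$i_next)] <-
      P[cbind(engine$i_assess, engine$i_next)] + sa * (1 - engine$par$line_resp)
    sc <- surv[engine$i_cont]
    P[cbind(engine$i_cont, engine$i_next)] <- sc * dc$lines
    P[cbind(engine$i_cont, engine$i_cont)] <- sc * (1 - dc$lines)
  }
  P[engine$i_pall, engine$i_pall] <- surv[engine$i_pall]
  P
}

#' Build the transition matrix for one cycle
#'
#' Cycle 0 is the assessment cycle: the entry state splits into the
#' exclusive response categories, with non-responders moving to the first
#' follow-up line. In later cycles responders remain on first-line
#' therapy, discontinue (per the median-duration hazard) to the first
#' follow-up line, or die; each follow-up line's assessment state sends
#' responders to its continuing state and non-responders to the next
#' line; palliation exits only to death. Competing risks are applied
#' sequentially — death first, then discontinuation among survivors — so
#' rows are stochastic without renormalisation.
#'
#' @param space A [state_space()].
#' @param config A `cea_config`.
#' @param strategy A [treatment_strategy()].
#' @param cycle_index 0-based cycle number.
#' @param state_haq Optional numeric vector of current mean HAQ per state
#'   (defaults to the baseline HAQ everywhere); drives the mortality
#'   adjustment.
#' @return Square row-stochastic matrix with dimnames = states.
#' @export
build_transition_matrix <- function(space, config, strategy, cycle_index,
                                    state_haq = NULL) {
  if (is.character(strategy)) strategy <- config$strategies[[strategy]]
  engine <- make_engine(config, strategy)
  if (cycle_index < 0 || cycle_index >= nrow(engine$grid)) {
    abort("cycle_index out of range")
  }
  if (is.null(state_haq)) {
    state_haq <- rep(config$population$baseline_haq, nrow(engine$space))
  }
  engine_transition_matrix(engine, cycle_index, state_haq)
}

#' Multiply a cohort through a sequence of transition matrices
#'
#' @param matrices List of row-stochastic matrices.
#' @param init Initial occupancy vector.
#' @return Matrix of occupancies, one row per step (including the initial
#'   row).
#' @export
propagate_occupancy <- function(matrices, init) {
  out <- matrix(NA_real_, length(matrices) + 1, length(init))
  out[1, ] <- init
  occ <- init
  for (i in seq_along(matrices)) {
    occ <- as.numeric(occ %*% matrices[[i]])
    out[i + 1, ] <- occ
  }
  colnames(out) <- names(init) %||% colnames(matrices[[1]])
  out
}

# Continuation-gain accrual fraction at model time t (months): gains
# accrue linearly over the 12 months following the first response
# assessment.
continuation_accrual <- function(t_months, assess_months, cont_fraction) {
  cont_fraction * pmin(1, pmax(0, (t_months - assess_months) / 12))
}

#' Run the cohort through the full model
#'
#' Propagates unit mass from the entry state across the cycle grid,
#' tracking per-state occupancy, mean HAQ-DI (with response gains,
#' continuation improvement, rebound on discontinuation, and
#' off-treatment drift), EQ-5D utility via the HAQ-utility mapping, and
#' the treatment-attributable gain needed for rebound accounting.
#'
#' @param config A `cea_config`.
#' @param strategy A [treatment_strategy()] (or its name in
#'   `config$strategies`).
#' @return A tibble of class `cea_trace`: one row per (cycle, state) with
#'   `cycle`, `time_years`, `cycle_years`, `state`, `occupancy`, `haq`,
#'   `utility`. Occupancy and attributes refer to the cycle start; the
#'   entry-state utility of cycle 0 is the time-average of the
#'   front-loaded first-cycle profile mixed over response categories.
#' @export
run_cohort <- function(config, strategy) {
  if (is.character(strategy)) strategy <- config$strategies[[strategy]]
  stopifnot(inherits(strategy, "cea_strategy"))
  engine <- make_engine(config, strategy)
  core <- run_cohort_core(engine)
  S <- nrow(engine$space)
  grid <- engine$grid
  out <- tibble(
    cycle = rep(grid$cycle, each = S),
    time_years = rep(grid$time_years, each = S),
    cycle_years = rep(grid$cycle_years, each = S),
    state = rep(engine$space$state, nrow(grid)),
    occupancy = as.numeric(t(core$occ)),
    haq = as.numeric(t(core$haq)),
    utility = as.numeric(t(core$utility))
  )
  class(out) <- c("cea_trace", class(out))
  attr(out, "strategy") <- strategy$name
  out
}

# Matrix-form cohort propagation: returns per-cycle-by-state occupancy,
# mean HAQ and utility matrices (rows = cycles, cols = states), with all
# quantities referring to the cycle start.
run_cohort_core <- function(engine) {
  config <- engine$config
  space <- engine$space
  grid <- engine$grid
  par <- engine$par
  u <- config$utility
  S <- nrow(space)
  n_cycles <- nrow(grid)
  base_haq <- config$population$baseline_haq
  base_u <- u$baseline_utility
  m1 <- config$settings$response_assessment_months
  imp_cat <- -par$dhaq[c("acr20", "acr50", "acr70")] # positive improvements
  cat_idx <- engine$i_cat
  n_lines <- length(par$fl_drugs)
  reb <- u$rebound_fraction
  cf <- u$continuation_gain_fraction

  # per-state static drift rates (HAQ units / year)
  drift <- numeric(S)
  drift[space$type %in% c("entry", "responder")] <- u$haq_progression_on_biologic
  drift[space$type %in% c("assess", "cont")] <- u$haq_progression_conventional
  drift[space$type == "palliation"] <- u$haq_progression_palliative

  # static part of the edge-jump matrix (HAQ change applied on a
  # transition); the responder-exit entries depend on the accrued
  # continuation gain and are refreshed per cycle
  J <- matrix(0, S, S)
  if (n_lines > 0) {
    J[engine$i_entry, engine$i_first_exit] <- -par$line_gain[1]
    for (k in seq_len(n_lines)) {
      gain_next <- if (k < n_lines) par$line_gain[k + 1] else 0
      J[engine$i_assess[k], engine$i_next[k]] <- reb * par$line_gain[k] - gain_next
      J[engine$i_cont[k], engine$i_next[k]] <- reb * par$line_gain[k] - gain_next
    }
  }
  J[engine$i_entry, cat_idx] <- par$dhaq[c("acr20", "acr50", "acr70")]

  occ <- numeric(S)
  occ[engine$i_entry] <- 1
  h <- rep(base_haq, S)

  occ_out <- matrix(0, n_cycles, S)
  haq_out <- matrix(base_haq, n_cycles, S)

  for (ci in seq_len(n_cycles)) {
    t0 <- grid$time_years[ci]
    months <- grid$months[ci]
    t_end_months <- (t0 + months / 12) * 12
    occ_out[ci, ] <- occ
    haq_out[ci, ] <- h

    P <- engine_transition_matrix(engine, ci - 1L, state_haq = h)

    # end-of-cycle HAQ per state: drift plus continuation accrual for
    # first-line responders
    accr_end <- continuation_accrual(t_end_months, m1, cf)
    dc <- accr_end - continuation_accrual(t0 * 12, m1, cf)
    h_end <- pmin(u$haq_max, h + drift * months / 12)
    h_end[cat_idx] <- h_end[cat_idx] - imp_cat * dc

    # treatment-attributable gain currently held, for rebound on exit
    gain_cat <- imp_cat * (1 + accr_end)
    J[cat_idx, engine$i_first_exit] <- reb * gain_cat -
      if (n_lines > 0) par$line_gain[1] else 0

    flows <- occ * P # S x S: flow from i to j
    occ_new <- colSums(flows)
    h_new <- h_end # carry forward for unoccupied states
    pos <- which(occ_new > 1e-300)
    for (j in pos) {
      if (j == engine$i_death) next
      w <- flows[, j]
      nz <- which(w > 0)
      if (length(nz) == 0) next
      h_new[j] <- sum(w[nz] * (h_end[nz] + J[nz, j])) / occ_new[j]
    }
    occ <- occ_new
    h <- pmin(u$haq_max, pmax(0, h_new))
  }

  util_out <- base_u + u$bansback_coefficient * (haq_out - base_haq)
  util_out <- pmin(pmax(util_out, u$utility_floor), u$utility_ceiling)
  util_out[, engine$i_death] <- 0

  # cycle-0 entry utility: category-mixed time-average of the
  # front-loaded first-cycle profile
  p <- par$p_first
  gains_u <- -u$bansback_coefficient * imp_cat # utility gains by category
  mean_u0 <- p[["none"]] * base_u
  for (ci2 in 1:3) {
    prof <- first_cycle_utility_profile(base_u, gains_u[[ci2]], grid$months[1], u)
    mean_u0 <- mean_u0 + p[[c("acr20", "acr50", "acr70")[ci2]]] * prof$mean_utility
  }
  util_out[1, engine$i_entry] <- mean_u0

  list(occ = occ_out, haq = haq_out, utility = util_out)
}
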