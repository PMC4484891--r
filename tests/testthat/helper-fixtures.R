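# Shared fixtures: the base-case configuration is cached once per test
# run; shorter-horizon variants keep individual tests fast.

base_config <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- default_parameter_set()
    cached
  }
})

short_config <- function(horizon_years = 10) {
  resolve_scenario(base_config(), list(settings = list(horizon_years = horizon_years)))
}

combo_strategies <- c(
  "CZP+MTX", "ADA+MTX q2w", "ADA+MTX weekly", "ETA+MTX", "IFX3+MTX", "IFX5+MTX"
)

# A minimal sequence model (first line -> palliation) used for
# hand-unrolled oracles.
toy_strategy <- function(median_duration_months = 37) {
  treatment_strategy(
    name = "CZP+MTX", drug = "CZP",
    regimen = default_strategies()[["CZP+MTX"]]$regimen,
    with_methotrexate = TRUE,
    median_duration_months = median_duration_months,
    followup_sequence = "palliation"
  )
}

# Remove background mortality entirely (all-zero life table).
zero_mortality_config <- function(cfg) {
  cfg$mortality$life_table$qx <- 0
  cfg
}

# mortality_enabled = FALSE removes deaths entirely (all-zero life table)
toy_config <- function(horizon_years = 3, mortality_enabled = FALSE) {
  cfg <- base_config()
  cfg$strategies <- list("CZP+MTX" = toy_strategy())
  cfg <- resolve_scenario(cfg, list(
    settings = list(horizon_years = horizon_years)
  ))
  if (!mortality_enabled) cfg <- zero_mortality_config(cfg)
  cfg
}
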