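#' Dosing regimen
#'
#' Describes how a drug is administered: optional loading doses at fixed
#' weeks, then maintenance doses on a regular interval. Exactly one of
#' `maintenance_dose_mg` (fixed dose) or `mg_per_kg` (weight-based dose)
#' must be given.
#'
#' @param loading_doses Tibble or data frame with columns `week` and
#'   `dose_mg` (strictly increasing weeks), or `NULL` for none.
#' @param maintenance_dose_mg Fixed maintenance dose in mg, or `NULL`.
#' @param mg_per_kg Weight-based maintenance dose in mg per kg, or `NULL`.
#' @param maintenance_interval_weeks Weeks between maintenance doses (> 0;
#'   fractional values express more-than-weekly dosing, e.g. 0.5 for twice
#'   weekly).
#' @param maintenance_start_week Week of the first maintenance dose.
#' @param route One of `"subcutaneous"`, `"intravenous"`, `"oral"`,
#'   `"intramuscular"`.
#'
#' @return A list of class `cea_regimen`.
#' @export
#' @examples
#' # certolizumab pegol: 400 mg at weeks 0, 2, 4 then 200 mg every 2 weeks
#' regimen(
#'   loading_doses = data.frame(week = c(0, 2, 4), dose_mg = 400),
#'   maintenance_dose_mg = 200, maintenance_interval_weeks = 2,
#'   maintenance_start_week = 6, route = "subcutaneous"
#' )
regimen <- function(loading_doses = NULL,
                    maintenance_dose_mg = NULL,
                    mg_per_kg = NULL,
                    maintenance_interval_weeks,
                    maintenance_start_week,
                    route = c("subcutaneous", "intravenous", "oral", "intramuscular")) {
  route <- match.arg(route)
  if (is.null(loading_doses)) {
    loading_doses <- tibble(week = numeric(), dose_mg = numeric())
  }
  loading_doses <- as_tibble(loading_doses)
  stopifnot(all(c("week", "dose_mg") %in% names(loading_doses)))
  if (nrow(loading_doses) > 1 && any(diff(loading_doses$week) <= 0)) {
    abort("loading dose weeks must be strictly increasing")
  }
  if (any(loading_doses$dose_mg <= 0, na.rm = TRUE)) abort("loading doses must be positive")
  if (is.null(maintenance_dose_mg) == is.null(mg_per_kg)) {
    abort("exactly one of maintenance_dose_mg and mg_per_kg must be set")
  }
  if (!is.null(maintenance_dose_mg) && maintenance_dose_mg <= 0) {
    abort("maintenance_dose_mg must be positive")
  }
  if (!is.null(mg_per_kg) && mg_per_kg <= 0) abort("mg_per_kg must be positive")
  if (maintenance_interval_weeks <= 0) abort("maintenance_interval_weeks must be positive")
  structure(
    list(
      loading_doses = loading_doses,
      maintenance_dose_mg = maintenance_dose_mg,
      mg_per_kg = mg_per_kg,
      maintenance_interval_weeks = maintenance_interval_weeks,
      maintenance_start_week = maintenance_start_week,
      route = route
    ),
    class = "cea_regimen"
  )
}

#' Treatment strategy
#'
#' A first-line therapy (drug + regimen, with or without background
#' methotrexate) and the ordered sequence of follow-up therapies a patient
#' moves through after discontinuation, ending in palliation.
#'
#' @param name Strategy label used in result tables.
#' @param drug Drug code matching the unit-cost table (e.g. `"CZP"`).
#' @param regimen A [regimen()].
#' @param with_methotrexate Logical; background methotrexate co-therapy.
#' @param median_duration_months Median time on the first-line therapy in
#'   months; converted to a per-cycle discontinuation probability under a
#'   constant hazard.
#' @param followup_sequence Character vector of follow-up therapies in
#'   order, ending with `"palliation"`.
#'
#' @return A list of class `cea_strategy`.
#' @export
treatment_strategy <- function(name, drug, regimen, with_methotrexate,
                               median_duration_months = 37,
                               followup_sequence = default_followup_sequence()) {
  stopifnot(inherits(regimen, "cea_regimen"))
  if (median_duration_months <= 0) abort("median_duration_months must be positive")
  if (utils::tail(followup_sequence, 1) != "palliation") {
    abort("followup_sequence must end with 'palliation'")
  }
  structure(
    list(
      name = name, drug = drug, regimen = regimen,
      with_methotrexate = with_methotrexate,
      median_duration_months = median_duration_months,
      followup_sequence = followup_sequence
    ),
    class = "cea_strategy"
  )
}

#' Default follow-up sequence of conventional DMARDs
#'
#' The conventional DMARD cascade applied after first-line biologic
#' discontinuation, ending in palliation.
#'
#' @return Character vector.
#' @export
default_followup_sequence <- function() {
  c(
    "sulfasalazine", "leflunomide", "gold sodium thiomalate",
    "hydroxychloroquine", "azathioprine", "cyclosporine",
    "penicillamine", "palliation"
  )
}

# Regimens for the licensed 2009 first-line biologics (and methotrexate).
default_regimens <- function() {
  list(
    CZP = regimen(
      loading_doses = tibble(week = c(0, 2, 4), dose_mg = 400),
      maintenance_dose_mg = 200, maintenance_interval_weeks = 2,
      maintenance_start_week = 6, route = "subcutaneous"
    ),
    ADA_q2w = regimen(
      maintenance_dose_mg = 40, maintenance_interval_weeks = 2,
      maintenance_start_week = 0, route = "subcutaneous"
    ),
    ADA_weekly = regimen(
      maintenance_dose_mg = 40, maintenance_interval_weeks = 1,
      maintenance_start_week = 0, route = "subcutaneous"
    ),
    ETA = regimen( # 25 mg twice weekly
      maintenance_dose_mg = 25, maintenance_interval_weeks = 0.5,
      maintenance_start_week = 0, route = "subcutaneous"
    ),
    IFX3 = regimen(
      loading_doses = tibble(week = c(0, 2, 6), dose_mg = NA_real_),
      mg_per_kg = 3, maintenance_interval_weeks = 8,
      maintenance_start_week = 14, route = "intravenous"
    ),
    IFX5 = regimen(
      loading_doses = tibble(week = c(0, 2, 6), dose_mg = NA_real_),
      mg_per_kg = 5, maintenance_interval_weeks = 8,
      maintenance_start_week = 14, route = "intravenous"
    ),
    MTX = regimen( # 15 mg weekly oral
      maintenance_dose_mg = 15, maintenance_interval_weeks = 1,
      maintenance_start_week = 0, route = "oral"
    )
  )
}

# Loading doses for weight-based regimens carry dose_mg = NA; the cost model
# substitutes mg_per_kg * weight for them.

#' Default treatment strategies
#'
#' The strategy set evaluated in the base case: certolizumab pegol,
#' adalimumab (every 2 weeks and weekly), etanercept and infliximab
#' (3 and 5 mg/kg) as combination therapy with methotrexate, plus the
#' monotherapy arms and methotrexate alone.
#'
#' @return Named list of [treatment_strategy()] objects.
#' @export
default_strategies <- function() {
  reg <- default_regimens()
  combo <- function(name, drug, r) {
    treatment_strategy(name, drug, r, with_methotrexate = TRUE)
  }
  mono <- function(name, drug, r) {
    treatment_strategy(name, drug, r, with_methotrexate = FALSE)
  }
  list(
    "CZP+MTX" = combo("CZP+MTX", "CZP", reg$CZP),
    "ADA+MTX q2w" = combo("ADA+MTX q2w", "ADA", reg$ADA_q2w),
    "ADA+MTX weekly" = combo("ADA+MTX weekly", "ADA", reg$ADA_weekly),
    "ETA+MTX" = combo("ETA+MTX", "ETA", reg$ETA),
    "IFX3+MTX" = combo("IFX3+MTX", "IFX", reg$IFX3),
    "IFX5+MTX" = combo("IFX5+MTX", "IFX", reg$IFX5),
    "MTX" = mono("MTX", "MTX", reg$MTX),
    "CZP mono" = mono("CZP mono", "CZP", reg$CZP),
    "ADA mono q2w" = mono("ADA mono q2w", "ADA", reg$ADA_q2w),
    "ADA mono weekly" = mono("ADA mono weekly", "ADA", reg$ADA_weekly),
    "ETA mono" = mono("ETA mono", "ETA", reg$ETA)
  )
}

#' ACR response probabilities per strategy and assessment timepoint
#'
#' Cumulative ACR20/50/70 response fractions at 3 and 6 months for every
#' strategy, from published indirect-comparison estimates. Values are
#' stored verbatim as cumulative fractions; conversion to exclusive
#' response-category probabilities happens in the transition engine.
#' The 3-month ACR50/70 for adalimumab combination therapy are not
#' published; they are imputed by scaling the 3-month ACR20 with the
#' 6-month ACR50/ACR20 and ACR70/ACR20 ratios and flagged as defaults.
#'
#' @return Tibble with columns `strategy`, `timepoint_months`, `acr20`,
#'   `acr50`, `acr70`, `source`.
#' @export
default_response_table <- function() {
  rows <- tibble::tribble(
    ~group, ~timepoint_months, ~acr20, ~acr50, ~acr70,
    "MTX", 3, 21.5, 7.2, 2.0,
    "MTX", 6, 24.2, 9.7, 3.7,
    "CZP+MTX", 3, 71.1, 35.9, 21.6,
    "CZP+MTX", 6, 77.2, 49.2, 28.2,
    "ADA+MTX", 3, 70.8, NA, NA,
    "ADA+MTX", 6, 61.0, 41.8, 19.7,
    "ETA+MTX", 3, 66.4, 61.1, 23.7,
    "ETA+MTX", 6, 68.5, 66.4, 30.7,
    "IFX+MTX", 3, 58.6, 27.0, 19.6,
    "IFX+MTX", 6, 48.2, 26.1, 11.3,
    "placebo", 3, 14.0, 3.2, 1.1,
    "placebo", 6, 13.1, 5.7, 1.0,
    "CZP mono", 3, 53.3, 45.1, 11.6,
    "CZP mono", 6, 55.9, 31.4, 12.3,
    "ADA mono", 3, 55.3, 25.7, 16.4,
    "ADA mono", 6, 39.0, 18.8, 8.5,
    "ETA mono", 3, 46.2, 21.4, 5.1,
    "ETA mono", 6, 62.0, 42.3, 12.9
  )
  rows <- mutate(rows, across(c("acr20", "acr50", "acr70"), ~ .x / 100),
    source = "paper"
  )
  # impute the missing ADA+MTX 3-month cumulative fractions
  ada6 <- filter(rows, .data$group == "ADA+MTX", .data$timepoint_months == 6)
  rows <- rows |>
    mutate(
      acr50 = ifelse(is.na(.data$acr50),
        .data$acr20 * ada6$acr50 / ada6$acr20, .data$acr50
      ),
      acr70 = ifelse(is.na(.data$acr70),
        .data$acr20 * ada6$acr70 / ada6$acr20, .data$acr70
      ),
      source = ifelse(.data$group == "ADA+MTX" & .data$timepoint_months == 3,
        "default", .data$source
      )
    )
  # expand group rows to the strategy labels that share them
  map <- tibble::tribble(
    ~strategy, ~group,
    "CZP+MTX", "CZP+MTX",
    "ADA+MTX q2w", "ADA+MTX",
    "ADA+MTX weekly", "ADA+MTX",
    "ETA+MTX", "ETA+MTX",
    "IFX3+MTX", "IFX+MTX",
    "IFX5+MTX", "IFX+MTX",
    "MTX", "MTX",
    "CZP mono", "CZP mono",
    "ADA mono q2w", "ADA mono",
    "ADA mono weekly", "ADA mono",
    "ETA mono", "ETA mono",
    "placebo", "placebo"
  )
  map |>
    left_join(rows, by = "group", relationship = "many-to-many") |>
    select("strategy", "timepoint_months", "acr20", "acr50", "acr70", "source") |>
    arrange(.data$strategy, .data$timepoint_months)
}
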