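#' Run manifest for a set of outputs
#'
#' Records everything needed to reproduce a run: a stable hash of the
#' configuration, the seed, the scenario list, a timestamp and the
#' package version.
#'
#' @param config A `cea_config`.
#' @param seed Seed used (or `NA`).
#' @param scenarios Character vector of scenario names (or empty).
#' @return A list with `config_hash`, `seed`, `scenarios`, `timestamp`,
#'   `package_version`.
#' @export
run_manifest <- function(config, seed = NA, scenarios = character()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_model_config(config, tmp)
  list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    scenarios = scenarios,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("seqcea"))
  )
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Write base-case results to a directory
#'
#' Evaluates the strategies, writes the per-strategy results and the
#' incremental table as CSV, plus a reproducibility manifest.
#'
#' @param config A `cea_config` or path to a configuration file.
#' @param out_dir Output directory (created if needed).
#' @param strategies Strategy names (default: all configured).
#' @param reference Reference strategy for the incremental table.
#' @return Invisibly, the list of files written.
#' @export
write_base_case <- function(config, out_dir, strategies = NULL, reference = NULL) {
  config <- as_config(config)
  strategies <- strategies %||% names(config$strategies)
  reference <- reference %||% strategies[1]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- evaluate_strategies(config, strategies)
  inc <- incremental_table(res, reference)
  f1 <- file.path(out_dir, "strategy_results.csv")
  f2 <- file.path(out_dir, "incremental_results.csv")
  utils::write.csv(res, f1, row.names = FALSE)
  utils::write.csv(inc, f2, row.names = FALSE)
  write_manifest(run_manifest(config), out_dir)
  invisible(c(f1, f2, file.path(out_dir, "manifest.json")))
}

#' Write one-way sensitivity-analysis results to a directory
#'
#' @param config A `cea_config` or configuration file path.
#' @param scenarios Registered scenario names.
#' @param out_dir Output directory.
#' @param strategies,reference As in [write_base_case()].
#' @return Invisibly, the files written.
#' @export
write_owsa <- function(config, scenarios, out_dir, strategies = NULL,
                       reference = NULL) {
  config <- as_config(config)
  strategies <- strategies %||% names(config$strategies)
  reference <- reference %||% strategies[1]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- run_owsa(config, scenarios, strategies, reference)
  f <- file.path(out_dir, "owsa_results.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  write_manifest(run_manifest(config, scenarios = scenarios), out_dir)
  invisible(c(f, file.path(out_dir, "manifest.json")))
}

#' Write probabilistic sensitivity-analysis results to a directory
#'
#' Writes the per-draw incremental results, the acceptability curves and
#' a manifest including the seed.
#'
#' @param config A `cea_config` or configuration file path.
#' @param out_dir Output directory.
#' @param strategies,reference As in [write_base_case()].
#' @param n_draws Number of PSA draws.
#' @param seed RNG seed.
#' @return Invisibly, the files written.
#' @export
write_psa <- function(config, out_dir, strategies = NULL, reference = NULL,
                      n_draws = 1000, seed = 1) {
  config <- as_config(config)
  strategies <- strategies %||% names(config$strategies)
  reference <- reference %||% strategies[1]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  psa <- run_psa(config, strategies, n_draws = n_draws, seed = seed,
                 reference = reference)
  curves <- ceac(psa)
  f1 <- file.path(out_dir, "psa_draws.csv")
  f2 <- file.path(out_dir, "ceac.csv")
  utils::write.csv(psa, f1, row.names = FALSE)
  utils::write.csv(curves, f2, row.names = FALSE)
  write_manifest(run_manifest(config, seed = seed), out_dir)
  invisible(c(f1, f2, file.path(out_dir, "manifest.json")))
}

#' Write the synthetic fixtures to a directory
#'
#' Exports the synthetic life table (CSV) and the default configuration
#' including the defaults registry (YAML).
#'
#' @param out_dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(out_dir, "life_table.csv")
  f2 <- file.path(out_dir, "default_config.yaml")
  write_life_table(make_synthetic_life_table(), f1)
  write_model_config(default_parameter_set(), f2)
  invisible(c(f1, f2))
}

as_config <- function(config) {
  if (inherits(config, "cea_config")) return(config)
  if (is.character(config)) return(load_model_config(config))
  abort("config must be a cea_config or a file path")
}
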