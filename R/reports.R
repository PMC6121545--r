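#' Assemble a run configuration
#'
#' Resolves file paths and run options into a validated configuration used by
#' the report writers ([report_base()], [report_psa()], [report_owsa()],
#' [report_scenario()]) and by the command-line wrapper shipped at
#' `system.file("cli", "flightnoise", package = "flightnoise")`.
#'
#' @param out_dir Output directory; created if missing.
#' @param params_file Optional YAML parameter file ([read_parameters()]);
#'   default: package base-case parameters.
#' @param life_table_file Optional life-table CSV ([read_life_table()]);
#'   default: the bundled synthetic Gompertz table.
#' @param n_draws PSA draws (default 10,000).
#' @param seed Integer seed.
#' @param wtp WTP grid for the acceptability curve.
#' @param population_65 Exposed population for the stricter-threshold
#'   scenario; `NA` unless supplied.
#' @param verbose Emit progress messages to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       params_file = NULL,
                       life_table_file = NULL,
                       n_draws = 10000,
                       seed = 1,
                       wtp = seq(0, 200000, by = 1000),
                       population_65 = NA_real_,
                       verbose = TRUE) {
  if (n_draws < 1) stop("`n_draws` must be >= 1", call. = FALSE)
  for (f in c(params_file, life_table_file)) {
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- if (is.null(params_file)) cea_parameters() else read_parameters(params_file)
  table <- if (is.null(life_table_file)) {
    bundled <- system.file("extdata", "life_table_synthetic.csv", package = "flightnoise")
    if (nzchar(bundled)) read_life_table(bundled) else gompertz_life_table()
  } else {
    read_life_table(life_table_file)
  }
  structure(
    list(
      out_dir = out_dir, params = params, table = table,
      params_file = params_file, life_table_file = life_table_file,
      n_draws = n_draws, seed = as.integer(seed), wtp = wtp,
      population_65 = population_65, verbose = verbose
    ),
    class = "run_config"
  )
}

log_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[flightnoise] ", ...)
}

log_config <- function(config, what) {
  log_msg(
    config,
    sprintf(
      "%s | params=%s life_table=%s n_draws=%d seed=%d out=%s",
      what,
      config$params_file %||% "<default>",
      config$life_table_file %||% "<bundled synthetic>",
      config$n_draws, config$seed, config$out_dir
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the base-case report
#'
#' Runs the deterministic base case and writes `base_case.csv` (one row per
#' arm plus the incremental row) and `base_case_summary.txt`.
#'
#' @param config A `run_config`.
#' @return The `cea_result`, invisibly.
#' @export
report_base <- function(config) {
  log_config(config, "base case")
  res <- run_cea(config$params, config$table)
  readr::write_csv(tidy(res), file.path(config$out_dir, "base_case.csv"))
  g <- glance(res)
  writeLines(
    c(
      sprintf("incremental cost:  $%.2f", g$inc_cost),
      sprintf("incremental QALYs: %.4f", g$inc_qalys),
      sprintf("ICER:              $%.0f/QALY (%s)", g$icer, g$dominance)
    ),
    file.path(config$out_dir, "base_case_summary.txt")
  )
  log_msg(config, sprintf("ICER $%.0f/QALY (%s)", g$icer, g$dominance))
  invisible(res)
}

#' Write the probabilistic sensitivity analysis report
#'
#' Runs the PSA and writes `psa_samples.csv` (per-draw incremental costs and
#' QALYs), `ceac.csv`, `psa_summary.csv`, and plot files for the
#' cost-effectiveness plane and acceptability curve.
#'
#' @param config A `run_config`.
#' @param plots Also write `ce_plane.pdf` and `ceac.pdf`.
#' @return A list with `psa`, `ceac`, `summary`, invisibly.
#' @export
report_psa <- function(config, plots = TRUE) {
  log_config(config, "PSA")
  psa <- run_psa(config$params, config$table, n_draws = config$n_draws, seed = config$seed)
  curve <- ceac(psa, config$wtp)
  smry <- psa_summary(psa)
  readr::write_csv(psa, file.path(config$out_dir, "psa_samples.csv"))
  readr::write_csv(curve, file.path(config$out_dir, "ceac.csv"))
  readr::write_csv(smry, file.path(config$out_dir, "psa_summary.csv"))
  if (plots) {
    ggplot2::ggsave(file.path(config$out_dir, "ce_plane.pdf"), autoplot(psa),
      width = 6, height = 5
    )
    ggplot2::ggsave(file.path(config$out_dir, "ceac.pdf"), plot_ceac(curve),
      width = 6, height = 4
    )
  }
  log_msg(config, sprintf(
    "cost-saving in %.1f%% of draws; CEAC %.0f%% at $50k, %.0f%% at $100k",
    100 * smry$p_cost_saving, 100 * smry$ceac_at_50k, 100 * smry$ceac_at_100k
  ))
  invisible(list(psa = psa, ceac = curve, summary = smry))
}

#' Write the one-way sensitivity (tornado) report
#'
#' @param config A `run_config`.
#' @param ranges Ranges tibble (default [default_owsa_ranges()]).
#' @param plots Also write `tornado.pdf`.
#' @return The `cea_tornado` tibble, invisibly.
#' @export
report_owsa <- function(config, ranges = default_owsa_ranges(), plots = TRUE) {
  log_config(config, "one-way sensitivity")
  tor <- tornado_analysis(config$params, config$table, ranges)
  readr::write_csv(tor, file.path(config$out_dir, "tornado.csv"))
  if (plots) {
    ggplot2::ggsave(file.path(config$out_dir, "tornado.pdf"), autoplot(tor),
      width = 7, height = 5
    )
  }
  invisible(tor)
}

#' Write the stricter-threshold scenario report
#'
#' @param config A `run_config` with `population_65` set.
#' @return The scenario `cea_result`, invisibly.
#' @export
report_scenario <- function(config) {
  if (is.na(config$population_65)) {
    stop("`population_65` must be set in the configuration for the scenario report",
      call. = FALSE
    )
  }
  log_config(config, "65 dB scenario")
  res <- scenario_population(config$params, config$table, config$population_65)
  readr::write_csv(tidy(res), file.path(config$out_dir, "scenario_65db.csv"))
  g <- glance(res)
  log_msg(config, sprintf("scenario ICER $%.0f/QALY (%s)", g$icer, g$dominance))
  invisible(res)
}

#' Materialise the synthetic input fixtures
#'
#' Writes the default parameter YAML, the synthetic life table CSV, and the
#' income distribution CSV into a directory, so external tools can consume
#' the same inputs the package generates in code.
#'
#' @param dir Target directory; created if missing.
#' @return Paths of the written files, invisibly.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inputs <- generate_reference_inputs()
  paths <- c(
    params = file.path(dir, "parameters.yaml"),
    life_table = file.path(dir, "life_table_synthetic.csv"),
    income = file.path(dir, "income_distribution.csv")
  )
  write_parameters(inputs$params, paths["params"])
  write_life_table(inputs$life_table, paths["life_table"])
  readr::write_csv(tibble::as_tibble(unclass(inputs$income)), paths["income"])
  invisible(paths)
}
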