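# End-to-end scenario runner, configuration, and fixture generation.

#' Run configuration
#'
#' @param projection A `population_projection`, a path to a Eurostat bulk
#'   TSV extract, or `"eu-preset"` for the synthetic EU-like demography.
#' @param scenarios Scenario ids to run; the reference is always run
#'   (and calibrated) first.
#' @param drug_year Drug introduction year (use a year beyond the
#'   horizon as a sentinel for "never").
#' @param prev A [prevalence_model()] (overrides for curve parameters).
#' @param cost_table A [stage_cost_table()].
#' @param report_years Years reported in comparison tables.
#' @param output_dir Directory for CSV outputs, or `NULL` to skip writing.
#' @param seed Integer seed forwarded to the synthetic generator.
#' @return An object of class `run_config`.
#' @export
run_config <- function(projection = "eu-preset",
                       scenarios = scenario_ids(),
                       drug_year = 2023,
                       prev = prevalence_model(),
                       cost_table = stage_cost_table(),
                       report_years = c(2030, 2040, 2050, 2060, 2070, 2080),
                       output_dir = NULL,
                       seed = 1L) {
  bad <- setdiff(scenarios, scenario_ids())
  if (length(bad))
    stop("unknown scenario(s): ", paste(bad, collapse = ", "),
         "; valid ids: ", paste(scenario_ids(), collapse = ", "), call. = FALSE)
  structure(list(projection = projection, scenarios = unique(scenarios),
                 drug_year = as.integer(drug_year), prev = prev,
                 cost_table = cost_table, report_years = report_years,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

resolve_projection <- function(config) {
  p <- config$projection
  if (inherits(p, "population_projection")) return(p)
  if (identical(p, "eu-preset"))
    return(generate_projection(eu_preset_config(seed = config$seed)))
  if (is.character(p) && length(p) == 1L && file.exists(p))
    return(read_eurostat_tsv(p))
  stop("`projection` must be a population_projection, 'eu-preset', or a ",
       "path to a Eurostat TSV extract", call. = FALSE)
}

#' Run the full scenario battery
#'
#' Resolves the demographic projection, calibrates incidence and healthy
#' mortality once on the reference scenario, then simulates every
#' requested scenario with the frozen calibration (the shared-calibration
#' rule is enforced here, not left to callers). Produces cost
#' trajectories and scenario-versus-reference comparisons, and -- when
#' `output_dir` is set -- writes trajectory, cost and comparison CSVs
#' plus a run manifest echoing the configuration, calibration
#' diagnostics, and package version. The whole pipeline is deterministic
#' for a fixed configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the projection, the calibration, and
#'   per-scenario `trajectories`, `costs` and `comparisons`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  projection <- resolve_projection(config)
  if (any(!config$report_years %in% projection$years))
    stop("report years outside the projection horizon", call. = FALSE)
  calib <- calibrate(projection, prev = config$prev)

  want <- union("reference", config$scenarios)
  trajectories <- costs <- list()
  for (nm in want) {
    spec <- scenario_spec(nm, drug_year = config$drug_year)
    trajectories[[nm]] <- simulate_scenario(projection, spec, calib)
    costs[[nm]] <- cost_trajectory(trajectories[[nm]], config$cost_table)
  }
  comparisons <- list()
  for (nm in setdiff(want, "reference"))
    comparisons[[nm]] <- compare_costs(costs[["reference"]], costs[[nm]],
                                       years = config$report_years)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    safe <- function(nm) gsub("[^A-Za-z0-9]+", "-", nm)
    for (nm in want) {
      write_trajectory_csv(trajectories[[nm]],
        file.path(config$output_dir, paste0("trajectory-", safe(nm), ".csv")))
      write_cost_csv(costs[[nm]],
        file.path(config$output_dir, paste0("costs-", safe(nm), ".csv")))
    }
    for (nm in names(comparisons))
      write_comparison_csv(comparisons[[nm]],
        file.path(config$output_dir, paste0("comparison-", safe(nm), ".csv")))
    write_age_year_csv(calib$schedule,
                       file.path(config$output_dir, "incidence-schedule.csv"))
    write_age_year_csv(calib$healthy_mortality,
                       file.path(config$output_dir, "healthy-mortality.csv"))
    manifest <- c(
      sprintf("package: adcohort %s", as.character(utils::packageVersion("adcohort"))),
      sprintf("scenarios: %s", paste(want, collapse = ", ")),
      sprintf("drug_year: %d", config$drug_year),
      sprintf("prevalence: a=%g b=%g onset=%g cap=%g", config$prev$a,
              config$prev$b, config$prev$onset_age, config$prev$cap),
      sprintf("report_years: %s", paste(config$report_years, collapse = ", ")),
      sprintf("seed: %d", config$seed),
      sprintf("calibration_clamps: %d", nrow(calib$diagnostics)))
    writeLines(manifest, file.path(config$output_dir, "manifest.txt"))
  }
  invisible(list(projection = projection, calibration = calib,
                 trajectories = trajectories, costs = costs,
                 comparisons = comparisons))
}

#' Small deterministic test bundle
#'
#' A tiny projection (20 ages x 10 years, about 1e5 persons) with its
#' calibration and reference trajectory, sized so a full pipeline run
#' completes in well under a second. Used by the test suite and handy
#' for quick experiments.
#'
#' @param seed Integer seed (forwarded to the generator).
#' @return List with `projection`, `prev`, `calibration` and
#'   `reference` (an `ad_trajectory`).
#' @export
make_fixtures <- function(seed = 1L) {
  cfg <- projection_config(total_base = 1e5, ages = 60:79, years = 2015:2024,
                           old_age_share = NA, seed = seed)
  projection <- generate_projection(cfg)
  prev <- prevalence_model()
  calib <- calibrate(projection, prev = prev)
  list(projection = projection, prev = prev, calibration = calib,
       reference = calib$trajectory)
}
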