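# Frozen reference values, computed once with an independent dense
# linear solve (and cross-checked by Neumann series and Monte Carlo).
baseline_years_from_mild <- c(Mild = 4.9213537839, Moderate = 1.6032279309,
                              Severe = 0.8013157016)
baseline_limit_mix <- c(Mild = 0.6717748699, Moderate = 0.2188438958,
                        Severe = 0.1093812343)
annual_costs_ref <- c(Mild = 23112, Moderate = 40118.40, Severe = 55401.60)

# Expensive shared fixtures, built once per test run.
fixture_env <- new.env(parent = emptyenv())

toy_bundle <- function() {
  if (is.null(fixture_env$toy)) fixture_env$toy <- make_fixtures(seed = 2L)
  fixture_env$toy
}

eu_bundle <- function() {
  if (is.null(fixture_env$eu)) {
    proj <- generate_projection(eu_preset_config())
    fixture_env$eu <- list(projection = proj, calibration = calibrate(proj))
  }
  fixture_env$eu
}

# Small Eurostat-dialect TSV written programmatically.
write_fixture_tsv <- function(path, years = 2015:2017, ages = c("Y64", "Y65", "Y66"),
                              flag_cell = NULL) {
  header <- paste(c("unit,age,geo\\time", years), collapse = "\t")
  lines <- header
  val <- 1000
  for (a in ages) {
    cells <- as.character(val + seq_along(years))
    if (!is.null(flag_cell) && a == ages[1L]) cells[1L] <- flag_cell
    lines <- c(lines, paste(c(paste0("NR,", a, ",EU28"), cells), collapse = "\t"))
    val <- val + 100
  }
  writeLines(lines, path)
  path
}
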