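# Stage-wise cost accounting and scenario comparison reports.

#' Stage cost table
#'
#' Monthly cost per patient in euros, by stage and Drummond cost class:
#' informal (caregiver time, surveillance), nonmedical (day care, home
#' help, alarm services) and medical (visits, hospitalisation,
#' medication). The annual per-patient stage cost is twelve times the
#' row sum.
#'
#' @param monthly 3x3 numeric matrix (stages x classes); the default is
#'   the published table.
#' @return An object of class `stage_cost_table`.
#' @export
stage_cost_table <- function(monthly = NULL) {
  if (is.null(monthly)) {
    monthly <- rbind(Mild     = c(1027.00, 619.00, 280.00),
                     Moderate = c(1676.64, 1432.20, 234.36),
                     Severe   = c(2315.36, 1977.80, 323.64))
  }
  monthly <- as.matrix(monthly)
  if (!identical(dim(monthly), c(3L, 3L)) || any(monthly < 0))
    stop("`monthly` must be a nonnegative 3x3 matrix (stage x cost class)",
         call. = FALSE)
  dimnames(monthly) <- list(stage_names(), c("informal", "nonmedical", "medical"))
  structure(list(monthly = monthly), class = "stage_cost_table")
}

#' Annual per-patient cost of a stage
#'
#' @param stage A stage name, or `NULL` for all three.
#' @param table A [stage_cost_table()].
#' @return Euros per patient-year (named vector if `stage` is `NULL`).
#' @export
annual_stage_cost <- function(stage = NULL, table = stage_cost_table()) {
  stopifnot(inherits(table, "stage_cost_table"))
  ann <- 12 * rowSums(table$monthly)
  if (is.null(stage)) return(ann)
  if (!(stage %in% stage_names()))
    stop("`stage` must be a transient stage", call. = FALSE)
  ann[[stage]]
}

#' Annual costs of a simulated trajectory
#'
#' Multiplies the patient counts per stage and year by the annual stage
#' cost. The `Overall` row is the exact stage sum.
#'
#' @param traj An `ad_trajectory`.
#' @param table A [stage_cost_table()].
#' @return An object of class `cost_trajectory`: `cost` (4 x years
#'   matrix, rows Mild/Moderate/Severe/Overall, euros) plus `years` and
#'   the scenario name.
#' @export
cost_trajectory <- function(traj, table = stage_cost_table()) {
  stopifnot(inherits(traj, "ad_trajectory"))
  ann <- annual_stage_cost(table = table)
  by_stage <- patients_by_stage(traj) * ann
  cost <- rbind(by_stage, Overall = colSums(by_stage))
  structure(list(cost = cost, years = traj$years, scenario = traj$scenario),
            class = "cost_trajectory")
}

#' @export
print.cost_trajectory <- function(x, ...) {
  cat("<cost_trajectory> scenario '", x$scenario, "' (billions of euros)\n",
      sep = "")
  show <- x$years[x$years %% 10 == 0 | x$years == min(x$years)]
  print(round(x$cost[, as.character(show), drop = FALSE] / 1e9, 1))
  invisible(x)
}

#' Average annual cost per patient in a given year
#'
#' @param costs A `cost_trajectory`.
#' @param traj The matching `ad_trajectory`.
#' @param year Calendar year.
#' @return Euros per patient-year.
#' @export
per_patient_average <- function(costs, traj, year) {
  stopifnot(inherits(costs, "cost_trajectory"), inherits(traj, "ad_trajectory"))
  y <- as.character(year)
  if (!(year %in% traj$years)) stop("year outside the trajectory", call. = FALSE)
  total <- sum(traj$patients[, , y])
  if (total <= 0)
    stop("no patients in ", year, "; per-patient average undefined", call. = FALSE)
  costs$cost["Overall", y] / total
}

#' Steady-state average annual cost per patient
#'
#' The cost of one patient-year under the long-run stage mix of the
#' progression law: the limit stage mix from the fundamental matrix
#' (Mild entry) weighted by the annual stage costs. Approximates the
#' per-patient average of a population fed by a steady entrant stream,
#' independent of demography.
#'
#' @param m A `stage_model`.
#' @param table A [stage_cost_table()].
#' @return Euros per patient-year.
#' @export
steady_state_average_cost <- function(m, table = stage_cost_table()) {
  mix <- fundamental_matrix(m)$limit_mix
  sum(mix * annual_stage_cost(table = table))
}

#' Scenario-versus-reference cost comparison
#'
#' For each stage and the overall row, in each selected year: the
#' absolute cost difference (scenario minus reference, billions of
#' euros) and the scenario cost as a percentage of the reference. The
#' stored values are unrounded; [format()] and the CSV writer round to
#' one decimal (billions) and two decimals (percent) for reporting.
#'
#' @param reference,scenario `cost_trajectory` objects on the same year grid.
#' @param years Years to report (default every year common to both).
#' @return An object of class `cost_comparison` with matrices `delta_bn`
#'   and `pct` (4 x length(years)).
#' @export
compare_costs <- function(reference, scenario, years = NULL) {
  stopifnot(inherits(reference, "cost_trajectory"),
            inherits(scenario, "cost_trajectory"))
  if (!identical(reference$years, scenario$years))
    stop("reference and scenario are on different year grids", call. = FALSE)
  if (is.null(years)) years <- reference$years
  if (!all(years %in% reference$years))
    stop("requested years outside the trajectories", call. = FALSE)
  ys <- as.character(years)
  delta <- (scenario$cost[, ys, drop = FALSE] -
            reference$cost[, ys, drop = FALSE]) / 1e9
  pct <- 100 * (scenario$cost[, ys, drop = FALSE] /
                reference$cost[, ys, drop = FALSE])
  structure(list(delta_bn = delta, pct = pct, years = years,
                 scenario = scenario$scenario, reference = reference$scenario),
            class = "cost_comparison")
}

#' @export
print.cost_comparison <- function(x, ...) {
  cat("<cost_comparison> '", x$scenario, "' vs '", x$reference, "'\n", sep = "")
  for (r in rownames(x$delta_bn)) {
    cat(r, "\n")
    tab <- rbind(`delta (bn EUR)` = round(x$delta_bn[r, ], 1),
                 `% of reference` = round(x$pct[r, ], 2))
    colnames(tab) <- x$years
    print(tab)
  }
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' One row per stage and measure (delta in billions to one decimal,
#' percentage of reference to two decimals), one column per reported
#' year; mirrors the published comparison-table layout.
#'
#' @param cmp A `cost_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(cmp, path) {
  stopifnot(inherits(cmp, "cost_comparison"))
  rows <- list()
  for (r in rownames(cmp$delta_bn)) {
    rows[[paste0(r, "_delta_bn")]] <- round(cmp$delta_bn[r, ], 1)
    rows[[paste0(r, "_pct")]] <- round(cmp$pct[r, ], 2)
  }
  df <- data.frame(row = names(rows), do.call(rbind, rows), check.names = FALSE)
  colnames(df) <- c("row", cmp$years)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cost trajectory as CSV
#'
#' @param costs A `cost_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_csv <- function(costs, path) {
  stopifnot(inherits(costs, "cost_trajectory"))
  df <- data.frame(stage = rownames(costs$cost), costs$cost, check.names = FALSE)
  colnames(df) <- c("stage", costs$years)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
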