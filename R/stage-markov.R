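# Disease-stage Markov algebra: the four-state absorbing chain
# (Mild, Moderate, Severe, Death) and everything derived from it.

#' Transient disease stages
#'
#' @return Character vector of the three transient stage labels, in order.
#' @export
stage_names <- function() c("Mild", "Moderate", "Severe")

#' Construct a stage-transition model
#'
#' A one-year disease-progression law over the three transient stages plus
#' an absorbing Death state. `q` holds the transient-to-transient
#' probabilities (row = from-stage); `death` the per-stage one-year death
#' probabilities. Each row of the full chain must be stochastic:
#' `rowSums(q) + death == 1`.
#'
#' @param q 3x3 numeric matrix of transient transition probabilities.
#' @param death Length-3 numeric vector of stage death probabilities.
#' @param name Identifier for the model (scenario id or free text).
#' @return An object of class `stage_model`.
#' @export
stage_model <- function(q, death, name = "custom") {
  q <- as.matrix(q)
  death <- as.numeric(death)
  if (!identical(dim(q), c(3L, 3L)))
    stop("`q` must be a 3x3 matrix (Mild, Moderate, Severe)", call. = FALSE)
  if (length(death) != 3L)
    stop("`death` must have one probability per transient stage", call. = FALSE)
  dimnames(q) <- list(stage_names(), stage_names())
  names(death) <- stage_names()
  m <- structure(list(q = q, death = death, name = as.character(name)[1L]),
                 class = "stage_model")
  validate_stage_model(m)
  m
}

validate_stage_model <- function(m) {
  p <- c(m$q, m$death)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all transition and death probabilities must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(m$q) + m$death
  if (any(abs(rs - 1) > 1e-12))
    stop("each stage row (transitions + death) must sum to 1 within 1e-12; got ",
         paste(format(rs, digits = 15), collapse = ", "), call. = FALSE)
  if (m$q["Severe", "Mild"] != 0)
    stop("two-stage improvement (Severe to Mild) is not part of the model", call. = FALSE)
  invisible(m)
}

#' @export
print.stage_model <- function(x, ...) {
  cat("<stage_model> ", x$name, "\n", sep = "")
  full <- cbind(x$q, Death = x$death)
  print(round(full, 4))
  mult <- attr(x, "incidence_multiplier")
  if (!is.null(mult) && mult != 1)
    cat("incidence multiplier:", mult, "\n")
  invisible(x)
}

#' Baseline disease-progression model
#'
#' One-year stage transition probabilities estimated from the National
#' Alzheimer's Coordinating Centre cohort: Mild stays with probability
#' 0.774, worsens to Moderate 0.158, to Severe 0.013; Moderate improves
#' 0.070, stays 0.501, worsens 0.214; Severe improves 0.028, stays 0.492.
#' Stage death probabilities are 0.055 (Mild), 0.215 (Moderate), 0.480
#' (Severe), so each row closes to 1.
#'
#' @return A `stage_model`.
#' @export
build_baseline_model <- function() {
  q <- rbind(Mild     = c(0.774, 0.158, 0.013),
             Moderate = c(0.070, 0.501, 0.214),
             Severe   = c(0.000, 0.028, 0.492))
  stage_model(q, death = c(0.055, 0.215, 0.480), name = "reference")
}

#' Canonical scenario identifiers
#'
#' The nine scenarios of the study design: the unchanged-treatment
#' reference, five drug scenarios that prolong the expected stay in one
#' stage by one or two years (verbatim adjusted transition matrices), and
#' three prevention scenarios that lower incidence by 10/30/50% while
#' keeping the baseline progression law.
#'
#' @return Character vector of scenario ids.
#' @export
scenario_ids <- function() {
  c("reference", "mild+1", "mild+2", "moderate+1", "moderate+2", "severe+1",
    "mci-10", "mci-30", "mci-50")
}

# Published scenario rows. Probabilities not named in the scenario
# description stay at baseline; the residual that closes the row to 1 goes
# to the death probability (Moderate scenarios) or the stay probability
# (Severe scenario).
scenario_rows <- function() {
  list(
    "mild+1"     = list(stage = "Mild",
                        q = c(Mild = 0.814, Moderate = 0.121, Severe = 0.010),
                        death = 0.055),
    "mild+2"     = list(stage = "Mild",
                        q = c(Mild = 0.844, Moderate = 0.092, Severe = 0.009),
                        death = 0.055),
    "moderate+1" = list(stage = "Moderate",
                        q = c(Mild = 0.050, Moderate = 0.700, Severe = 0.040),
                        death = 0.210),
    "moderate+2" = list(stage = "Moderate",
                        q = c(Mild = 0.040, Moderate = 0.770, Severe = 0.004),
                        death = 0.186),
    "severe+1"   = list(stage = "Severe",
                        q = c(Mild = 0.000, Moderate = 0.028, Severe = 0.772),
                        death = 0.200)
  )
}

mci_multipliers <- function() {
  c("reference" = 1.0, "mci-10" = 0.9, "mci-30" = 0.7, "mci-50" = 0.5)
}

#' Build a named scenario model
#'
#' Returns the progression model attached to a scenario id. The five
#' stage-prolongation scenarios replace one row of the baseline matrix
#' with its published adjusted values; the reference and the three
#' incidence-reduction (MCI) scenarios keep the baseline matrix, the
#' latter carrying an `incidence_multiplier` attribute (0.9, 0.7 or 0.5)
#' consumed by the cohort engine.
#'
#' @param name One of [scenario_ids()].
#' @return A `stage_model`; MCI models carry attribute `incidence_multiplier`.
#' @export
build_scenario_model <- function(name) {
  ids <- scenario_ids()
  if (!is.character(name) || length(name) != 1L || !(name %in% ids))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid ids: ", paste(ids, collapse = ", "), call. = FALSE)
  base <- build_baseline_model()
  if (name %in% names(scenario_rows())) {
    s <- scenario_rows()[[name]]
    q <- base$q; death <- base$death
    q[s$stage, ] <- s$q
    death[s$stage] <- s$death
    return(stage_model(q, death, name = name))
  }
  m <- stage_model(base$q, base$death, name = name)
  attr(m, "incidence_multiplier") <- unname(mci_multipliers()[name])
  if (name == "reference") attr(m, "incidence_multiplier") <- 1.0
  m
}

#' Fundamental matrix of the absorbing chain
#'
#' For the transient block `Q`, the fundamental matrix `N = (I - Q)^-1`
#' gives in entry (i, j) the expected total number of years spent in stage
#' j before death, for a patient entering in stage i. Since all new
#' patients enter at Mild, the Mild row is the study's sojourn metric, and
#' its normalisation (`limit_mix`) is the long-run stage mix of a patient
#' population fed by a steady stream of Mild entrants; it is used to split
#' prevalent patients across stages at simulation start.
#'
#' @param m A `stage_model`.
#' @return An object of class `fundamental_summary` with elements `n`
#'   (3x3 matrix), `years_from_mild` (Mild row of `n`) and `limit_mix`
#'   (that row normalised to sum 1).
#' @export
fundamental_matrix <- function(m) {
  validate_stage_model(m)
  im <- diag(3) - m$q
  n <- tryCatch(solve(im), error = function(e)
    stop("(I - Q) is singular: some transient stage has no exit", call. = FALSE))
  if (any(!is.finite(n)) || any(n < -1e-9))
    stop("(I - Q) is not invertible to a nonnegative fundamental matrix; ",
         "the transient block must be substochastic", call. = FALSE)
  n[n < 0] <- 0
  dimnames(n) <- dimnames(m$q)
  ym <- n["Mild", ]
  structure(list(n = n, years_from_mild = ym, limit_mix = ym / sum(ym)),
            class = "fundamental_summary")
}

#' @export
print.fundamental_summary <- function(x, ...) {
  cat("<fundamental_summary>\n")
  cat("expected years by stage (entry at Mild):\n")
  print(round(x$years_from_mild, 3))
  cat("limit stage mix:\n")
  print(round(x$limit_mix, 4))
  invisible(x)
}

#' Expected years per stage from a given entry stage
#'
#' The entry-stage row of the fundamental matrix: expected total years a
#' patient entering at `entry` spends in each transient stage before
#' death. Scenario comparisons always use `entry = "Mild"` because all
#' incident patients enter there.
#'
#' @param m A `stage_model`.
#' @param entry Entry stage, one of [stage_names()].
#' @return Named length-3 numeric vector of expected years.
#' @export
expected_stage_years <- function(m, entry = "Mild") {
  if (!(is.character(entry) && length(entry) == 1L && entry %in% stage_names()))
    stop("`entry` must be a transient stage (", paste(stage_names(), collapse = ", "),
         "); Death is absorbing and has no sojourn", call. = FALSE)
  fundamental_matrix(m)$n[entry, ]
}

#' Solve for transition probabilities that prolong a stage sojourn
#'
#' Finds the one-year law under which the expected total years spent in
#' `stage` (for a Mild entrant) exceed the input model's by exactly
#' `delta`. The built-in policy mirrors the published drug scenarios: all
#' worsening probabilities out of `stage` are scaled by a common factor
#' `alpha` in (0, 1], the stage death probability is held fixed, and the
#' freed mass is absorbed into the stay probability. Severe has no onward
#' worsening, so there the policy instead lowers the death probability
#' (stay absorbing the mass). The scalar equation is solved by bisection
#' on the fundamental-matrix sojourn to within 1e-9 years.
#'
#' @param m A `stage_model` (the pre-drug law).
#' @param stage Stage whose sojourn is prolonged.
#' @param delta Additional expected years required (>= 0).
#' @param policy Adjustment policy; only `"proportional-worsening"` is built in.
#' @return A `stage_model` meeting the sojourn target.
#' @export
solve_prolongation <- function(m, stage, delta,
                               policy = "proportional-worsening") {
  validate_stage_model(m)
  policy <- match.arg(policy, "proportional-worsening")
  if (!(is.character(stage) && length(stage) == 1L && stage %in% stage_names()))
    stop("`stage` must be one of ", paste(stage_names(), collapse = ", "), call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta < 0)
    stop("`delta` must be a single nonnegative number of years", call. = FALSE)
  if (delta == 0) return(m)

  base_years <- fundamental_matrix(m)$years_from_mild[[stage]]
  target <- base_years + delta

  if (stage == "Severe") {
    # No onward worsening exists: prolong by lowering death, stay absorbs.
    d0 <- m$death["Severe"]
    at <- function(d) {
      q <- m$q; death <- m$death
      q["Severe", "Severe"] <- q["Severe", "Severe"] + (d0 - d)
      death["Severe"] <- d
      stage_model(q, death, name = m$name)
    }
    metric <- function(d) fundamental_matrix(at(d))$years_from_mild[["Severe"]]
    lo <- 1e-12
    max_years <- metric(lo)
    if (target > max_years)
      stop(sprintf(paste0("requested prolongation of %.3f years in Severe is ",
                          "unreachable; the attainable maximum is %.3f additional years"),
                   delta, max_years - base_years), call. = FALSE)
    root <- stats::uniroot(function(d) metric(d) - target, c(lo, d0),
                           tol = .Machine$double.eps^0.75)$root
    out <- at(root)
  } else {
    worse <- which(seq_len(3) > match(stage, stage_names()))
    w0 <- m$q[stage, worse]
    at <- function(alpha) {
      q <- m$q
      q[stage, worse] <- w0 * alpha
      q[stage, stage] <- 1 - m$death[stage] - sum(q[stage, -match(stage, stage_names())])
      stage_model(q, m$death, name = m$name)
    }
    metric <- function(alpha) fundamental_matrix(at(alpha))$years_from_mild[[stage]]
    lo <- 1e-12
    max_years <- metric(lo)
    if (target > max_years)
      stop(sprintf(paste0("requested prolongation of %.3f years in %s is ",
                          "unreachable; the attainable maximum is %.3f additional years"),
                   delta, stage, max_years - base_years), call. = FALSE)
    root <- stats::uniroot(function(a) metric(a) - target, c(lo, 1),
                           tol = .Machine$double.eps^0.75)$root
    out <- at(root)
  }
  achieved <- fundamental_matrix(out)$years_from_mild[[stage]]
  stopifnot(abs(achieved - target) <= 1e-9)
  out$name <- sprintf("%s|%s+%g", m$name, stage, delta)
  out
}

#' Monte-Carlo sojourn oracle
#'
#' Simulates independent patients entering at Mild and stepping the
#' four-state chain yearly until death, and returns the empirical mean
#' years spent in each transient stage with standard errors. A stochastic
#' cross-check on the fundamental-matrix sojourns; reproducible given
#' `seed`.
#'
#' @param m A `stage_model`.
#' @param walkers Number of simulated patients (>= 1).
#' @param seed Integer RNG seed.
#' @return List with `mean_years`, `se` (both named length-3) and `walkers`.
#' @export
mc_stage_walk <- function(m, walkers, seed = 1L) {
  validate_stage_model(m)
  walkers <- as.integer(walkers)
  if (is.na(walkers) || walkers < 1L) stop("`walkers` must be >= 1", call. = FALSE)
  cum <- t(apply(cbind(m$q, m$death), 1L, cumsum))
  cum[, 4L] <- 1  # guard rounding in the final column
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  years <- matrix(0, nrow = walkers, ncol = 3L,
                  dimnames = list(NULL, stage_names()))
  idx <- seq_len(walkers)
  state <- rep.int(1L, walkers)
  while (length(idx)) {
    years[cbind(idx, state)] <- years[cbind(idx, state)] + 1
    u <- stats::runif(length(idx))
    nxt <- 1L + (u > cum[state, 1L]) + (u > cum[state, 2L]) + (u > cum[state, 3L])
    alive <- nxt < 4L
    idx <- idx[alive]
    state <- nxt[alive]
  }
  list(mean_years = colMeans(years),
       se = apply(years, 2L, stats::sd) / sqrt(walkers),
       walkers = walkers)
}

#' Serialise a stage model to a flat key-value vector
#'
#' Keys are `<from>.<to>` for transient transitions, `<stage>.Death` for
#' death probabilities, plus `name`. [stage_model_from_config()] inverts it.
#'
#' @param m A `stage_model`.
#' @return Named character vector.
#' @export
stage_model_to_config <- function(m) {
  validate_stage_model(m)
  out <- character(0)
  for (i in stage_names()) for (j in stage_names())
    out[paste(i, j, sep = ".")] <- format(m$q[i, j], digits = 17)
  for (i in stage_names())
    out[paste(i, "Death", sep = ".")] <- format(m$death[i], digits = 17)
  out["name"] <- m$name
  out
}

#' @rdname stage_model_to_config
#' @param config Named character vector as produced by [stage_model_to_config()].
#' @export
stage_model_from_config <- function(config) {
  q <- matrix(0, 3, 3, dimnames = list(stage_names(), stage_names()))
  death <- numeric(3); names(death) <- stage_names()
  for (i in stage_names()) {
    for (j in stage_names()) q[i, j] <- as.numeric(config[[paste(i, j, sep = ".")]])
    death[i] <- as.numeric(config[[paste(i, "Death", sep = ".")]])
  }
  stage_model(q, death, name = if ("name" %in% names(config)) config[["name"]] else "custom")
}
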