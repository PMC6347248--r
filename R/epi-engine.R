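# Cohort simulation engine: exponential age-prevalence curve, first-run
# incidence calibration and healthy-mortality derivation, yearly state
# update, scenario execution.

#' Age-prevalence model
#'
#' Prevalence of diagnosed disease as an exponential function of age:
#' `a * exp(b * (age - onset_age))`, zero below `onset_age` and clamped
#' to `cap`. With the defaults the curve gives 1.42% at the onset age 60
#' and about 25.9% at 85; the raw exponential would exceed 1 near age 97,
#' hence the cap.
#'
#' @param a Prevalence at the onset age (default 0.0142).
#' @param b Exponential slope per year of age (default 0.1161).
#' @param onset_age Age at which the curve starts (prevalence 0 below).
#' @param cap Maximum prevalence, in [0, 1).
#' @return An object of class `prevalence_model`.
#' @export
prevalence_model <- function(a = 0.0142, b = 0.1161, onset_age = 60, cap = 0.95) {
  if (a < 0 || b < 0 || cap < 0 || cap >= 1)
    stop("need a >= 0, b >= 0 and cap in [0, 1)", call. = FALSE)
  structure(list(a = a, b = b, onset_age = onset_age, cap = cap),
            class = "prevalence_model")
}

#' Evaluate the prevalence curve
#'
#' @param age Numeric vector of ages.
#' @param model A [prevalence_model()].
#' @return Prevalence per age, in [0, cap].
#' @export
prevalence <- function(age, model = prevalence_model()) {
  stopifnot(inherits(model, "prevalence_model"))
  ifelse(age < model$onset_age, 0,
         pmin(model$a * exp(model$b * (age - model$onset_age)), model$cap))
}

#' Initial split of prevalent patients across stages
#'
#' At the start of the simulation every age's prevalent patients
#' (`prevalence(a) * counts[a, first year]`) are distributed over the
#' three stages according to the limit stage mix of the progression
#' chain (see [fundamental_matrix()]).
#'
#' @param projection A `population_projection`.
#' @param prev A `prevalence_model`.
#' @param mix Length-3 simplex vector (stage shares, Mild/Moderate/Severe).
#' @return List with `patients` (3 x ages matrix) and `healthy` (vector).
#' @export
initial_patient_state <- function(projection, prev = prevalence_model(),
                                  mix = fundamental_matrix(build_baseline_model())$limit_mix) {
  stopifnot(inherits(projection, "population_projection"))
  mix <- as.numeric(mix)
  if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    stop("`mix` must be a length-3 vector on the simplex", call. = FALSE)
  p0 <- prevalence(projection$ages, prev) * projection$counts[, 1L]
  patients <- rbind(Mild = mix[1L] * p0, Moderate = mix[2L] * p0,
                    Severe = mix[3L] * p0)
  colnames(patients) <- projection$ages
  list(patients = patients, healthy = projection$counts[, 1L] - p0)
}

#' Scenario specification
#'
#' Bundles a scenario id with its progression model, incidence
#' multiplier, and the drug introduction year. Before `drug_year` every
#' scenario runs under the baseline law with multiplier 1.
#'
#' @param name One of [scenario_ids()], or any name if `model` is given.
#' @param drug_year First calendar year in which the scenario law applies.
#' @param model Optional explicit `stage_model` (defaults to the
#'   registered scenario model).
#' @param multiplier Optional incidence multiplier from `drug_year` on.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, drug_year = 2023, model = NULL, multiplier = NULL) {
  if (is.null(model)) {
    model <- build_scenario_model(name)   # validates the id
  } else if (!inherits(model, "stage_model")) {
    stop("`model` must be a stage_model", call. = FALSE)
  }
  if (is.null(multiplier)) {
    multiplier <- attr(model, "incidence_multiplier")
    if (is.null(multiplier)) multiplier <- 1.0
  }
  if (multiplier < 0 || multiplier > 1)
    stop("`multiplier` must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, model = model, drug_year = as.integer(drug_year),
                 multiplier = multiplier),
            class = "scenario_spec")
}

# The single yearly-update engine used by both calibration and scenario
# simulation, so that the reference scenario reproduces the calibration
# run bit for bit. Step order within year t -> t+1:
#   1. patient deaths by stage-specific probability;
#   2. stage transitions among survivors (law conditioned on survival);
#   3. healthy deaths (derived table, or derived on the fly when calibrating);
#   4. ageing by one year (closed top age; entry age refilled from the
#      projection, all healthy);
#   5. new Mild entrants drawn from the healthy pool by the incidence
#      schedule times the scenario multiplier.
# The scenario law and multiplier apply to steps starting in drug_year or
# later.
run_engine <- function(projection, prev, mix, base_model, spec,
                       schedule = NULL, healthy_mortality = NULL,
                       calibrating = FALSE) {
  ages <- projection$ages; years <- projection$years
  na <- length(ages); nt <- length(years)
  counts <- projection$counts
  init <- initial_patient_state(projection, prev, mix)

  healthy <- matrix(0, na, nt, dimnames = list(ages, years))
  patients <- array(0, dim = c(3L, na, nt),
                    dimnames = list(stage_names(), ages, years))
  healthy[, 1L] <- init$healthy
  patients[, , 1L] <- init$patients
  ad_deaths <- healthy_deaths <- stats::setNames(numeric(nt), years)

  if (calibrating) {
    schedule <- matrix(0, na, nt - 1L, dimnames = list(ages, years[-nt]))
    healthy_mortality <- matrix(0, na, nt - 1L, dimnames = list(ages, years[-nt]))
    diagnostics <- list()
  }
  target_prev <- prevalence(ages, prev)

  cond_law <- function(m) {
    tm <- m$q / (1 - m$death)        # survival-conditioned transition law
    t(tm)
  }
  base_cond <- cond_law(base_model)
  scen_cond <- cond_law(spec$model)

  for (t in seq_len(nt - 1L)) {
    active <- years[t] >= spec$drug_year
    mdl <- if (active) spec$model else base_model
    tcond <- if (active) scen_cond else base_cond
    mult <- if (active) spec$multiplier else 1.0

    P <- patients[, , t]
    ad_d <- colSums(P * mdl$death)               # death recycles over rows
    surv <- P * (1 - mdl$death)
    moved <- tcond %*% surv

    if (calibrating) {
      hd_raw <- projection$cohort_deaths[, t] - ad_d
      hm <- ifelse(healthy[, t] > 0, hd_raw / healthy[, t], 0)
      n_floor <- sum(hm < 0); n_cap <- sum(hm > 1)
      if (n_floor + n_cap > 0)
        diagnostics[[length(diagnostics) + 1L]] <-
          data.frame(year = years[t], type = "healthy_mortality_clip",
                     n_floored = n_floor, n_capped = n_cap)
      hm <- pmin(pmax(hm, 0), 1)
      healthy_mortality[, t] <- hm
    } else {
      hm <- healthy_mortality[, t]
    }
    h_d <- healthy[, t] * hm
    h_surv <- healthy[, t] - h_d

    # ageing (closed top age); entry age refilled from the projection
    h_next <- c(counts[1L, t + 1L], h_surv[1:(na - 1L)])
    h_next[na] <- h_next[na] + h_surv[na]
    P_next <- cbind(0, moved[, 1:(na - 1L), drop = FALSE])
    P_next[, na] <- P_next[, na] + moved[, na]

    if (calibrating) {
      target <- target_prev * counts[, t + 1L]
      have <- colSums(P_next)
      want <- pmax(target - have, 0)
      over <- sum(have > target * (1 + 1e-12) & target > 0)
      short <- want > h_next
      if (over > 0 || any(short))
        diagnostics[[length(diagnostics) + 1L]] <-
          data.frame(year = years[t + 1L], type = "entrant_gap",
                     n_floored = over, n_capped = sum(short))
      ent_target <- pmin(want, h_next)
      schedule[, t] <- ifelse(h_next > 0, ent_target / h_next, 0)
    }
    entrants <- schedule[, t] * mult * h_next
    P_next["Mild", ] <- P_next["Mild", ] + entrants
    h_next <- h_next - entrants

    healthy[, t + 1L] <- h_next
    patients[, , t + 1L] <- P_next
    ad_deaths[t] <- sum(ad_d)
    healthy_deaths[t] <- sum(h_d)
  }

  traj <- structure(list(healthy = healthy, patients = patients,
                         ad_deaths = ad_deaths, healthy_deaths = healthy_deaths,
                         ages = ages, years = years, scenario = spec$name),
                    class = "ad_trajectory")
  if (!calibrating) return(traj)
  list(trajectory = traj, schedule = schedule,
       healthy_mortality = healthy_mortality,
       diagnostics = if (length(diagnostics)) do.call(rbind, diagnostics)
                     else data.frame(year = integer(0), type = character(0),
                                     n_floored = integer(0), n_capped = integer(0)))
}

#' Calibrate incidence and healthy mortality on the reference run
#'
#' Runs the yearly update once under the baseline law and, in each year
#' and age, sets the number of new Mild entrants so that post-update
#' patient counts match the prevalence curve applied to the projected
#' population (floored at zero where surviving patients already exceed
#' the target, and truncated by the available healthy pool; both events
#' are recorded in the diagnostics). The resulting incidence schedule
#' (entrants / healthy pool) and the healthy-mortality table (cohort
#' deaths minus model disease deaths, over the healthy count, clipped to
#' [0, 1]) are frozen and reused verbatim by every scenario.
#'
#' @param projection A `population_projection`.
#' @param prev A `prevalence_model`.
#' @param model Baseline `stage_model`.
#' @return An object of class `ad_calibration`: `schedule`,
#'   `healthy_mortality` (both ages x years-1), the reference
#'   `trajectory`, clamp `diagnostics`, and the inputs (`prev`, `mix`,
#'   `model`).
#' @export
calibrate <- function(projection, prev = prevalence_model(),
                      model = build_baseline_model()) {
  stopifnot(inherits(projection, "population_projection"))
  mix <- fundamental_matrix(model)$limit_mix
  ref <- scenario_spec("reference", drug_year = max(projection$years) + 1L,
                       model = model, multiplier = 1.0)
  out <- run_engine(projection, prev, mix, model, ref, calibrating = TRUE)
  structure(list(schedule = out$schedule,
                 healthy_mortality = out$healthy_mortality,
                 trajectory = out$trajectory,
                 diagnostics = out$diagnostics,
                 prev = prev, mix = mix, model = model),
            class = "ad_calibration")
}

#' @export
print.ad_calibration <- function(x, ...) {
  cat("<ad_calibration> ", ncol(x$schedule), " calibrated years, ",
      nrow(x$schedule), " ages\n", sep = "")
  if (nrow(x$diagnostics)) {
    cat("clamping events:\n"); print(x$diagnostics)
  } else cat("no clamping events\n")
  invisible(x)
}

#' Simulate a scenario with frozen calibration inputs
#'
#' Deterministic expected-value propagation of healthy persons and staged
#' patients through the yearly update, using the incidence schedule and
#' healthy-mortality table of the calibration. The scenario's progression
#' law and incidence multiplier take effect in `drug_year`; the reference
#' scenario reproduces the calibration trajectory exactly.
#'
#' @param projection The `population_projection` used for calibration.
#' @param spec A [scenario_spec()].
#' @param calibration An [calibrate()] result.
#' @return An `ad_trajectory`: `healthy` (ages x years), `patients`
#'   (3 x ages x years), yearly `ad_deaths` and `healthy_deaths`.
#' @export
simulate_scenario <- function(projection, spec, calibration) {
  stopifnot(inherits(projection, "population_projection"),
            inherits(calibration, "ad_calibration"))
  if (!inherits(spec, "scenario_spec")) {
    if (is.character(spec)) spec <- scenario_spec(spec)
    else stop("`spec` must be a scenario_spec or a scenario id", call. = FALSE)
  }
  validate_stage_model(spec$model)
  run_engine(projection, calibration$prev, calibration$mix,
             calibration$model, spec,
             schedule = calibration$schedule,
             healthy_mortality = calibration$healthy_mortality)
}

#' @export
print.ad_trajectory <- function(x, ...) {
  cat("<ad_trajectory> scenario '", x$scenario, "', years ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  tot <- apply(x$patients, 3L, sum)
  show <- x$years[x$years %% 10 == 0 | x$years == min(x$years)]
  cat("patients (millions):\n")
  print(round(tot[as.character(show)] / 1e6, 2))
  invisible(x)
}

#' Total patients by stage and year
#'
#' @param traj An `ad_trajectory`.
#' @return 3 x years matrix of patient counts summed over ages.
#' @export
patients_by_stage <- function(traj) {
  stopifnot(inherits(traj, "ad_trajectory"))
  apply(traj$patients, c(1L, 3L), sum)
}

#' Write a trajectory as tidy CSV
#'
#' Long format with columns year, age, compartment
#' (healthy/Mild/Moderate/Severe) and count.
#'
#' @param traj An `ad_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ad_trajectory"))
  grid <- expand.grid(age = traj$ages, year = traj$years)
  out <- data.frame(year = grid$year, age = grid$age,
                    compartment = "healthy", count = as.vector(traj$healthy))
  for (s in stage_names()) {
    out <- rbind(out, data.frame(year = grid$year, age = grid$age,
                                 compartment = s,
                                 count = as.vector(traj$patients[s, , ])))
  }
  utils::write.csv(out[order(out$year, out$age, out$compartment), ],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stochastic individual-based oracle for the cohort engine
#'
#' Replays the yearly update on a small projection with every death,
#' stage transition and disease onset sampled as an individual Bernoulli
#' or multinomial event, in the same order and with the same
#' probabilities as the deterministic engine. Counts are integerised by
#' rounding at initialisation. Because every sampling step is linear in
#' the state, the deterministic engine propagates the exact expectation
#' of this process; the oracle validates it within Monte-Carlo error.
#'
#' @param projection A small `population_projection` (about 1e5 persons).
#' @param spec A [scenario_spec()].
#' @param calibration An [calibrate()] result for the same projection.
#' @param seed Integer RNG seed.
#' @return An `ad_trajectory` with integer counts.
#' @export
micro_oracle <- function(projection, spec, calibration, seed = 1L) {
  stopifnot(inherits(projection, "population_projection"),
            inherits(calibration, "ad_calibration"))
  if (is.character(spec)) spec <- scenario_spec(spec)
  ages <- projection$ages; years <- projection$years
  na <- length(ages); nt <- length(years)
  if (sum(projection$counts[, 1L]) > 2e5)
    stop("micro_oracle is meant for small projections (<= ~1e5 persons)", call. = FALSE)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  init <- initial_patient_state(projection, calibration$prev, calibration$mix)
  healthy <- matrix(0, na, nt, dimnames = list(ages, years))
  patients <- array(0, dim = c(3L, na, nt),
                    dimnames = list(stage_names(), ages, years))
  healthy[, 1L] <- round(init$healthy)
  patients[, , 1L] <- round(init$patients)
  ad_deaths <- healthy_deaths <- stats::setNames(numeric(nt), years)

  for (t in seq_len(nt - 1L)) {
    active <- years[t] >= spec$drug_year
    mdl <- if (active) spec$model else calibration$model
    mult <- if (active) spec$multiplier else 1.0
    tm <- mdl$q / (1 - mdl$death)

    P <- patients[, , t]
    moved <- matrix(0, 3L, na)
    ad_d <- 0
    for (a in seq_len(na)) {
      for (s in 1:3) {
        n <- P[s, a]
        if (n == 0) next
        d <- stats::rbinom(1L, n, mdl$death[s])
        ad_d <- ad_d + d
        if (n - d > 0)
          moved[, a] <- moved[, a] + stats::rmultinom(1L, n - d, tm[s, ])
      }
    }
    hm <- calibration$healthy_mortality[, t]
    h_d <- stats::rbinom(na, healthy[, t], hm)
    h_surv <- healthy[, t] - h_d

    h_next <- c(round(projection$counts[1L, t + 1L]), h_surv[1:(na - 1L)])
    h_next[na] <- h_next[na] + h_surv[na]
    P_next <- cbind(0, moved[, 1:(na - 1L), drop = FALSE])
    P_next[, na] <- P_next[, na] + moved[, na]

    rate <- pmin(calibration$schedule[, t] * mult, 1)
    entrants <- stats::rbinom(na, h_next, rate)
    P_next[1L, ] <- P_next[1L, ] + entrants
    h_next <- h_next - entrants

    healthy[, t + 1L] <- h_next
    patients[, , t + 1L] <- P_next
    ad_deaths[t] <- ad_d
    healthy_deaths[t] <- sum(h_d)
  }
  structure(list(healthy = healthy, patients = patients,
                 ad_deaths = ad_deaths, healthy_deaths = healthy_deaths,
                 ages = ages, years = years,
                 scenario = paste0(spec$name, " (micro)")),
            class = "ad_trajectory")
}
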