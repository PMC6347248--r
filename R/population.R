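# Synthetic cohort-component demographic projection (EU-28-like stand-in)
# and cohort mortality extraction.
#
# The preset generates cohort deaths jointly with the disease process
# (disease_consistent = TRUE): healthy persons die under the
# Gompertz-Makeham law while prevalent patients die under the
# progression chain's stage mortality. Because the chain's death
# probabilities are age-independent, a demography whose total old-age
# mortality is far above patient mortality cannot keep the prevalence
# curve attainable (the healthy-mortality derivation would go negative
# and the entrant floor would bind); blending the two laws at prevailing
# prevalence makes the projection internally consistent with the model
# it feeds. Setting disease_consistent = FALSE gives a plain
# demographic projection under the healthy law alone.

#' Configuration for the synthetic population generator
#'
#' Parameters of a closed (default zero-migration) cohort-component
#' projection with single-year ages and a Gompertz-Makeham mortality law
#' mu(a) = makeham_a + gompertz_b * exp(gompertz_c * a), converted to
#' one-year death probabilities q(a) = 1 - exp(-mu(a)). The base-year
#' pyramid is a survival profile times a Gaussian cohort bump centred at
#' `modal_age` whose height is solved so that the share of the population
#' aged 65+ equals `old_age_share`; the profile is scaled to `total_base`
#' persons in the first year. Entry-age counts (age 0 in a full-age
#' projection) follow a geometric path with yearly growth `birth_growth`.
#'
#' @param total_base Total persons in the first projection year.
#' @param ages Integer vector of single-year ages (top age closed).
#' @param years Integer vector of consecutive calendar years.
#' @param modal_age Centre of the large-cohort bump in the base pyramid.
#' @param bump_sd Width (sd, years) of that bump.
#' @param old_age_share Target share of the base-year population aged 65+.
#' @param makeham_a,gompertz_b,gompertz_c Mortality law parameters (per year).
#' @param birth_growth Yearly growth rate of the entry-age cohort size.
#' @param net_migration Scalar, or ages x (years-1) matrix, of net migrants
#'   added to each cohort during each year (default 0: closed cohorts).
#' @param disease_consistent If `TRUE` (default), cohort deaths blend the
#'   healthy mortality law with the stage mortality of prevalent disease
#'   patients (baseline progression model, default prevalence curve), so
#'   the projection is internally consistent with the cohort engine.
#' @param noise_sd If > 0, sd of a lognormal perturbation applied once per
#'   age to the mortality law (the only stochastic element, behind `seed`).
#' @param seed Integer seed for the optional noise.
#' @return An object of class `projection_config`.
#' @export
projection_config <- function(total_base = 5.08e8,
                              ages = 0:100,
                              years = 2015:2080,
                              modal_age = 45,
                              bump_sd = 12,
                              old_age_share = 0.19,
                              makeham_a = 2e-4,
                              gompertz_b = 7.7e-5,
                              gompertz_c = 0.075,
                              birth_growth = -0.002,
                              net_migration = 0,
                              disease_consistent = TRUE,
                              noise_sd = 0,
                              seed = 1L) {
  ages <- as.integer(ages); years <- as.integer(years)
  if (length(ages) < 2L || any(diff(ages) != 1L))
    stop("`ages` must be consecutive single-year ages", call. = FALSE)
  if (length(years) < 2L || any(diff(years) != 1L))
    stop("`years` must be consecutive calendar years", call. = FALSE)
  if (total_base <= 0) stop("`total_base` must be positive", call. = FALSE)
  structure(list(total_base = total_base, ages = ages, years = years,
                 modal_age = modal_age, bump_sd = bump_sd,
                 old_age_share = old_age_share,
                 makeham_a = makeham_a, gompertz_b = gompertz_b,
                 gompertz_c = gompertz_c, birth_growth = birth_growth,
                 net_migration = net_migration,
                 disease_consistent = isTRUE(disease_consistent),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "projection_config")
}

#' EU-28-like preset configuration
#'
#' The default study demography: about 5.08e8 persons in 2015, a large
#' mid-life cohort bump (so the population ages over the horizon), 19% of
#' the population aged 65+ in the base year, closed cohorts (no
#' migration), and a Gompertz-Makeham mortality law kept moderate at the
#' top ages so that the age-independent patient mortality of the disease
#' chain remains compatible with total cohort mortality (see the package
#' vignette).
#'
#' @param ... Overrides passed to [projection_config()].
#' @return A `projection_config`.
#' @export
eu_preset_config <- function(...) {
  args <- list(...)
  do.call(projection_config, args)
}

mortality_curve <- function(config) {
  a <- config$ages
  mu <- config$makeham_a + config$gompertz_b * exp(config$gompertz_c * a)
  if (config$noise_sd > 0) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
    mu <- mu * exp(stats::rnorm(length(a), sd = config$noise_sd))
  }
  q <- 1 - exp(-mu)
  names(q) <- a
  q
}

base_pyramid <- function(config, q) {
  a <- config$ages
  surv <- cumprod(c(1, 1 - q[-length(q)]))
  bump <- exp(-0.5 * ((a - config$modal_age) / config$bump_sd)^2)
  share65 <- function(r) {
    w <- surv * (1 + r * bump)
    sum(w[a >= 65]) / sum(w)
  }
  target <- config$old_age_share
  r <- if (is.null(target) || is.na(target) || !any(a >= 65) ||
           share65(0) <= target) 0
  else if (share65(50) > target)
    stop("`old_age_share` target unreachable for this age range; ",
         "use NA to keep the untilted survival profile", call. = FALSE)
  else stats::uniroot(function(r) share65(r) - target, c(0, 50),
                      tol = .Machine$double.eps^0.5)$root
  w <- surv * (1 + r * bump)
  w / sum(w) * config$total_base
}

#' Generate a synthetic cohort-component projection
#'
#' Builds the base-year pyramid from the configured survival profile and
#' cohort bump, then advances cohorts year by year under the mortality
#' law and net migration, closing the top age (survivors of the top age
#' remain there). In the default disease-consistent mode the healthy
#' mortality law applies to the disease-free share of each cohort while
#' prevalent patients (kept on the prevalence curve, limit-mix stages)
#' die under the progression chain, and cohort deaths are the sum of the
#' two; a plain demographic projection under the healthy law alone is
#' obtained with `disease_consistent = FALSE`. The bookkeeping identity
#' `counts[a+1, t+1] == counts[a, t] - deaths[a, t] + migration[a, t]`
#' holds exactly for every interior age, and the projection is fully
#' deterministic given its configuration.
#'
#' @param config A [projection_config()].
#' @return An object of class `population_projection` with elements
#'   `counts` (ages x years), `cohort_deaths` (ages x years, deaths during
#'   year t of persons aged a at the start of t), `net_migration`,
#'   `mortality` (the ages x years mortality rates actually applied),
#'   `ages`, `years`, and the generating `config`.
#' @export
generate_projection <- function(config) {
  stopifnot(inherits(config, "projection_config"))
  a <- config$ages; y <- config$years
  na <- length(a); nt <- length(y)
  qh <- mortality_curve(config)
  mig <- config$net_migration
  if (is.matrix(mig)) {
    if (!identical(dim(mig), c(na, nt - 1L)))
      stop("`net_migration` matrix must be ages x (years - 1)", call. = FALSE)
  } else {
    mig <- matrix(as.numeric(mig), na, nt - 1L)
  }
  counts <- matrix(0, na, nt, dimnames = list(a, y))
  deaths <- matrix(0, na, nt, dimnames = list(a, y))
  applied <- matrix(0, na, nt, dimnames = list(a, y))
  counts[, 1L] <- base_pyramid(config, qh)
  entry0 <- counts[1L, 1L]

  if (config$disease_consistent) {
    model <- build_baseline_model()
    prev <- prevalence_model()
    mix <- fundamental_matrix(model)$limit_mix
    pr <- prevalence(a, prev)
    P <- outer(mix, pr * counts[, 1L])          # 3 x ages patient stock
    h <- counts[, 1L] - colSums(P)
  }

  for (t in seq_len(nt - 1L)) {
    if (config$disease_consistent) {
      ad_d <- colSums(P * model$death)
      h_d <- h * qh
      deaths[, t] <- ad_d + h_d
      moved <- t(model$q) %*% P
      surv_h <- h - h_d + mig[, t]             # migrants enter the healthy pool
    } else {
      deaths[, t] <- counts[, t] * qh
    }
    surv <- counts[, t] - deaths[, t] + mig[, t]
    nxt <- numeric(na)
    nxt[2:na] <- surv[1:(na - 1L)]
    nxt[na] <- nxt[na] + surv[na]            # closed top age
    nxt[1L] <- entry0 * (1 + config$birth_growth)^t
    if (any(nxt < 0))
      stop("configuration yields negative cohort counts (check migration)",
           call. = FALSE)
    counts[, t + 1L] <- nxt
    applied[, t] <- ifelse(counts[, t] > 0, deaths[, t] / counts[, t], 0)

    if (config$disease_consistent) {
      # age the two subpopulations and top patients up to the curve
      P_next <- cbind(0, moved[, 1:(na - 1L), drop = FALSE])
      P_next[, na] <- P_next[, na] + moved[, na]
      h_next <- c(nxt[1L], surv_h[1:(na - 1L)])
      h_next[na] <- h_next[na] + surv_h[na]
      entrants <- pmin(pmax(pr * nxt - colSums(P_next), 0), h_next)
      P_next[1L, ] <- P_next[1L, ] + entrants
      h_next <- h_next - entrants
      P <- P_next
      h <- pmax(h_next, 0)
    }
  }
  if (config$disease_consistent) {
    deaths[, nt] <- colSums(P * model$death) + h * qh
  } else {
    deaths[, nt] <- counts[, nt] * qh
  }
  applied[, nt] <- ifelse(counts[, nt] > 0, deaths[, nt] / counts[, nt], 0)
  structure(list(counts = counts, cohort_deaths = deaths,
                 net_migration = mig, mortality = applied,
                 ages = a, years = y, config = config),
            class = "population_projection")
}

#' @export
print.population_projection <- function(x, ...) {
  cat("<population_projection> ages ", min(x$ages), "-", max(x$ages),
      ", years ", min(x$years), "-", max(x$years), "\n", sep = "")
  tot <- colSums(x$counts)
  show <- x$years[x$years %% 10 == 0 | x$years == min(x$years)]
  cat("total persons (millions):\n")
  print(round(tot[as.character(show)] / 1e6, 1))
  invisible(x)
}

#' Cohort mortality rates of a projection
#'
#' One-year death probabilities `m[a, t] = deaths[a, t] / counts[a, t]`,
#' clipped to [0, 1]; cells with a zero-count cohort get rate 0 and are
#' reported in the `zero_cohorts` attribute.
#'
#' @param p A `population_projection`.
#' @return Ages x years numeric matrix of mortality probabilities.
#' @export
cohort_mortality <- function(p) {
  stopifnot(inherits(p, "population_projection"))
  m <- p$cohort_deaths / p$counts
  zero <- which(p$counts == 0, arr.ind = TRUE)
  m[p$counts == 0] <- 0
  m <- pmin(pmax(m, 0), 1)
  attr(m, "zero_cohorts") <- zero
  m
}
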