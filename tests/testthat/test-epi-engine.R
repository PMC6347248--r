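test_that("prevalence curve evaluates, clamps, and vanishes below onset", {
  pm <- prevalence_model()
  expect_equal(prevalence(60, pm), 0.0142)
  expect_equal(prevalence(85, pm), 0.0142 * exp(0.1161 * 25), tolerance = 1e-12)
  expect_equal(prevalence(85, pm), 0.2588, tolerance = 1e-3)
  expect_equal(prevalence(100, pm), 0.95) # raw curve exceeds 1 near age 97
  expect_equal(prevalence(c(0, 30, 59.9), pm), c(0, 0, 0))
  expect_error(prevalence_model(cap = 1.2), "cap")
})

test_that("initial patients follow prevalence times the limit mix at every age", {
  proj <- toy_bundle()$projection
  st <- initial_patient_state(proj, prevalence_model(), c(1, 0, 0))
  expect_equal(unname(st$patients["Moderate", ]), rep(0, length(proj$ages)))
  expect_equal(unname(colSums(st$patients)),
               unname(prevalence(proj$ages) * proj$counts[, 1]))
  mix <- baseline_limit_mix
  st2 <- initial_patient_state(proj, prevalence_model(), mix)
  tot <- colSums(st2$patients)
  for (s in stage_names())
    expect_equal(unname(st2$patients[s, tot > 0] / tot[tot > 0]),
                 rep(unname(mix[s]), sum(tot > 0)), tolerance = 1e-12)
  expect_equal(st2$healthy + tot, proj$counts[, 1], ignore_attr = TRUE)
  expect_error(initial_patient_state(proj, mix = c(0.5, 0.5, 0.5)), "simplex")
})

test_that("calibration reproduces the prevalence curve on re-simulation", {
  b <- toy_bundle()
  traj <- simulate_scenario(b$projection, scenario_spec("reference"),
                            b$calibration)
  ptot <- apply(traj$patients, c(2, 3), sum)
  tgt <- prevalence(b$projection$ages, b$prev)
  sim <- ptot / b$projection$counts
  rel <- abs(sim[tgt > 0, ] - tgt[tgt > 0]) / tgt[tgt > 0]
  expect_lt(max(rel), 0.005)
  expect_identical(nrow(b$calibration$diagnostics), 0L)
  expect_true(all(b$calibration$schedule >= 0 & b$calibration$schedule <= 1))
  expect_true(all(b$calibration$healthy_mortality >= 0 &
                  b$calibration$healthy_mortality <= 1))
})

test_that("zero prevalence calibrates to zero incidence and cohort-level healthy mortality", {
  proj <- toy_bundle()$projection
  cal <- calibrate(proj, prev = prevalence_model(a = 0))
  expect_true(all(cal$schedule == 0))
  m <- cohort_mortality(proj)
  expect_equal(cal$healthy_mortality, m[, -ncol(m)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("reference simulation is the calibration fixed point, bit for bit", {
  b <- toy_bundle()
  traj <- simulate_scenario(b$projection, scenario_spec("reference"),
                            b$calibration)
  expect_identical(traj$patients, b$calibration$trajectory$patients)
  expect_identical(traj$healthy, b$calibration$trajectory$healthy)
})

test_that("inactive scenarios collapse onto the reference", {
  b <- toy_bundle()
  ref <- simulate_scenario(b$projection, scenario_spec("reference"), b$calibration)
  # MCI scenario with multiplier forced to 1
  m1 <- simulate_scenario(b$projection,
                          scenario_spec("mci-30", multiplier = 1), b$calibration)
  expect_identical(m1$patients, ref$patients)
  # drug year beyond the horizon never activates
  m2 <- simulate_scenario(b$projection,
                          scenario_spec("mild+1", drug_year = 3000), b$calibration)
  expect_identical(m2$patients, ref$patients)
  expect_error(simulate_scenario(b$projection, 42, b$calibration), "scenario")
})

test_that("cohort counts are conserved and never negative in every scenario", {
  b <- toy_bundle()
  for (id in c("reference", "mild+2", "severe+1", "mci-50")) {
    traj <- simulate_scenario(b$projection, scenario_spec(id, drug_year = 2018),
                              b$calibration)
    expect_true(all(traj$healthy >= 0))
    expect_true(all(traj$patients >= 0))
  }
  ref <- simulate_scenario(b$projection, scenario_spec("reference"), b$calibration)
  tot <- ref$healthy + apply(ref$patients, c(2, 3), sum)
  expect_equal(tot, b$projection$counts, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("incidence multipliers nest patient counts monotonically", {
  b <- eu_bundle()
  tots <- sapply(c("mci-10", "mci-30", "mci-50"), function(id)
    colSums(patients_by_stage(simulate_scenario(b$projection, scenario_spec(id),
                                                b$calibration))))
  ref <- colSums(patients_by_stage(b$calibration$trajectory))
  yrs <- as.character(2024:2080)
  expect_true(all(tots[yrs, "mci-10"] < ref[yrs]))
  expect_true(all(tots[yrs, "mci-30"] < tots[yrs, "mci-10"]))
  expect_true(all(tots[yrs, "mci-50"] < tots[yrs, "mci-30"]))
})

test_that("micro oracle is reproducible, static without events, and tracks the engine", {
  b <- toy_bundle()
  spec <- scenario_spec("reference")
  expect_identical(micro_oracle(b$projection, spec, b$calibration, seed = 9),
                   micro_oracle(b$projection, spec, b$calibration, seed = 9))
  # all probabilities zero: population static along cohort diagonals
  cfg <- projection_config(total_base = 1e4, ages = 60:69, years = 2015:2019,
                           old_age_share = NA, makeham_a = 0, gompertz_b = 0,
                           birth_growth = 0, disease_consistent = FALSE)
  p0 <- generate_projection(cfg)
  cal0 <- calibrate(p0, prev = prevalence_model(a = 0))
  mic0 <- micro_oracle(p0, spec, cal0, seed = 4)
  expect_true(all(mic0$patients == 0))
  for (t in 1:4) # interior ages: survivors age in place (top age pools)
    expect_equal(mic0$healthy[2:9, t + 1], mic0$healthy[1:8, t],
                 ignore_attr = TRUE)
  # agreement with the deterministic engine (expectation is exact; the
  # only systematic gap is integerisation of the initial state)
  det <- patients_by_stage(simulate_scenario(b$projection, spec,
                                             b$calibration))[, "2024"]
  reps <- sapply(1:20, function(i)
    patients_by_stage(micro_oracle(b$projection, spec, b$calibration,
                                   seed = 200 + i))[, "2024"])
  se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  slack <- 0.5 * length(b$projection$ages)
  expect_true(all(abs(rowMeans(reps) - det) <= 3 * se + slack))
})
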