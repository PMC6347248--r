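test_that("baseline model carries the published transition law", {
  m <- build_baseline_model()
  expect_equal(m$q["Mild", "Mild"], 0.774)
  expect_equal(m$q["Mild", "Moderate"], 0.158)
  expect_equal(m$q["Moderate", "Mild"], 0.070)
  expect_equal(m$q["Severe", "Mild"], 0)
  expect_equal(unname(m$death), c(0.055, 0.215, 0.480))
  expect_equal(unname(rowSums(m$q) + m$death), rep(1, 3))
})

test_that("stage model construction rejects invalid probability rows", {
  q <- build_baseline_model()$q
  expect_error(stage_model(q, c(0.05, 0.215, 0.48)), "sum to 1")
  expect_error(stage_model(q * -1, c(0.055, 0.215, 0.48)), "\\[0, 1\\]")
  q2 <- q; q2["Severe", "Mild"] <- 0.01; q2["Severe", "Severe"] <- 0.482
  expect_error(stage_model(q2, c(0.055, 0.215, 0.48)), "two-stage improvement")
})

test_that("scenario models reproduce the published rows with unit-sum residuals", {
  m1 <- build_scenario_model("mild+1")
  expect_equal(unname(m1$q["Mild", ]), c(0.814, 0.121, 0.010))
  expect_equal(unname(m1$death["Mild"]), 0.055)
  m4 <- build_scenario_model("moderate+2")
  expect_equal(unname(m4$q["Moderate", ]), c(0.040, 0.770, 0.004))
  expect_equal(unname(m4$death["Moderate"]), 0.186) # residual closing the row
  m5 <- build_scenario_model("severe+1")
  expect_equal(unname(m5$q["Severe", ]), c(0, 0.028, 0.772)) # stay is the residual
  expect_equal(unname(m5$death["Severe"]), 0.200)
  # untouched rows stay at baseline
  expect_equal(m1$q["Moderate", ], build_baseline_model()$q["Moderate", ])
  expect_error(build_scenario_model("mild+3"), "mild\\+1")
  for (id in scenario_ids()) {
    m <- build_scenario_model(id)
    expect_equal(unname(rowSums(m$q) + m$death), rep(1, 3), tolerance = 1e-14)
  }
  expect_equal(attr(build_scenario_model("mci-30"), "incidence_multiplier"), 0.7)
})

test_that("fundamental matrix gives expected sojourn years and limit mix", {
  fm <- fundamental_matrix(build_baseline_model())
  expect_equal(fm$years_from_mild, baseline_years_from_mild, tolerance = 1e-9)
  expect_equal(fm$limit_mix, baseline_limit_mix, tolerance = 1e-9)
  expect_equal(sum(fm$limit_mix), 1, tolerance = 1e-12)
  expect_equal(fm$n %*% (diag(3) - build_baseline_model()$q), diag(3),
               ignore_attr = TRUE, tolerance = 1e-9)
  # immediate absorption: identity fundamental matrix
  m0 <- stage_model(matrix(0, 3, 3), c(1, 1, 1))
  expect_equal(unname(fundamental_matrix(m0)$years_from_mild), c(1, 0, 0))
  # a stage with no exit makes (I - Q) singular
  qs <- matrix(0, 3, 3); qs[1, 1] <- 1
  expect_error(fundamental_matrix(stage_model(qs, c(0, 1, 1))), "singular|invertible")
})

test_that("fundamental matrix matches the truncated Neumann series", {
  for (id in c("reference", "mild+2", "severe+1")) {
    m <- build_scenario_model(id)
    acc <- diag(3); pk <- diag(3)
    for (k in seq_len(10000)) {
      pk <- pk %*% m$q
      acc <- acc + pk
    }
    expect_equal(fundamental_matrix(m)$n, acc, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("expected stage years match the dense-solve oracle per scenario", {
  yrs <- function(id) expected_stage_years(build_scenario_model(id))
  expect_equal(unname(yrs("mild+1")), c(5.9335, 1.4803, 0.7404), tolerance = 1e-4)
  expect_equal(yrs("moderate+2")[["Moderate"]], 3.4820, tolerance = 1e-4)
  expect_equal(yrs("severe+1")[["Severe"]], 1.8476, tolerance = 1e-4)
  expect_error(expected_stage_years(build_baseline_model(), "Death"), "absorbing")
})

test_that("each published scenario matrix yields its advertised extra years", {
  gains <- c("mild+1" = 1, "mild+2" = 2, "moderate+1" = 1,
             "moderate+2" = 2, "severe+1" = 1)
  targets <- c("mild+1" = "Mild", "mild+2" = "Mild", "moderate+1" = "Moderate",
               "moderate+2" = "Moderate", "severe+1" = "Severe")
  base <- expected_stage_years(build_baseline_model())
  for (id in names(gains)) {
    got <- expected_stage_years(build_scenario_model(id))[[targets[id]]] -
      base[[targets[id]]]
    expect_equal(round(got), unname(gains[id]), ignore_attr = TRUE)
  }
})

test_that("prolongation solver hits the sojourn target and matches the published mild+1 row", {
  base <- build_baseline_model()
  s1 <- solve_prolongation(base, "Mild", 1.0)
  expect_equal(unname(s1$q["Mild", "Mild"]), 0.8135962153, tolerance = 1e-7)
  expect_equal(round(unname(s1$q["Mild", ]), 3), c(0.814, 0.121, 0.010))
  expect_equal(unname(s1$death["Mild"]), 0.055)
  expect_equal(expected_stage_years(s1)[["Mild"]],
               baseline_years_from_mild[["Mild"]] + 1, tolerance = 1e-9)
  # zero prolongation returns the model unchanged
  expect_identical(solve_prolongation(base, "Mild", 0), base)
  # Delta = 2 does not round to the published mild+2 stay value
  s2 <- solve_prolongation(base, "Mild", 2.0)
  expect_equal(unname(s2$q["Mild", "Mild"]), 0.8417506762, tolerance = 1e-7)
  # Severe policy lowers death, stay absorbs
  s3 <- solve_prolongation(base, "Severe", 1.0)
  expect_lt(s3$death[["Severe"]], 0.48)
  expect_equal(unname(s3$q["Severe", "Moderate"]), 0.028)
  expect_equal(expected_stage_years(s3)[["Severe"]],
               baseline_years_from_mild[["Severe"]] + 1, tolerance = 1e-9)
  expect_error(solve_prolongation(base, "Mild", 100), "unreachable")
})

test_that("solver output is monotone in delta and always row-stochastic", {
  base <- build_baseline_model()
  stays <- vapply(c(0.25, 0.5, 1, 2, 4), function(d) {
    m <- solve_prolongation(base, "Mild", d)
    expect_equal(unname(rowSums(m$q) + m$death), rep(1, 3), tolerance = 1e-12)
    m$q["Mild", "Mild"]
  }, numeric(1))
  expect_true(all(diff(stays) > 0))
  # with Moderate death held fixed the attainable gain tops out near +1.4,
  # which is why the published moderate+2 row also lowers the death entry
  expect_error(solve_prolongation(base, "Moderate", 2), "1.375")
  mods <- vapply(c(0.25, 0.5, 1), function(d) {
    m <- solve_prolongation(base, "Moderate", d)
    expect_equal(unname(rowSums(m$q) + m$death), rep(1, 3), tolerance = 1e-12)
    m$q["Moderate", "Moderate"]
  }, numeric(1))
  expect_true(all(diff(mods) > 0))
})

test_that("Monte-Carlo walkers agree with the fundamental matrix and are reproducible", {
  m <- build_baseline_model()
  w <- mc_stage_walk(m, 2e4, seed = 11)
  z <- (w$mean_years - baseline_years_from_mild) / w$se
  expect_true(all(abs(z) < 3))
  expect_identical(mc_stage_walk(m, 10, seed = 5), mc_stage_walk(m, 10, seed = 5))
  m0 <- stage_model(matrix(0, 3, 3), c(1, 1, 1))
  expect_equal(unname(mc_stage_walk(m0, 50, seed = 1)$mean_years), c(1, 0, 0))
})

test_that("stage models round-trip through the flat key-value config", {
  for (id in c("reference", "moderate+2", "severe+1")) {
    m <- build_scenario_model(id)
    m2 <- stage_model_from_config(stage_model_to_config(m))
    expect_equal(m2$q, m$q)
    expect_equal(m2$death, m$death)
    expect_identical(m2$name, m$name)
  }
})
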