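test_that("spec validation rejects bad blocks and unknown planted effects", {
  expect_error(
    synthetic_spec(variable_blocks = list(list(size = 3, rho = -0.9))),
    "positive semi-definite"
  )
  expect_error(
    synthetic_spec(
      variable_blocks = list(list(size = 2, rho = 0)),
      planted_effects = c(NOPE = 0.5)
    ),
    "NOPE"
  )
  # equicorrelation PSD boundary: rho = -1/(m-1) is admissible
  expect_s3_class(
    synthetic_spec(variable_blocks = list(list(size = 3, rho = -0.5))),
    "synthetic_spec"
  )
})

test_that("exposure generation realizes the block correlation structure", {
  # uncorrelated block at n = 62: every pairwise |r| stays inside the
  # Fisher-z 99% band (|z| < 2.58/sqrt(59) -> |r| < 0.4 comfortably)
  X <- generate_exposures(synthetic_spec(
    n_counties = 62, variable_blocks = list(list(size = 6, rho = 0)), seed = 11
  ))
  R <- cor(as.data.frame(X[, -1]))
  expect_true(all(abs(R[upper.tri(R)]) < 0.4))

  # strong two-variable block at n = 1000 recovers r within 0.05
  Xb <- generate_exposures(synthetic_spec(
    n_counties = 1000, variable_blocks = list(list(size = 2, rho = 0.9)),
    seed = 4
  ))
  expect_lt(abs(cor(Xb$B1V1, Xb$B1V2) - 0.9), 0.05)

  # determinism: identical seeds give bit-identical tables
  spec <- synthetic_spec(
    n_counties = 30,
    variable_blocks = list(list(size = 3, rho = 0.5), list(size = 2, rho = 0)),
    seed = 99
  )
  expect_identical(generate_exposures(spec), generate_exposures(spec))
})

test_that("moment recovery at n = 10000: means, SDs and correlations", {
  X <- generate_exposures(synthetic_spec(
    n_counties = 10000,
    variable_blocks = list(list(size = 3, rho = 0.6), list(size = 2, rho = -0.4)),
    seed = 21
  ))
  M <- as.matrix(X[, -1])
  # zero-mean target: 3 standard errors (3/sqrt(1e4) = 0.03) per variable
  expect_true(all(abs(colMeans(M)) < 0.03))
  expect_true(all(abs(apply(M, 2, sd) - 1) < 0.02))
  R <- cor(M)
  expect_lt(max(abs(R[c("B1V1", "B1V2", "B1V3"), c("B1V1", "B1V2", "B1V3")] -
    (0.6 + 0.4 * diag(3)))), 0.03)
  expect_lt(abs(R["B2V1", "B2V2"] - (-0.4)), 0.03)
})

test_that("outcome generation: noiseless slope, calibration identity, unknown names", {
  X <- generate_exposures(synthetic_spec(
    n_counties = 62, variable_blocks = list(list(size = 3, rho = 0)), seed = 2
  ))
  expect_error(generate_outcome(X, c(Q9 = 1), 1, seed = 1), "Q9")

  # noiseless single effect: standardized bivariable slope is exactly beta
  Xy0 <- generate_outcome(X, c(B1V1 = 0.5), 0, seed = 2)
  Xs <- standardize_columns(Xy0, c("B1V1", "y"))
  est <- fit_bivariable(Xs, "y", "B1V1")$estimate
  expect_equal(est, cor(Xy0$B1V1, Xy0$y), tolerance = 1e-12)
  expect_equal(abs(est), 1, tolerance = 1e-10)

  # reported population R2 matches the analytic formula exactly
  Xy <- generate_outcome(X, c(B1V1 = 0.5, B1V2 = 0.3), 0.8, seed = 5)
  lp <- 0.5 * X$B1V1 + 0.3 * X$B1V2
  expect_equal(
    attr(Xy, "population_r2"), var(lp) / (var(lp) + 0.64),
    tolerance = 1e-12
  )
  # and noise_sd_for_r2 inverts it
  sdn <- noise_sd_for_r2(X, c(B1V1 = 0.5, B1V2 = 0.3), 0.5)
  Xy2 <- generate_outcome(X, c(B1V1 = 0.5, B1V2 = 0.3), sdn, seed = 5)
  expect_equal(attr(Xy2, "population_r2"), 0.5, tolerance = 1e-12)
})

test_that("null effects leave single-variable slopes unbiased", {
  slopes <- vapply(1:1000, function(s) {
    X <- generate_exposures(synthetic_spec(
      n_counties = 62, variable_blocks = list(list(size = 1, rho = 0)),
      seed = s
    ))
    Xy <- generate_outcome(X, c(), 1, seed = s + 20000)
    cor(Xy$B1V1, Xy$y) * sd(Xy$y) / sd(Xy$B1V1)
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("outcomes calibrated to R2 = 0.5 give adjusted R2 near 0.5 at n = 62", {
  r2 <- vapply(1:500, function(s) {
    X <- generate_exposures(synthetic_spec(
      n_counties = 62, variable_blocks = list(list(size = 2, rho = 0)),
      seed = s
    ))
    sdn <- noise_sd_for_r2(X, c(B1V1 = 0.5, B1V2 = 0.5), 0.5)
    Xy <- generate_outcome(X, c(B1V1 = 0.5, B1V2 = 0.5), sdn, seed = s + 5e4)
    summary(lm(y ~ B1V1 + B1V2, data = Xy))$adj.r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.5), 0.1)
})

test_that("count generation is Poisson-consistent and reproducible", {
  expect_error(generate_counts(c(-1, 2), c(10, 10)), "nonnegative")
  z <- generate_counts(c(0, 0, 0), c(1e5, 1e5, 1e5), seed = 1)
  expect_true(all(z$cases == 0))
  cc <- generate_counts(rep(100, 4), rep(1e6, 4), seed = 8)
  expect_true(all(abs(cc$cases - 1000) < 3 * sqrt(1000)))
  expect_identical(cc, generate_counts(rep(100, 4), rep(1e6, 4), seed = 8))
})

test_that("trend series follow the piecewise log-linear model", {
  expect_error(trend_spec(segment_apcs = c(3, -2)), "one APC per segment")
  expect_error(
    trend_spec(segment_apcs = c(3, -2), break_years = 1999),
    "strictly inside"
  )
  expect_error(trend_spec(segment_apcs = -100), "-100")

  flat <- generate_trend_series(trend_spec(segment_apcs = 0, baseline_rate = 30))
  expect_equal(flat$rate, rep(30, nrow(flat)), tolerance = 1e-12)

  up <- generate_trend_series(trend_spec(segment_apcs = 5, baseline_rate = 10))
  expect_equal(up$rate[-1] / up$rate[-nrow(up)], rep(1.05, nrow(up) - 1),
    tolerance = 1e-12
  )

  # noiseless two-segment series: per-side log regressions recover slopes
  two <- generate_trend_series(trend_spec(
    segment_apcs = c(3, -2), break_years = 2009
  ))
  left <- two[two$year <= 2009, ]
  right <- two[two$year >= 2009, ]
  expect_equal(
    unname(coef(lm(log(rate) ~ year, left))[2]), log(1.03),
    tolerance = 1e-10
  )
  expect_equal(
    unname(coef(lm(log(rate) ~ year, right))[2]), log(0.98),
    tolerance = 1e-10
  )
})

test_that("fixture bundles materialize all pipeline inputs with ground truth", {
  dir <- withr::local_tempdir()
  paths <- write_fixtures(dir, spec = synthetic_spec(
    n_counties = 10, variable_blocks = list(list(size = 3, rho = 0)),
    planted_effects = c(B1V1 = 0.5), noise_sd = 1, seed = 3
  ))
  expect_true(all(file.exists(unlist(paths))))
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$planted_effects$B1V1, 0.5)
  exposures <- readr::read_csv(paths$exposures, show_col_types = FALSE)
  expect_true(all(c("county", "B1V1", "y") %in% names(exposures)))
})
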