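# Exposure statistics from fitted PC surrogates.

toy_model <- function(indices, coefficients, p = 3, tissue = "toy") {
  spec <- basis_spec(2, p)
  structure(
    list(tissue = tissue, spec = spec, active_indices = indices,
         coefficients = coefficients, Q = length(coefficients),
         loo_error = 0, n_build = 0L, pmse_percent = NA_real_),
    class = "pc_model")
}

test_that("analytic moments are the constant coefficient and the coefficient sum of squares", {
  m <- toy_model(matrix(c(0L, 0L, 1L, 0L, 0L, 1L), ncol = 2, byrow = TRUE),
                 c(2.0, 0.5, 0.3))
  mom <- moments_from_coefficients(m)
  expect_equal(mom$mean, 2.0)
  expect_equal(mom$variance, 0.34)
  m0 <- toy_model(matrix(c(0L, 0L), ncol = 2), 1.4e-3)
  expect_equal(moments_from_coefficients(m0),
               list(mean = 1.4e-3, variance = 0))
  bad <- toy_model(matrix(c(1L, 0L), ncol = 2), 1)
  expect_error(moments_from_coefficients(bad), "constant term")
})

test_that("analytic moments agree with Monte-Carlo sampling of the surrogate", {
  m <- toy_model(matrix(c(0L, 0L, 1L, 0L, 2L, 1L, 0L, 3L), ncol = 2,
                        byrow = TRUE), c(1.5, 0.4, -0.25, 0.1))
  mom <- moments_from_coefficients(m)
  M <- 200000L
  v <- predict(m, uniform_random_design(M, 31))
  se_mean <- sd(v) / sqrt(M)
  expect_lt(abs(mean(v) - mom$mean), 4 * se_mean)
  se_var <- sd((v - mean(v))^2) / sqrt(M)
  expect_lt(abs(var(v) - mom$variance), 4 * se_var)
})

test_that("the coefficient of variation is reported in percent", {
  expect_equal(coefficient_of_variation(2, 0.04), 10)
  expect_equal(coefficient_of_variation(5, 0), 0)
  expect_equal(coefficient_of_variation(1, 0.1849), 43)
  expect_error(coefficient_of_variation(0, 1), "mean")
})

test_that("the orientation sweep records surrogate values and their maximum", {
  m0 <- toy_model(matrix(c(0L, 0L), ncol = 2), 0.003)
  sw <- orientation_sweep(m0, M = 500, seed = 5)
  expect_true(all(sw$values == 0.003))
  expect_equal(sw$mE99th, 0.003)
  sw1 <- orientation_sweep(m0, M = 1, seed = 5)
  expect_equal(sw1$mE99th, sw1$values)
})

test_that("worst-case ratios use the limit matching the CNS-of-head flag", {
  expect_equal(ws_percent(0.02, TRUE), 100)
  expect_equal(ws_percent(0.1, FALSE), 25)
  expect_equal(ws_percent(0, TRUE), 0)
})

test_that("band classification respects the threshold boundaries and partitions the sweep", {
  m <- 2.0
  expect_equal(as.character(band_classify(m, m)), "ge90")
  expect_equal(as.character(band_classify(0.85 * m, m)), "b80_89")
  expect_equal(as.character(band_classify(0.75 * m, m)), "b70_79")
  expect_equal(as.character(band_classify(0.7 * m - 1e-9, m)), "below70")
  expect_equal(as.character(band_classify(0.9 * m, m)), "ge90")
  v <- seq(0, m, length.out = 1000)
  b <- band_classify(v, m)
  expect_equal(sum(tabulate(b, 4)), 1000L)
})

test_that("the 70% band threshold is a 3 dB amplitude reduction", {
  expect_equal(band_threshold_db(0.7), 20 * log10(1 / 0.7))
  expect_equal(round(band_threshold_db(0.7)), 3)
  expect_equal(band_threshold_db(0.5), 6.0206, tolerance = 1e-4)
})

test_that("the sin-weighted solid-angle estimator recovers closed-form regions", {
  d <- uniform_random_design(10000, 17)
  th <- d$points$theta_deg
  full <- solid_angle(d, rep(TRUE, 10000))
  expect_lt(abs(full$omega_sr - 4 * pi), 3 * full$se_sr)
  hemi <- solid_angle(d, th < 90)
  expect_lt(abs(hemi$omega_sr - 2 * pi), 3 * hemi$se_sr)
  cap <- solid_angle(d, th < 60)
  expect_lt(abs(cap$omega_sr - pi), 3 * cap$se_sr)
  expect_error(solid_angle(uniform_random_design(50, 1), rep(TRUE, 50)),
               "100")
})

test_that("band solid angles are additive to the full sphere", {
  m <- toy_model(matrix(c(0L, 0L, 1L, 0L, 0L, 2L), ncol = 2, byrow = TRUE),
                 c(2, 0.6, 0.4))
  sw <- orientation_sweep(m, M = 10000, seed = 23)
  b <- band_classify(sw$values, sw$mE99th)
  parts <- vapply(levels(b), function(lv) {
    solid_angle(sw$design, b == lv)$omega_sr
  }, numeric(1))
  ses <- vapply(levels(b), function(lv) {
    solid_angle(sw$design, b == lv)$se_sr
  }, numeric(1))
  expect_lt(abs(sum(parts) - 4 * pi), 3 * sqrt(sum(ses^2)) + 1e-9)
  expect_equal(sum(tabulate(b, 4)), 10000L)
})

test_that("the dense-grid maximum cross-checks the random-sweep maximum", {
  m <- toy_model(matrix(c(0L, 0L, 2L, 0L), ncol = 2, byrow = TRUE),
                 c(1, 0.3))
  gm <- grid_max(m, step_deg = 2)
  sw <- orientation_sweep(m, M = 5000, seed = 3)
  expect_gte(gm$max + 1e-9, sw$mE99th)
  # analytic maximum of 1 + 0.3 * sqrt(5) (3 xi^2 - 1) / 2 at xi = +/-1
  expect_equal(gm$max, 1 + 0.3 * sqrt(5), tolerance = 1e-3)
})
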