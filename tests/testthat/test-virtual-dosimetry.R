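# Closed-form ellipsoid eddy-current solver and the E_99th observation
# operator.

test_that("the spherical loop-induction closed form is reproduced", {
  sph <- body_ellipsoid(0.1, 0.1, 0.1)
  E <- eddy_field(cbind(0.1, 0, 0), c(0, 0, 1), sph)
  expect_equal(sqrt(sum(E^2)), pi * 50 * 200e-6 * 0.1, tolerance = 1e-12)
  # field vanishes at the center for any orientation
  u <- drop(orientation_to_unit_vector(orientation_angles(37, 122)))
  expect_equal(drop(eddy_field(cbind(0, 0, 0), u,
                               body_ellipsoid(0.2, 0.1, 0.4))),
               c(0, 0, 0), ignore_attr = TRUE)
  expect_error(eddy_field(cbind(0.2, 0, 0), c(0, 0, 1), sph), "outside")
  expect_error(eddy_field(cbind(0, 0, 0), c(1, 1, 0), sph), "unit")
})

test_that("the induced current has no normal component on the boundary", {
  body <- body_ellipsoid(0.12, 0.17, 0.25)
  pts <- pcdosim:::with_seed(8, {
    th <- acos(runif(100, -1, 1))
    ph <- runif(100, -pi, pi)
    cbind(body$a * sin(th) * cos(ph), body$b * sin(th) * sin(ph),
          body$c * cos(th))
  })
  for (u in list(c(1, 0, 0), c(0, 0, 1),
                 drop(orientation_to_unit_vector(orientation_angles(63, -49))))) {
    E <- eddy_field(pts, u, body)
    normal <- cbind(pts[, 1] / body$a^2, pts[, 2] / body$b^2,
                    pts[, 3] / body$c^2)
    expect_lt(max(abs(rowSums(E * normal))), 1e-12)
  }
})

test_that("the solution is the exact interior eddy-current field (curl check)", {
  # curl E must equal -dB/dt, i.e. omega * B for the RMS phasor
  body <- body_ellipsoid(0.08, 0.15, 0.22)
  cfg <- solver_config()
  u <- drop(orientation_to_unit_vector(orientation_angles(71, 28)))
  h <- 1e-6
  p0 <- c(0.01, -0.02, 0.03)
  curl <- numeric(3)
  dE <- function(dim, delta) {
    p <- p0; p[dim] <- p[dim] + delta
    drop(eddy_field(matrix(p, 1), u, body, cfg))
  }
  Jx <- (dE(1, h) - dE(1, -h)) / (2 * h)
  Jy <- (dE(2, h) - dE(2, -h)) / (2 * h)
  Jz <- (dE(3, h) - dE(3, -h)) / (2 * h)
  curl <- c(Jy[3] - Jz[2], Jz[1] - Jx[3], Jx[2] - Jy[1])
  expect_equal(curl, 2 * pi * cfg$frequency * cfg$B_rms * u,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a concentric spherical region is rotationally invariant to within the grid anisotropy", {
  sm <- sphere_model()
  d <- uniform_random_design(20, 9)
  v <- e99th_batch(sm$region, d, sm$body)
  expect_lt(max(v) / min(v), 1.01)
})

test_that("E_99th is deterministic without noise and reproducibly noisy with it", {
  sm <- sphere_model()
  a <- orientation_angles(40, 30)
  v1 <- e99th(sm$region, a, sm$body)
  v2 <- e99th(sm$region, a, sm$body)
  expect_identical(v1, v2)
  cfg <- solver_config(noise_cv = 0.05, noise_seed = 4)
  n1 <- e99th(sm$region, a, sm$body, cfg)
  n2 <- e99th(sm$region, a, sm$body, cfg)
  expect_identical(n1, n2)
  expect_false(n1 == v1)
  # the noise model is capped at 5% CV
  expect_error(solver_config(noise_cv = 0.06), "noise_cv")
})

test_that("E_99th scales linearly in field amplitude and frequency", {
  sm <- sphere_model()
  ga <- ga_fixture("3mo")
  a <- orientation_angles(c(40, 95, 140), c(30, -120, 75))
  base <- e99th_batch(ga$fetus_whole_body, a, ga$body, solver_config())
  double_B <- e99th_batch(ga$fetus_whole_body, a, ga$body,
                          solver_config(B_rms = 400e-6))
  expect_equal(double_B, 2 * base, tolerance = 1e-12)
  f100 <- e99th_batch(ga$fetus_whole_body, a, ga$body,
                      solver_config(frequency = 100))
  expect_equal(f100, 2 * base, tolerance = 1e-12)
})

test_that("E_99th is antipodally symmetric in the field direction", {
  ga <- ga_fixture("3mo")
  ang <- uniform_random_design(25, 21)$points
  anti <- orientation_angles(180 - ang$theta_deg,
                             ifelse(ang$phi_deg > 0, ang$phi_deg - 180,
                                    ang$phi_deg + 180))
  v1 <- e99th_batch(ga$fetus_whole_body, ang, ga$body)
  v2 <- e99th_batch(ga$fetus_whole_body, anti, ga$body)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("the whole-body response is smooth across neighboring orientations", {
  ga <- ga_fixture("3mo")
  th <- seq(2.5, 177.5, by = 5)
  ph <- seq(-177.5, 177.5, by = 5)
  g <- expand.grid(theta_deg = th, phi_deg = ph)
  v <- matrix(e99th_batch(ga$fetus_whole_body, g, ga$body),
              nrow = length(th))
  rel_d_theta <- abs(diff(v)) / v[-1, ]
  rel_d_phi <- abs(t(diff(t(v)))) / v[, -1]
  expect_lt(max(rel_d_theta), 0.10)
  expect_lt(max(rel_d_phi), 0.10)
})

test_that("whole-body magnitudes stay in the expected mV/m range at the reference exposure", {
  for (lab in c("3mo", "9mo")) {
    ga <- ga_fixture(lab)
    v <- e99th_batch(ga$fetus_whole_body, uniform_random_design(50, 12),
                     ga$body)
    expect_true(all(v > 0.1e-3 & v < 20e-3))
  }
})

test_that("point clouds honor the minimum size and regions must fit the body", {
  expect_error(
    region_cloud(tissue_region("tiny", c(0, 0, 0), rep(0.01, 3),
                               grid_step = 0.01)),
    "500")
  sm <- sphere_model()
  expect_gte(nrow(region_cloud(sm$region)), 500L)
  out_region <- tissue_region("escapee", c(0.09, 0, 0), rep(0.05, 3))
  expect_error(e99th(out_region, orientation_angles(90, 0), sm$body),
               "outside the body")
})
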