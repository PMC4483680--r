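# Sparse PC regression: LARS selection, hybrid least squares, leave-one-out
# model choice, pMSE and the N x p refinement loop.

make_instance <- function(seed, n = 30, p = 4) {
  pcdosim:::with_seed(seed, {
    spec <- basis_spec(2, p)
    xi <- matrix(runif(2 * n, -1, 1), ncol = 2)
    Psi <- evaluate_basis(xi, spec)
    y <- 2 + drop(Psi[, -1] %*% rnorm(ncol(Psi) - 1, 0, 0.3)) + rnorm(n, 0, 0.1)
    list(spec = spec, xi = xi, Psi = Psi, y = y)
  })
}

test_that("the first LARS selection maximizes the absolute correlation and a planted column enters first", {
  inst <- make_instance(1)
  path <- lars_path(inst$Psi, inst$y)
  Xc <- scale(inst$Psi[, -1])
  cors <- abs(drop(crossprod(Xc, inst$y - mean(inst$y))))
  expect_equal(path$order[1] - 1L, which.max(cors))
  # response equal to one basis column: that column enters first and the
  # first-step least-squares residual is (near) zero
  y2 <- inst$Psi[, 5]
  path2 <- lars_path(inst$Psi, y2)
  expect_equal(path2$order[1], 5L)
  fit <- hybrid_ols(inst$Psi, y2, path2$order[1])
  expect_lt(sum((y2 - inst$Psi[, c(1, 5)] %*% fit)^2), 1e-20)
})

test_that("least-squares refits along the path have non-increasing residual norms", {
  inst <- make_instance(2, n = 25, p = 3)
  path <- lars_path(inst$Psi, inst$y)
  rss <- vapply(seq_along(path$order), function(k) {
    act <- path$order[seq_len(k)]
    # independent explicit least-squares oracle
    fit <- stats::lm.fit(inst$Psi[, c(1L, act), drop = FALSE], inst$y)
    sum(fit$residuals^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("hybrid least squares reproduces exact combinations and satisfies the normal equations", {
  inst <- make_instance(3, n = 20)
  # intercept-only fit is the mean
  expect_equal(unname(hybrid_ols(inst$Psi, inst$y)), mean(inst$y))
  # exact recovery of y = 2 + 0.5 * psi_(1,0)
  j10 <- which(apply(inst$spec$indices, 1,
                     function(a) all(a == c(1, 0))))
  y <- 2 + 0.5 * inst$Psi[, j10]
  coefs <- hybrid_ols(inst$Psi, y, j10)
  expect_equal(unname(coefs), c(2, 0.5), tolerance = 1e-10)
  # residual orthogonality on a random 20 x 4 instance
  act <- c(3L, 5L, 7L)
  fit <- hybrid_ols(inst$Psi, inst$y, act)
  res <- inst$y - drop(inst$Psi[, c(1L, act)] %*% fit)
  expect_lt(max(abs(crossprod(inst$Psi[, c(1L, act)], res))), 1e-10)
  expect_error(hybrid_ols(cbind(1, inst$Psi[, 2], inst$Psi[, 2]),
                          inst$y, c(2L, 3L)), "singular")
})

test_that("the closed-form leave-one-out error equals explicit refits", {
  # a 12 x 3 instance to 1e-10, then many seeded small instances to 1e-8
  inst <- make_instance(4, n = 12, p = 1)
  coefs <- hybrid_ols(inst$Psi, inst$y, 2:3)
  expect_equal(loo_error(inst$Psi, inst$y, coefs),
               loo_brute(inst$Psi, inst$y), tolerance = 1e-10)
  for (seed in 1:30) {
    inst <- make_instance(seed, n = sample(8:15, 1), p = 1)
    q <- sample(0:2, 1)
    act <- if (q > 0) 1L + seq_len(q) else integer(0)
    A <- inst$Psi[, c(1L, act), drop = FALSE]
    coefs <- hybrid_ols(inst$Psi, inst$y, act)
    expect_equal(loo_error(A, inst$y, coefs), loo_brute(A, inst$y),
                 tolerance = 1e-8)
  }
})

test_that("leave-one-out closed form matches hand algebra and degenerate cases error", {
  # intercept-only, N = 2: h_i = 1/2 so the error is exactly 4
  A <- cbind(c(1, 1))
  y <- c(0, 1)
  expect_equal(loo_error(A, y, mean(y)), 4)
  # noiseless spanned response -> zero
  inst <- make_instance(5, n = 15)
  y2 <- drop(inst$Psi[, 1:3] %*% c(1, 0.5, -0.2))
  coefs <- hybrid_ols(inst$Psi, y2, 2:3)
  expect_lt(loo_error(inst$Psi[, 1:3], y2, coefs), 1e-15)
  expect_error(loo_error(A, c(1, 1), 1), "constant response")
  # leverage-one observation
  A3 <- cbind(1, c(1, 0, 0, 0))
  expect_error(loo_error(A3, c(1, 2, 3, 4),
                         stats::lm.fit(A3, c(1, 2, 3, 4))$coefficients),
               "leverage")
})

test_that("leave-one-out model selection recovers planted sparse responses", {
  spec <- basis_spec(2, 5)
  planted <- matrix(c(0L, 0L, 2L, 1L, 0L, 3L), ncol = 2, byrow = TRUE)
  coef_true <- c(2.0, 0.7, -0.4)
  solver <- planted_solver(planted, coef_true)
  d <- sobol_design(50)
  y <- solver(d$points)
  Psi <- evaluate_basis(standardize_angles(d$points), spec)
  model <- select_model(lars_path(Psi, y), Psi, y, spec)
  expect_equal(model$Q, 3L)
  expect_equal(model$active_indices[order(model$active_indices[, 1],
                                          model$active_indices[, 2]), ],
               planted[order(planted[, 1], planted[, 2]), ])
  got <- model$coefficients[match(
    paste(planted[, 1], planted[, 2]),
    paste(model$active_indices[, 1], model$active_indices[, 2]))]
  expect_lt(max(abs(got - coef_true)), 1e-8)
})

test_that("exact recovery holds for random sparse combinations within the basis", {
  spec <- basis_spec(2, 6)
  for (seed in c(10, 20, 30)) {
    pick <- pcdosim:::with_seed(seed, {
      k <- sample(2:5, 1)
      list(idx = c(1L, sample(2:spec$P, k)),
           coefs = c(runif(1, 1, 3), runif(k, -1, 1)))
    })
    solver <- planted_solver(spec$indices[pick$idx, , drop = FALSE],
                             pick$coefs)
    d <- sobol_design(3 * length(pick$idx) + 40)
    y <- solver(d$points)
    Psi <- evaluate_basis(standardize_angles(d$points), spec)
    model <- select_model(lars_path(Psi, y), Psi, y, spec)
    pred <- predict(model, d)
    expect_lt(pmse(y, pred), 1e-10)
  }
})

test_that("pure-noise responses select models near the intercept-only end of the path", {
  spec <- basis_spec(2, 5)
  d <- sobol_design(40)
  Psi <- evaluate_basis(standardize_angles(d$points), spec)
  qs <- vapply(1:20, function(seed) {
    y <- pcdosim:::with_seed(seed, rnorm(40))
    select_model(lars_path(Psi, y), Psi, y, spec)$Q
  }, integer(1))
  expect_lte(median(qs), 4L)
  expect_true(all(qs <= min(spec$P, 40 - 1)))
})

test_that("constant responses short-circuit to the intercept-only model", {
  spec <- basis_spec(2, 3)
  d <- sobol_design(20)
  Psi <- evaluate_basis(standardize_angles(d$points), spec)
  y <- rep(1.4e-3, 20)
  model <- select_model(lars_path(Psi, y), Psi, y, spec)
  expect_equal(model$Q, 1L)
  expect_equal(model$coefficients, 1.4e-3)
  expect_equal(model$loo_error, 0)
})

test_that("pMSE matches its definition and rejects zero validation values", {
  expect_equal(pmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pmse(1, 1.1), 1.0, tolerance = 1e-10)
  expect_equal(pmse(c(1, 2), c(1.1, 2)), 0.5, tolerance = 1e-10)
  expect_error(pmse(c(1, 0), c(1, 1)), "zero validation")
  expect_error(pmse(1:3, 1:2), "equal length")
})

test_that("the refinement loop converges on polynomial responses at the smallest sufficient grid point", {
  solver <- planted_solver(matrix(c(0L, 0L, 1L, 1L, 0L, 2L), ncol = 2,
                                  byrow = TRUE), c(3, 0.5, 0.25))
  fit <- adaptive_fit(solver, n_grid = c(20L, 40L), p_grid = c(1L, 2L, 4L),
                      tau_percent = 0.5, seeds = list(validation = 7L))
  expect_true(fit$report$converged)
  expect_equal(unname(fit$report$selected), c(20, 2))
  expect_lt(fit$report$pmse_percent, 1e-8)
  # vacuous threshold: first grid point wins immediately
  fit2 <- adaptive_fit(solver, n_grid = 20L, p_grid = 1L,
                       tau_percent = Inf, seeds = list(validation = 7L))
  expect_true(fit2$report$converged)
  expect_equal(nrow(fit2$report$trials), 1L)
})

test_that("fits are deterministic: identical seeds give bit-identical model JSON", {
  solver <- planted_solver(matrix(c(0L, 0L, 2L, 2L), ncol = 2,
                                  byrow = TRUE), c(1, 0.2))
  noisy <- function(pts) solver(pts) *
    exp(pcdosim:::with_seed(13, rnorm(nrow(pts), 0, 0.01)))
  run <- function() {
    fit <- adaptive_fit(noisy, n_grid = c(30L, 60L), p_grid = c(2L, 4L),
                        tau_percent = 0.01, seeds = list(validation = 3L))
    as.character(write_pc_model(fit$model, seeds = list(validation = 3L)))
  }
  expect_identical(run(), run())
})

test_that("model JSON round-trips through write and read", {
  inst <- make_instance(6, n = 40)
  model <- select_model(lars_path(inst$Psi, inst$y), inst$Psi, inst$y,
                        inst$spec, tissue = "liver")
  f <- withr::local_tempfile(fileext = ".json")
  write_pc_model(model, f, seeds = list(validation = 1))
  back <- read_pc_model(f)
  expect_equal(back$tissue, "liver")
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$active_indices, model$active_indices)
  expect_equal(back$Q, model$Q)
  # predictions agree
  pts <- uniform_random_design(50, 2)
  expect_equal(predict(back, pts), predict(model, pts), tolerance = 1e-12)
})
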