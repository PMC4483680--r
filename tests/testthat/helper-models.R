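# Shared builders for test fixtures (all constructed in code at test time).

# Concentric spherical body + spherical tissue region: the rotationally
# invariant geometry whose exposure should not depend on orientation.
sphere_model <- function(R_body = 0.1, r_region = 0.05, grid_step = 0.004) {
  list(body = body_ellipsoid(R_body, R_body, R_body),
       region = tissue_region("sphere", c(0, 0, 0), rep(r_region, 3),
                              grid_step = grid_step))
}

# Solver returning an exact polynomial of the standardized angles; used to
# plant sparse responses with known coefficients.
planted_solver <- function(indices, coefficients) {
  force(indices); force(coefficients)
  function(pts) {
    xi <- standardize_angles(pts)
    drop(pcdosim:::evaluate_index_set(xi, indices) %*% coefficients)
  }
}

# Tensor-product Gauss-Legendre quadrature of the 2-D Gram matrix of a
# basis, against the uniform density 1/4 on (-1,1)^2.  Independent
# orthonormality oracle (exact for polynomial integrands up to the node
# count's degree).
quadrature_gram <- function(spec, n_nodes = 24L) {
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  g <- expand.grid(x = gl$x, y = gl$x)
  w <- as.vector(outer(gl$w, gl$w)) / 4
  Psi <- evaluate_basis(cbind(g$x, g$y), spec)
  crossprod(Psi, Psi * w)
}

# Brute-force leave-one-out error by N explicit refits.
loo_brute <- function(A, y) {
  n <- nrow(A)
  press <- vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(A[-i, , drop = FALSE], y[-i])
    (y[i] - sum(A[i, ] * fit$coefficients))^2
  }, numeric(1))
  sum(press) / sum((y - mean(y))^2)
}

# Smallest angle (degrees) between a direction and a target axis,
# identifying antipodes (the physics is symmetric under u -> -u).
axis_angle_deg <- function(angles, target_u) {
  u <- orientation_to_unit_vector(angles)
  cosang <- abs(drop(u %*% target_u))
  acos(pmin(1, cosang)) * 180 / pi
}
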