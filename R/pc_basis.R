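# Orthonormal Legendre tensor-product basis over the standardized
# orientation angles.  The polynomial family is the ORTHONORMAL one,
# sqrt(2n+1) * P_n, so that the analytic moment identities (mean = constant
# coefficient, variance = sum of squares of the remaining coefficients)
# hold exactly for the fitted expansions.

#' Validate magnetic-field orientation angles
#'
#' The polar angle `theta_deg` lives on the open interval (0, 180) degrees
#' and the azimuth `phi_deg` on (-180, 180), matching the uniform input
#' distributions of the exposure model.  Values lying exactly on an endpoint
#' are clamped inward by one machine epsilon (relative to the interval
#' width); values beyond an endpoint raise an error.
#'
#' @param theta_deg numeric vector of polar angles in degrees.
#' @param phi_deg numeric vector of azimuths in degrees, same length.
#' @return A `data.frame` with columns `theta_deg` and `phi_deg`.
#' @examples
#' orientation_angles(c(90, 45), c(0, -90))
#' @export
orientation_angles <- function(theta_deg, phi_deg) {
  if (length(theta_deg) != length(phi_deg)) {
    stop("theta_deg and phi_deg must have the same length", call. = FALSE)
  }
  if (length(theta_deg) == 0L) {
    stop("at least one orientation is required", call. = FALSE)
  }
  if (!is.numeric(theta_deg) || !is.numeric(phi_deg) ||
      any(!is.finite(theta_deg)) || any(!is.finite(phi_deg))) {
    stop("angles must be finite numeric values", call. = FALSE)
  }
  if (any(theta_deg < 0 | theta_deg > 180)) {
    stop("theta_deg must lie in (0, 180) degrees", call. = FALSE)
  }
  if (any(phi_deg < -180 | phi_deg > 180)) {
    stop("phi_deg must lie in (-180, 180) degrees", call. = FALSE)
  }
  eps_t <- 180 * .Machine$double.eps
  eps_p <- 360 * .Machine$double.eps
  data.frame(
    theta_deg = pmin(pmax(theta_deg, eps_t), 180 - eps_t),
    phi_deg = pmin(pmax(phi_deg, eps_p * 0.5 - 180), 180 - eps_p * 0.5)
  )
}

#' Map orientation angles to the standardized Legendre domain
#'
#' Affine bijection from the angle supports onto (-1, 1)^2:
#' `xi1 = theta_deg / 90 - 1`, `xi2 = phi_deg / 180`.
#'
#' @param angles a data.frame with columns `theta_deg`, `phi_deg` (as
#'   returned by [orientation_angles()]), or an orientation design.
#' @return A numeric matrix with columns `xi1`, `xi2`.
#' @seealso [destandardize_angles()] for the inverse map.
#' @export
standardize_angles <- function(angles) {
  angles <- as_angles(angles)
  cbind(xi1 = angles$theta_deg / 90 - 1, xi2 = angles$phi_deg / 180)
}

#' Map standardized points back to orientation angles
#'
#' @param xi numeric matrix (or 2-column data.frame) of standardized
#'   coordinates in (-1, 1)^2.
#' @return A data.frame with columns `theta_deg`, `phi_deg`.
#' @export
destandardize_angles <- function(xi) {
  xi <- as.matrix(xi)
  if (ncol(xi) != 2L) stop("xi must have two columns", call. = FALSE)
  orientation_angles((xi[, 1] + 1) * 90, xi[, 2] * 180)
}

# Accept either a bare angle data.frame or a design object.
as_angles <- function(x) {
  if (inherits(x, "orientation_design")) x <- x$points
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x) || !all(c("theta_deg", "phi_deg") %in% names(x))) {
    stop("expected columns theta_deg and phi_deg", call. = FALSE)
  }
  orientation_angles(x$theta_deg, x$phi_deg)
}

#' Total-degree multi-index set
#'
#' All `K`-dimensional multi-indices `alpha` with total degree
#' `|alpha| <= p`, in graded lexicographic order (degree first; within a
#' degree the leading components decrease last-to-first, so for `K = 2`,
#' degree 1 lists `(1,0)` before `(0,1)`).  The constant index `(0, ..., 0)`
#' is always first and the number of rows is `choose(p + K, K)`.
#'
#' @param K number of input dimensions (>= 1).
#' @param p maximum total degree (>= 0).
#' @return Integer matrix with `choose(p + K, K)` rows and `K` columns.
#' @examples
#' total_degree_indices(2, 1)
#' @export
total_degree_indices <- function(K, p) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K < 1 ||
      K != round(K)) {
    stop("K must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 ||
      p != round(p)) {
    stop("p must be a non-negative integer", call. = FALSE)
  }
  K <- as.integer(K)
  p <- as.integer(p)
  g <- as.matrix(expand.grid(rep(list(0:p), K), KEEP.OUT.ATTRS = FALSE))
  deg <- rowSums(g)
  keep <- deg <= p
  g <- g[keep, , drop = FALSE]
  deg <- deg[keep]
  ord <- do.call(order, c(list(deg),
                          lapply(seq_len(K), function(j) -g[, j])))
  g <- g[ord, , drop = FALSE]
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Basis specification for the truncated PC expansion
#'
#' Bundles the multi-index set of [total_degree_indices()] with its
#' dimensions.  The basis size is `P = choose(p + K, K)`.
#'
#' @param K number of inputs (2 for the orientation problem).
#' @param p maximum total degree.
#' @return An object of class `basis_spec` with elements `K`, `p`,
#'   `indices` (P x K integer matrix) and `P`.
#' @export
basis_spec <- function(K = 2L, p) {
  idx <- total_degree_indices(K, p)
  structure(
    list(K = as.integer(K), p = as.integer(p), indices = idx,
         P = nrow(idx)),
    class = "basis_spec"
  )
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf(
    "Orthonormal Legendre basis: K = %d inputs, total degree <= %d, P = %d terms\n",
    x$K, x$p, x$P))
  invisible(x)
}

# Table of orthonormal Legendre values: length(xi) x (nmax + 1), column
# n + 1 holding sqrt(2n+1) P_n(xi).  Three-term recurrence
# (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}.
legendre_table <- function(xi, nmax) {
  xi <- as.numeric(xi)
  if (any(!is.finite(xi)) || any(xi < -1 | xi > 1)) {
    stop("xi must lie in [-1, 1]", call. = FALSE)
  }
  out <- matrix(0, length(xi), nmax + 1L)
  out[, 1L] <- 1
  if (nmax >= 1L) out[, 2L] <- xi
  if (nmax >= 2L) {
    for (n in 1:(nmax - 1L)) {
      out[, n + 2L] <- ((2 * n + 1) * xi * out[, n + 1L] -
                          n * out[, n]) / (n + 1)
    }
  }
  sweep(out, 2L, sqrt(2 * (0:nmax) + 1), "*")
}

#' Orthonormal Legendre polynomial
#'
#' Evaluates `sqrt(2n+1) * P_n(xi)`, where `P_n` is the classical Legendre
#' polynomial.  The family is orthonormal with respect to the uniform
#' density 1/2 on (-1, 1).
#'
#' @param n polynomial degree (single non-negative integer).
#' @param xi evaluation points in `[-1, 1]` (vectorized).
#' @return Numeric vector of polynomial values.
#' @examples
#' legendre_orthonormal(1, 1)      # sqrt(3)
#' legendre_orthonormal(2, 0)      # -sqrt(5) / 2
#' @export
legendre_orthonormal <- function(n, xi) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0 ||
      n != round(n)) {
    stop("n must be a single non-negative integer", call. = FALSE)
  }
  legendre_table(xi, as.integer(n))[, as.integer(n) + 1L]
}

#' Evaluate the tensor-product basis at standardized points
#'
#' Entry `(i, j)` of the result is the product over dimensions `k` of
#' `legendre_orthonormal(alpha_j[k], xi_i[k])`; the first column (constant
#' index) is all ones.
#'
#' @param points numeric matrix (n x K) of standardized coordinates in
#'   `[-1, 1]`, e.g. from [standardize_angles()].
#' @param spec a [basis_spec()].
#' @return Numeric matrix of shape n x P.
#' @export
evaluate_basis <- function(points, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set", call. = FALSE)
  if (ncol(points) != spec$K) {
    stop(sprintf("points must have K = %d columns", spec$K), call. = FALSE)
  }
  evaluate_index_set(points, spec$indices)
}

# Evaluate an arbitrary multi-index subset (rows of `indices`) at `points`.
# Shared by evaluate_basis() and the fitted-model predictor.
evaluate_index_set <- function(points, indices) {
  points <- as.matrix(points)
  K <- ncol(indices)
  tables <- lapply(seq_len(K), function(k) {
    legendre_table(points[, k], max(indices[, k]))
  })
  out <- matrix(1, nrow(points), nrow(indices))
  for (j in seq_len(nrow(indices))) {
    for (k in seq_len(K)) {
      d <- indices[j, k]
      if (d > 0L) out[, j] <- out[, j] * tables[[k]][, d + 1L]
    }
  }
  out
}
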