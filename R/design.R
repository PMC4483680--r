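# Experimental designs over the orientation angles: the quasi-Monte-Carlo
# (Sobol) build design, the pseudo-random validation/sweep designs, and the
# shared spherical-coordinate convention.

# Direction numbers for the first two Sobol dimensions, scaled to `nbits`
# bits.  Dimension 1 is the van der Corput sequence in base 2; dimension 2
# uses the primitive polynomial x^2 + x + 1 with initial values m = (1, 3)
# (the standard Joe-Kuo table entry), via the recurrence
# m_k = 2 m_{k-1} XOR 4 m_{k-2} XOR m_{k-2}.
sobol2_directions <- function(nbits = 30L) {
  v1 <- bitwShiftL(1L, nbits - seq_len(nbits))
  m <- integer(nbits)
  m[1L] <- 1L
  m[2L] <- 3L
  for (k in 3:nbits) {
    m[k] <- bitwXor(bitwXor(bitwShiftL(m[k - 1L], 1L),
                            bitwShiftL(m[k - 2L], 2L)),
                    m[k - 2L])
  }
  list(v1 = v1, v2 = bitwShiftL(m, nbits - seq_len(nbits)),
       scale = 2^nbits)
}

# Points `skip, skip+1, ...` of the 2-D Sobol sequence on [0,1)^2, in the
# conventional Gray-code order (point 0 is the origin).
sobol2_unit <- function(n, skip = 1L) {
  d <- sobol2_directions()
  nb <- length(d$v1)
  u <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    idx <- skip + i - 1L
    g <- bitwXor(idx, bitwShiftR(idx, 1L))  # Gray code
    x1 <- 0L
    x2 <- 0L
    b <- 1L
    while (g > 0L && b <= nb) {
      if (bitwAnd(g, 1L) == 1L) {
        x1 <- bitwXor(x1, d$v1[b])
        x2 <- bitwXor(x2, d$v2[b])
      }
      g <- bitwShiftR(g, 1L)
      b <- b + 1L
    }
    u[i, ] <- c(x1, x2) / d$scale
  }
  u
}

new_design <- function(kind, points, seed_or_skip) {
  structure(list(kind = kind, points = points, seed_or_skip = seed_or_skip),
            class = "orientation_design")
}

#' @export
print.orientation_design <- function(x, ...) {
  cat(sprintf("%s orientation design: %d points (%s = %d)\n", x$kind,
              nrow(x$points),
              if (x$kind == "sobol") "skip" else "seed", x$seed_or_skip))
  invisible(x)
}

#' Sobol quasi-Monte-Carlo orientation design
#'
#' First `n` points of the deterministic 2-D Sobol low-discrepancy sequence
#' (after dropping `skip` initial points; the default `skip = 1` drops the
#' origin), mapped affinely from the unit square onto the angle supports
#' `(0, 180) x (-180, 180)` degrees.  Designs of increasing `n` are nested
#' by construction, which is what the refinement loop of [adaptive_fit()]
#' exploits.
#'
#' @param n number of design points (>= 1).
#' @param skip number of initial sequence points to drop (default 1).
#' @return An `orientation_design` with `$points` a data.frame of
#'   `theta_deg`, `phi_deg`.
#' @examples
#' sobol_design(4)$points  # first point is (90, 0)
#' @export
sobol_design <- function(n, skip = 1L) {
  check_number(n, "n", lower = 1)
  check_number(skip, "skip", lower = 0)
  u <- sobol2_unit(as.integer(n), as.integer(skip))
  pts <- orientation_angles(180 * u[, 1], 360 * u[, 2] - 180)
  if (anyDuplicated(pts)) {
    stop("duplicate points in Sobol design", call. = FALSE)
  }
  new_design("sobol", pts, as.integer(skip))
}

#' Pseudo-random orientation design, uniform in the angles
#'
#' `n` i.i.d. draws with `theta ~ Uniform(0, 180)` and
#' `phi ~ Uniform(-180, 180)` degrees, reproducible given `seed`.  Note the
#' distribution is uniform IN THE ANGLES (the input pdf of the exposure
#' model), not uniform on the sphere; [solid_angle()] reweights by
#' `sin(theta)` when area on the sphere is needed.
#'
#' @param n number of points (>= 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return An `orientation_design`.
#' @export
uniform_random_design <- function(n, seed) {
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  pts <- with_seed(seed, {
    orientation_angles(stats::runif(n, 0, 180), stats::runif(n, -180, 180))
  })
  new_design("uniform_random", pts, as.integer(seed))
}

#' Orientation angles to Cartesian unit vector
#'
#' Applies the package-wide convention `u = (sin(theta) cos(phi),
#' sin(theta) sin(phi), cos(theta))` (`z` vertical head-to-toe, `x`
#' front-to-back, `y` right-to-left).
#'
#' @param angles angle data.frame or `orientation_design`.
#' @return Numeric matrix (n x 3) of unit vectors.
#' @examples
#' orientation_to_unit_vector(orientation_angles(90, 0))  # (1, 0, 0)
#' @export
orientation_to_unit_vector <- function(angles) {
  a <- as_angles(angles)
  th <- a$theta_deg * pi / 180
  ph <- a$phi_deg * pi / 180
  cbind(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
}
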