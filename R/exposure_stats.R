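# Post-processing of fitted PC surrogates into exposure statistics:
# analytic moments, coefficient of variation, the random-orientation sweep
# and its maximum, worst-case ratios against the ICNIRP 2010 basic
# restrictions, and the high-exposure orientation bands with Monte-Carlo
# solid angles.

#' ICNIRP 2010 general-public limits for the 50 Hz scenario
#'
#' Basic restrictions on the induced electric field: 0.02 V/m for the
#' central-nervous-system tissues of the head and 0.4 V/m for all other
#' tissues, with the 200 microtesla RMS reference level at 50 Hz.
#'
#' @return A list of class `regulatory_limits`.
#' @export
regulatory_limits <- function() {
  structure(
    list(cns_head_limit = 0.02, other_limit = 0.4,
         reference_level_B = 200e-6, frequency = 50),
    class = "regulatory_limits"
  )
}

#' Analytic moments from the PC coefficients
#'
#' For an expansion on an ORTHONORMAL basis the mean is the coefficient of
#' the constant term and the variance is the sum of squares of the
#' remaining coefficients; no sampling of the surrogate is needed.
#'
#' @param model a `pc_model` (its first active index must be the constant
#'   term, which [select_model()] guarantees).
#' @return A list with `mean` (V/m) and `variance` (V^2/m^2).
#' @export
moments_from_coefficients <- function(model) {
  stopifnot(inherits(model, "pc_model"))
  if (any(model$active_indices[1L, ] != 0L)) {
    stop("model lacks the constant term", call. = FALSE)
  }
  list(mean = model$coefficients[1L],
       variance = sum(model$coefficients[-1L]^2))
}

#' Coefficient of variation in percent
#'
#' @param mean distribution mean (> 0).
#' @param variance distribution variance (>= 0).
#' @return `100 * sqrt(variance) / mean`.
#' @examples
#' coefficient_of_variation(2, 0.04)  # 10
#' @export
coefficient_of_variation <- function(mean, variance) {
  check_number(mean, "mean", lower = 0, strict_lower = TRUE)
  check_number(variance, "variance", lower = 0)
  100 * sqrt(variance) / mean
}

#' Random-orientation sweep of a PC surrogate
#'
#' Evaluates the surrogate on `M` orientations drawn uniform in the angles
#' and records the maximum, `mE99th`, the worst case over the sampled
#' exposure configurations.
#'
#' @param model a `pc_model`.
#' @param M number of orientations (default 10000).
#' @param seed integer seed for the sweep design.
#' @param design optional precomputed `orientation_design` reused across
#'   tissues (then `M` and `seed` are ignored).
#' @return A list with `design`, `values` (V/m) and `mE99th` (V/m).
#' @export
orientation_sweep <- function(model, M = 10000L, seed = 1L,
                              design = NULL) {
  stopifnot(inherits(model, "pc_model"))
  if (is.null(design)) {
    check_number(M, "M", lower = 1)
    design <- uniform_random_design(M, seed)
  }
  values <- predict(model, design)
  list(design = design, values = values, mE99th = max(values))
}

#' Maximum of a PC surrogate over a dense deterministic angle grid
#'
#' Cross-check of the sweep maximum: evaluates the (cheap polynomial)
#' surrogate on a regular `step_deg` x `step_deg` grid that includes the
#' (inward-clamped) support boundary, and returns the maximum and its
#' location.
#'
#' @param model a `pc_model`.
#' @param step_deg grid resolution in degrees (default 1).
#' @return A list with `max` and the maximizing `theta_deg`, `phi_deg`.
#' @export
grid_max <- function(model, step_deg = 1) {
  th <- unique(c(seq(0, 180, by = step_deg), 180))
  ph <- unique(c(seq(-180, 180, by = step_deg), 180))
  g <- orientation_angles(rep(th, times = length(ph)),
                          rep(ph, each = length(th)))
  v <- predict(model, g)
  i <- which.max(v)
  list(max = v[i], theta_deg = g$theta_deg[i], phi_deg = g$phi_deg[i])
}

#' Worst-case-scenario ratio against the applicable basic restriction
#'
#' `WS% = 100 * mE99th / E_lim`, with the limit chosen by whether the
#' tissue is central-nervous-system tissue of the head.
#'
#' @param mE99th maximum 99th-percentile induced field over the sweep (V/m).
#' @param is_cns_head logical flag selecting the 0.02 V/m limit.
#' @param limits a [regulatory_limits()].
#' @return Percentage.
#' @examples
#' ws_percent(0.02, TRUE)   # 100
#' ws_percent(0.1, FALSE)   # 25
#' @export
ws_percent <- function(mE99th, is_cns_head, limits = regulatory_limits()) {
  check_number(mE99th, "mE99th", lower = 0)
  lim <- if (isTRUE(is_cns_head)) limits$cns_head_limit else
    limits$other_limit
  100 * mE99th / lim
}

#' Classify sweep orientations into high-exposure bands
#'
#' Labels each orientation by its surrogate value relative to the sweep
#' maximum: `ge90` for values at or above 90% of `mE99th`, `b80_89` for
#' [80%, 90%), `b70_79` for [70%, 80%), `below70` otherwise.  The 70%
#' threshold corresponds to a 3 dB amplitude reduction from the maximum
#' (see [band_threshold_db()]).
#'
#' @param values sweep values (V/m).
#' @param mE99th the sweep maximum (> 0).
#' @param thresholds strictly increasing fractions of `mE99th`
#'   (default `c(0.7, 0.8, 0.9)`).
#' @return Factor with levels `below70`, `b70_79`, `b80_89`, `ge90`.
#' @export
band_classify <- function(values, mE99th, thresholds = c(0.7, 0.8, 0.9)) {
  check_number(mE99th, "mE99th", lower = 0, strict_lower = TRUE)
  if (length(thresholds) != 3L || is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must be three strictly increasing fractions in (0, 1)",
         call. = FALSE)
  }
  lev <- c("below70", "b70_79", "b80_89", "ge90")
  r <- values / mE99th
  lab <- lev[1L + findInterval(r, thresholds)]
  factor(lab, levels = lev)
}

#' Amplitude reduction of a band threshold in decibels
#'
#' `20 * log10(1 / threshold)`: the 0.7 default band threshold is a 3 dB
#' reduction from the maximum.
#'
#' @param threshold fraction of the maximum in (0, 1].
#' @return Decibels.
#' @export
band_threshold_db <- function(threshold) {
  check_number(threshold, "threshold", lower = 0, upper = 1,
               strict_lower = TRUE)
  20 * log10(1 / threshold)
}

#' Monte-Carlo solid angle of an orientation region
#'
#' The sweep is uniform in the angles, i.e. has density `1 / (2 pi^2)` per
#' unit `d theta d phi`, not uniform on the sphere.  The area on the unit
#' sphere subtended by a member set is therefore estimated by importance
#' weighting with `sin(theta)`:
#' `Omega = (2 pi^2 / M) * sum(sin(theta_i))` over member orientations,
#' together with the Monte-Carlo standard error of that estimate.
#'
#' @param sweep angle data.frame or `orientation_design` drawn uniform in
#'   the angles, with at least 100 points.
#' @param member logical vector marking the orientations in the region.
#' @return A list with `omega_sr` (steradians) and `se_sr`.
#' @examples
#' d <- uniform_random_design(10000, 7)
#' solid_angle(d, rep(TRUE, 10000))$omega_sr  # ~ 4 * pi
#' @export
solid_angle <- function(sweep, member) {
  a <- as_angles(sweep)
  M <- nrow(a)
  if (M < 100L) {
    stop("at least 100 sweep points are required", call. = FALSE)
  }
  if (length(member) != M || !is.logical(member)) {
    stop("member must be a logical vector matching the sweep",
         call. = FALSE)
  }
  w <- sin(a$theta_deg * pi / 180) * as.numeric(member)
  list(omega_sr = 2 * pi^2 * mean(w),
       se_sr = 2 * pi^2 * stats::sd(w) / sqrt(M))
}

#' Exposure summary for one tissue
#'
#' Combines the analytic moments, the coefficient of variation, the sweep
#' maximum and the worst-case ratio into the one-row summary used by the
#' pipeline's results table.
#'
#' @param model a fitted `pc_model`.
#' @param is_cns_head logical flag for the applicable basic restriction.
#' @param sweep optional precomputed sweep (from [orientation_sweep()]).
#' @param M,seed sweep size and seed when `sweep` is not supplied.
#' @param limits a [regulatory_limits()].
#' @return A one-row data.frame with columns `tissue`, `is_cns_head`,
#'   `mean_V_per_m`, `std_V_per_m`, `cv_percent`, `mE99th_V_per_m`,
#'   `e_lim_V_per_m`, `ws_percent`.
#' @export
summarize_tissue_exposure <- function(model, is_cns_head = FALSE,
                                      sweep = NULL, M = 10000L, seed = 1L,
                                      limits = regulatory_limits()) {
  mom <- moments_from_coefficients(model)
  if (is.null(sweep)) sweep <- orientation_sweep(model, M, seed)
  lim <- if (isTRUE(is_cns_head)) limits$cns_head_limit else
    limits$other_limit
  data.frame(
    tissue = model$tissue,
    is_cns_head = isTRUE(is_cns_head),
    mean_V_per_m = mom$mean,
    std_V_per_m = sqrt(mom$variance),
    cv_percent = coefficient_of_variation(mom$mean, mom$variance),
    mE99th_V_per_m = sweep$mE99th,
    e_lim_V_per_m = lim,
    ws_percent = ws_percent(sweep$mE99th, is_cns_head, limits)
  )
}
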