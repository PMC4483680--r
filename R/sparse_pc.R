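# Sparse polynomial chaos regression: least-angle-regression term
# selection on the orthonormal basis, hybrid least-squares refit of each
# active set, closed-form leave-one-out model choice, and the percentage
# mean-square validation error with its refinement loop over the design
# size N and the degree p.

#' Least-angle-regression inclusion path
#'
#' Classical LARS (Efron et al.) run on the non-constant basis columns,
#' which are centered and scaled to unit norm for the correlation
#' computations only; the constant column is always part of every candidate
#' model.  Counting the intercept-only model as the first candidate, the
#' path describes `m = min(P, N - 1)` nested candidate models, the k-th
#' having `k - 1` non-constant members.  If the active Gram matrix becomes
#' numerically singular the path stops early and reports it.
#'
#' @param design_matrix N x P basis matrix whose first column is constant.
#' @param y length-N response vector.
#' @return An object of class `lars_path`: `order` (original column numbers
#'   of `design_matrix` in inclusion order), `m` (candidate-model count),
#'   `early_stop`, `n`, `P`.
#' @export
lars_path <- function(design_matrix, y) {
  Psi <- as.matrix(design_matrix)
  N <- nrow(Psi)
  P <- ncol(Psi)
  if (N < 2L) stop("at least two observations are required", call. = FALSE)
  if (length(y) != N) stop("y must match the design rows", call. = FALSE)
  if (any(abs(Psi[, 1L] - Psi[1L, 1L]) > 1e-10 * max(1, abs(Psi[1L, 1L])))) {
    stop("the first column of the design matrix must be constant",
         call. = FALSE)
  }
  m <- min(P, N - 1L)
  X <- Psi[, -1L, drop = FALSE]
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  xn <- sqrt(colSums(Xc^2))
  usable <- which(xn > 1e-12 * sqrt(N) * (max(abs(X)) + 1))
  Xs <- sweep(Xc[, usable, drop = FALSE], 2L, xn[usable], "/")
  nsteps <- min(m - 1L, length(usable))
  yc <- y - mean(y)

  active <- integer(0)
  inactive <- seq_along(usable)
  early <- FALSE
  if (nsteps > 0L && sqrt(sum(yc^2)) > 0) {
    cvec <- drop(crossprod(Xs, yc))
    for (step in seq_len(nsteps)) {
      if (length(inactive) == 0L) break
      j <- inactive[which.max(abs(cvec[inactive]))]
      active <- c(active, j)
      inactive <- setdiff(inactive, j)
      s <- sign(cvec[active])
      s[s == 0] <- 1
      XA <- Xs[, active, drop = FALSE] * rep(s, each = N)
      R <- tryCatch(chol(crossprod(XA)), error = function(e) NULL)
      if (is.null(R)) {
        active <- active[-length(active)]
        early <- TRUE
        break
      }
      w <- backsolve(R, backsolve(R, rep(1, length(active)),
                                  transpose = TRUE))
      sw <- sum(w)
      if (!all(is.finite(w)) || sw <= 0) {
        active <- active[-length(active)]
        early <- TRUE
        break
      }
      AA <- 1 / sqrt(sw)
      u <- drop(XA %*% (AA * w))
      a <- drop(crossprod(Xs, u))
      Cmax <- max(abs(cvec[active]))
      gamma_full <- Cmax / AA
      if (length(inactive) > 0L) {
        g <- c((Cmax - cvec[inactive]) / (AA - a[inactive]),
               (Cmax + cvec[inactive]) / (AA + a[inactive]))
        g <- g[is.finite(g) & g > 1e-12 * gamma_full]
        gamma <- if (length(g)) min(g, gamma_full) else gamma_full
      } else {
        gamma <- gamma_full
      }
      cvec <- cvec - gamma * a
    }
  }
  structure(
    list(order = usable[active] + 1L, m = m, early_stop = early,
         n = N, P = P),
    class = "lars_path"
  )
}

#' @export
print.lars_path <- function(x, ...) {
  cat(sprintf("LARS path: %d inclusions (m = %d candidate models%s)\n",
              length(x$order), x$m,
              if (x$early_stop) ", stopped early on rank deficiency" else ""))
  invisible(x)
}

#' Hybrid least-squares refit of an active set
#'
#' Ordinary least squares on the selected columns of the ORIGINAL
#' (unscaled) basis matrix, with the constant column always included.
#' These "hybrid LAR" coefficients are the ones used by every downstream
#' quantity (moments, predictions), because the analytic moment identities
#' require unbiased coefficients on the orthonormal basis.
#'
#' @param design_matrix N x P basis matrix (first column constant).
#' @param y response vector.
#' @param active integer vector of non-constant column numbers of
#'   `design_matrix` to include (may be empty: intercept-only fit).
#' @return Named numeric vector of coefficients, first entry the constant
#'   term.
#' @export
hybrid_ols <- function(design_matrix, y, active = integer(0)) {
  cols <- c(1L, as.integer(active))
  A <- as.matrix(design_matrix)[, cols, drop = FALSE]
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    bad <- cols[qa$pivot[(qa$rank + 1L):ncol(A)]]
    stop(sprintf("singular normal system; offending columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  coefs <- qr.coef(qa, y)
  names(coefs) <- paste0("c", cols)
  coefs
}

#' Relative leave-one-out cross-validation error
#'
#' Closed form requiring no refits: with `h_i` the diagonal of the hat
#' matrix `A (A'A)^{-1} A'`,
#' `err = sum(((y - yhat) / (1 - h))^2) / sum((y - mean(y))^2)`.
#' The error is normalized by the response variance so that it is
#' scale-free.
#'
#' @param A N x q active design matrix (full column rank, N > q).
#' @param y response vector.
#' @param coefficients the least-squares coefficients for `A`.
#' @return Single non-negative number.
#' @export
loo_error <- function(A, y, coefficients) {
  A <- as.matrix(A)
  if (nrow(A) <= ncol(A)) {
    stop("leave-one-out requires more observations than columns",
         call. = FALSE)
  }
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    stop("active matrix is rank deficient", call. = FALSE)
  }
  h <- rowSums(qr.Q(qa)^2)
  if (any(h >= 1 - 1e-10)) {
    stop("an observation has leverage one; leave-one-out undefined",
         call. = FALSE)
  }
  den <- sum((y - mean(y))^2)
  if (den <= 0) {
    stop("constant response: leave-one-out error undefined", call. = FALSE)
  }
  res <- y - drop(A %*% coefficients)
  sum((res / (1 - h))^2) / den
}

new_pc_model <- function(tissue, spec, active, coefficients, loo,
                         n_build) {
  structure(
    list(tissue = tissue, spec = spec,
         active_indices = spec$indices[c(1L, active), , drop = FALSE],
         coefficients = unname(coefficients),
         Q = length(coefficients), loo_error = loo, n_build = n_build,
         pmse_percent = NA_real_),
    class = "pc_model"
  )
}

#' Select the sparse PC model along a LARS path
#'
#' Refits every candidate active set with [hybrid_ols()], computes the
#' closed-form [loo_error()], and returns the candidate with the minimal
#' leave-one-out error (ties broken toward the smaller model).  Candidates
#' whose fit or leave-one-out error fails (rank deficiency, leverage one)
#' are skipped.  A response that is numerically constant across the design
#' short-circuits to the intercept-only model so that degenerate geometries
#' (e.g. a spherical body) do not crash the pipeline.
#'
#' @param path a [lars_path()].
#' @param design_matrix the basis matrix the path was computed on.
#' @param y response vector.
#' @param spec the [basis_spec()] describing the columns.
#' @param tissue tissue label stored in the model.
#' @return An object of class `pc_model` with elements `tissue`, `spec`,
#'   `active_indices` (constant index first), `coefficients`, `Q`,
#'   `loo_error`, `n_build`; attribute `"loo_path"` records the error at
#'   every usable path step.
#' @export
select_model <- function(path, design_matrix, y, spec,
                         tissue = "response") {
  stopifnot(inherits(path, "lars_path"), inherits(spec, "basis_spec"))
  Psi <- as.matrix(design_matrix)
  N <- nrow(Psi)
  ybar <- mean(y)
  if (stats::sd(y) <= 1e-12 * (abs(ybar) + .Machine$double.xmin)) {
    mod <- new_pc_model(tissue, spec, integer(0), ybar, 0, N)
    attr(mod, "loo_path") <- data.frame(Q = 1L, loo_error = 0)
    return(mod)
  }
  best <- NULL
  steps <- c(list(integer(0)),
             lapply(seq_along(path$order),
                    function(k) path$order[seq_len(k)]))
  loo_rows <- vector("list", length(steps))
  for (k in seq_along(steps)) {
    act <- steps[[k]]
    fit <- tryCatch({
      coefs <- hybrid_ols(Psi, y, act)
      loo <- loo_error(Psi[, c(1L, act), drop = FALSE], y, coefs)
      list(coefs = coefs, loo = loo)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    loo_rows[[k]] <- data.frame(Q = length(act) + 1L, loo_error = fit$loo)
    if (is.null(best) || fit$loo < best$loo) {
      best <- list(act = act, coefs = fit$coefs, loo = fit$loo)
    }
  }
  if (is.null(best)) {
    stop("all candidate models along the path failed", call. = FALSE)
  }
  mod <- new_pc_model(tissue, spec, best$act, best$coefs, best$loo, N)
  attr(mod, "loo_path") <- do.call(rbind, loo_rows[!vapply(loo_rows,
                                                           is.null,
                                                           logical(1))])
  mod
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf(
    "Sparse PC model [%s]: Q = %d of P = %d terms (p = %d), N = %d\n",
    x$tissue, x$Q, x$spec$P, x$spec$p, x$n_build))
  cat(sprintf("  mean = %.6g, LOO error = %.3g", x$coefficients[1L],
              x$loo_error))
  if (is.finite(x$pmse_percent)) {
    cat(sprintf(", validation pMSE = %.3g%%", x$pmse_percent))
  }
  cat("\n")
  invisible(x)
}

#' Predict from a sparse PC model
#'
#' @param object a `pc_model`.
#' @param newdata orientation angles (data.frame with `theta_deg`,
#'   `phi_deg`), an `orientation_design`, or a matrix of standardized
#'   coordinates in `[-1, 1]^K`.
#' @param ... unused.
#' @return Numeric vector of surrogate values.
#' @export
predict.pc_model <- function(object, newdata, ...) {
  xi <- if (is.matrix(newdata) && !("theta_deg" %in% colnames(newdata))) {
    newdata
  } else {
    standardize_angles(newdata)
  }
  drop(evaluate_index_set(xi, object$active_indices) %*%
         object$coefficients)
}

#' Percentage mean-square validation error
#'
#' `pMSE = 100 / S * sum(((y_val - y_pred) / y_val)^2)`: the mean squared
#' RELATIVE prediction error on an independent validation set, in percent.
#'
#' @param y_val validation responses (all nonzero).
#' @param y_pred surrogate predictions, same length.
#' @return Single non-negative number (percent).
#' @examples
#' pmse(c(1, 2), c(1.1, 2))  # 0.5
#' @export
pmse <- function(y_val, y_pred) {
  if (length(y_val) != length(y_pred) || length(y_val) == 0L) {
    stop("y_val and y_pred must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(y_val == 0)) {
    stop("zero validation value: relative error undefined", call. = FALSE)
  }
  mean(((y_val - y_pred) / y_val)^2) * 100
}

#' Fit a sparse PC surrogate with refinement over N and p
#'
#' For each design size `N` in `n_grid` (nested Sobol build designs) and
#' each maximum degree `p` in `p_grid`, fits the hybrid-LAR model with
#' leave-one-out selection and validates it on a fresh pseudo-random design
#' of size `S = N/2` (seeded from `seeds$validation`, offset by the
#' position of `N` in the grid).  The loop stops at the first `(N, p)`
#' whose percentage mean-square error falls below `tau_percent`; if none
#' does, the best-pMSE model is returned with `converged = FALSE`.
#'
#' @param solver function mapping an angle data.frame to a numeric response
#'   vector (e.g. a closure over [e99th_batch()], or a lookup into
#'   observations from an external deterministic solver).
#' @param n_grid,p_grid ascending integer grids of design sizes and degrees.
#' @param tau_percent convergence threshold on the pMSE, in percent
#'   (default 0.5).
#' @param seeds list with element `validation` (integer seed).
#' @param sobol_skip initial Sobol points to drop (default 1).
#' @param tissue label attached to the fitted model.
#' @param build_responses optional precomputed responses aligned with
#'   `sobol_design(max(n_grid), sobol_skip)`; positions may be `NA` and are
#'   then filled by calling `solver` (designs are nested, so a prefix
#'   serves every `N`).
#' @param validation optional fixed validation set, a list with `points`
#'   (angle data.frame) and `y` (responses): used for every `(N, p)` trial
#'   instead of generating seeded designs.  This is how observation tables
#'   from an external deterministic solver are validated.
#' @return A list with `model` (the selected [select_model()] fit, with
#'   `pmse_percent` set) and `report` (class `fit_report`: every trial's
#'   `N`, `p`, `Q`, LOO and pMSE, the threshold, and the convergence flag).
#' @export
adaptive_fit <- function(solver, n_grid, p_grid, tau_percent = 0.5,
                         seeds = list(validation = 1L), sobol_skip = 1L,
                         tissue = "response", build_responses = NULL,
                         validation = NULL) {
  if (length(n_grid) == 0L || length(p_grid) == 0L) {
    stop("n_grid and p_grid must be non-empty", call. = FALSE)
  }
  if (is.unsorted(n_grid, strictly = TRUE) ||
      is.unsorted(p_grid, strictly = TRUE)) {
    stop("n_grid and p_grid must be strictly ascending", call. = FALSE)
  }
  if (!is.numeric(tau_percent) || length(tau_percent) != 1L ||
      is.na(tau_percent) || tau_percent <= 0) {
    stop("tau_percent must be a single positive number", call. = FALSE)
  }
  n_max <- max(n_grid)
  build_full <- sobol_design(n_max, sobol_skip)
  yb_full <- build_responses %||% rep(NA_real_, n_max)
  if (length(yb_full) != n_max) {
    stop("build_responses must align with sobol_design(max(n_grid))",
         call. = FALSE)
  }
  call_solver <- function(pts, what, N, p) {
    tryCatch(as.numeric(solver(pts)), error = function(e) {
      stop(sprintf("solver failed on the %s set (tissue %s, N = %d, p = %s): %s",
                   what, tissue, N, p, conditionMessage(e)), call. = FALSE)
    })
  }
  trials <- list()
  best <- NULL
  for (ni in seq_along(n_grid)) {
    N <- n_grid[ni]
    miss <- which(is.na(yb_full[seq_len(N)]))
    if (length(miss)) {
      yb_full[miss] <- call_solver(build_full$points[miss, , drop = FALSE],
                                   "build", N, "-")
    }
    yb <- yb_full[seq_len(N)]
    if (is.null(validation)) {
      S <- max(1L, as.integer(round(N / 2)))
      vdes <- uniform_random_design(S, seeds$validation + (ni - 1L))
      if (nrow(merge(vdes$points, build_full$points[seq_len(N), ])) > 0L) {
        stop("validation design collides with the build design",
             call. = FALSE)
      }
      vpts <- vdes$points
      yv <- call_solver(vpts, "validation", N, "-")
    } else {
      vpts <- as_angles(validation$points)
      yv <- as.numeric(validation$y)
    }
    xi_build <- standardize_angles(build_full$points[seq_len(N), ])
    for (p in p_grid) {
      spec <- basis_spec(2L, p)
      Psi <- evaluate_basis(xi_build, spec)
      model <- select_model(lars_path(Psi, yb), Psi, yb, spec,
                            tissue = tissue)
      pm <- pmse(yv, predict(model, vpts))
      model$pmse_percent <- pm
      trials[[length(trials) + 1L]] <-
        data.frame(N = N, p = p, Q = model$Q, loo_error = model$loo_error,
                   pmse_percent = pm)
      if (is.null(best) || pm < best$model$pmse_percent) {
        best <- list(model = model, N = N, p = p)
      }
      if (pm < tau_percent) {
        return(finish_fit(best, trials, tau_percent, n_grid, p_grid,
                          converged = TRUE))
      }
    }
  }
  finish_fit(best, trials, tau_percent, n_grid, p_grid, converged = FALSE)
}

finish_fit <- function(best, trials, tau_percent, n_grid, p_grid,
                       converged) {
  report <- structure(
    list(trials = do.call(rbind, trials), tau_percent = tau_percent,
         n_grid = n_grid, p_grid = p_grid, converged = converged,
         selected = c(N = best$N, p = best$p),
         pmse_percent = best$model$pmse_percent),
    class = "fit_report"
  )
  list(model = best$model, report = report)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "Refinement over N x p: %d trials, %s at (N = %d, p = %d), pMSE = %.4g%% (tau = %g%%)\n",
    nrow(x$trials),
    if (x$converged) "converged" else "NOT converged; best",
    x$selected["N"], x$selected["p"], x$pmse_percent, x$tau_percent))
  invisible(x)
}

#' Serialize a fitted PC model to JSON
#'
#' @param model a `pc_model`.
#' @param path output file; with `path = NULL` the JSON string is returned.
#' @param seeds optional named list of seeds recorded alongside the model.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_pc_model <- function(model, path = NULL, seeds = NULL) {
  stopifnot(inherits(model, "pc_model"))
  obj <- list(
    tissue = model$tissue, K = model$spec$K, p = model$spec$p,
    convention_note = paste(
      "z vertical head-to-toe, x front-to-back, y right-to-left;",
      "u = (sin t cos p, sin t sin p, cos t);",
      "orthonormal Legendre basis on xi1 = theta/90 - 1, xi2 = phi/180"),
    active_indices = unname(apply(model$active_indices, 1L, identity,
                                  simplify = FALSE)),
    coefficients = model$coefficients, Q = model$Q,
    loo_error = model$loo_error, n_build = model$n_build,
    seeds = seeds, pmse_percent = model$pmse_percent)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a PC model serialized by [write_pc_model()]
#'
#' @param path JSON file.
#' @return A `pc_model`.
#' @export
read_pc_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  spec <- basis_spec(obj$K, obj$p)
  idx <- matrix(as.integer(t(obj$active_indices)), ncol = obj$K,
                byrow = TRUE)
  mod <- structure(
    list(tissue = obj$tissue, spec = spec, active_indices = idx,
         coefficients = as.numeric(obj$coefficients), Q = obj$Q,
         loo_error = obj$loo_error, n_build = obj$n_build,
         pmse_percent = obj$pmse_percent %||% NA_real_),
    class = "pc_model"
  )
  mod
}
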