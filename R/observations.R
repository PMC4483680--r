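# Observation sets: paired orientation designs and per-tissue E_99th
# responses, produced by the virtual solver or supplied as CSV by a user
# running their own deterministic solver.

#' Bundle a design with per-tissue responses
#'
#' @param design an `orientation_design`.
#' @param responses data.frame, one column per tissue, rows aligned with
#'   the design points; all values must be strictly positive and finite.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(design, responses) {
  stopifnot(inherits(design, "orientation_design"))
  responses <- as.data.frame(responses)
  if (nrow(responses) != nrow(design$points)) {
    stop("responses must have one row per design point", call. = FALSE)
  }
  if (ncol(responses) == 0L) {
    stop("at least one response column is required", call. = FALSE)
  }
  for (nm in names(responses)) {
    v <- responses[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("response %s must be strictly positive and finite", nm),
           call. = FALSE)
    }
  }
  structure(list(design = design, responses = responses),
            class = "observation_set")
}

#' Evaluate the virtual solver over a design, for every tissue
#'
#' Runs [e99th_batch()] for the fetus whole body and each tissue of a
#' gestational-age fixture.  With `noise_cv > 0` each tissue receives an
#' independent, reproducible noise stream (the configured `noise_seed`
#' offset by the tissue's position).
#'
#' @param ga a [ga_fixture()].
#' @param design an `orientation_design`.
#' @param config a [solver_config()].
#' @param tissues tissue names to evaluate (default: all).
#' @param include_whole_body prepend the `whole_body` column (default TRUE).
#' @return An [observation_set()].
#' @export
observe <- function(ga, design, config = solver_config(), tissues = NULL,
                    include_whole_body = TRUE) {
  stopifnot(inherits(ga, "ga_model"))
  tissues <- tissues %||% names(ga$tissues)
  regions <- ga$tissues[tissues]
  if (include_whole_body) {
    regions <- c(list(whole_body = ga$fetus_whole_body), regions)
  }
  responses <- as.data.frame(lapply(seq_along(regions), function(i) {
    cfg <- config
    cfg$noise_seed <- config$noise_seed + i - 1L
    e99th_batch(regions[[i]], design, ga$body, cfg)
  }))
  names(responses) <- names(regions)
  observation_set(design, responses)
}

#' Write an observation set as CSV
#'
#' Dialect shared with external deterministic solvers: comma-separated,
#' `.` decimal, one header line `theta_deg,phi_deg,<tissue>,...`, angles in
#' degrees and responses in V/m.  Numbers are written with 17 significant
#' digits so a write/read round trip is bit-exact.
#'
#' @param path output file.
#' @param obs an [observation_set()].
#' @export
write_observations <- function(path, obs) {
  stopifnot(inherits(obs, "observation_set"))
  tab <- cbind(obs$design$points, obs$responses)
  txt <- vapply(seq_len(nrow(tab)), function(i) {
    paste(sprintf("%.17g", as.numeric(tab[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(paste(names(tab), collapse = ","), txt), path)
  invisible(path)
}

#' Read an observation CSV
#'
#' Strict parse of the dialect written by [write_observations()]: the
#' first two columns must be `theta_deg` and `phi_deg`, every cell must be
#' numeric, and responses must be strictly positive (a zero response would
#' make the relative validation error undefined).  Errors name the
#' offending row and column.
#'
#' @param path CSV file.
#' @param kind design kind recorded on the result (`"sobol"` or
#'   `"uniform_random"`; external designs default to `"uniform_random"`).
#' @return An [observation_set()].
#' @export
read_observations <- function(path, kind = "uniform_random") {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (ncol(tab) < 3L ||
      !identical(names(tab)[1:2], c("theta_deg", "phi_deg"))) {
    stop("header must start with theta_deg,phi_deg and name >= 1 tissue",
         call. = FALSE)
  }
  for (j in seq_along(tab)) {
    v <- tab[[j]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1L] %||% 1L
      stop(sprintf("non-numeric cell at row %d, column %s", bad,
                   names(tab)[j]), call. = FALSE)
    }
    if (j > 2L && any(v <= 0)) {
      stop(sprintf("non-positive response at row %d, column %s",
                   which(v <= 0)[1L], names(tab)[j]), call. = FALSE)
    }
  }
  design <- new_design(kind,
                       orientation_angles(tab$theta_deg, tab$phi_deg),
                       NA_integer_)
  observation_set(design, tab[, -(1:2), drop = FALSE])
}
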