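# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the user's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  }
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi) {
    stop(sprintf("%s = %g is outside the admissible range", name, x),
         call. = FALSE)
  }
  x
}

# 99th-percentile with the linear-interpolation order-statistic definition
# (quantile type 7), via partial sorting: only the two relevant order
# statistics are placed, which matters on point clouds of ~1e5 points.
pctl99 <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty sample", call. = FALSE)
  if (n == 1L) return(x[1L])
  h <- (n - 1) * 0.99 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs <- sort(x, partial = unique(c(lo, hi)))
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
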