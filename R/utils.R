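# Internal helpers shared across modules.

# Error constructors: every user-facing failure is a classed condition so
# callers (and the pipeline's error isolation) can discriminate failure modes.
stop_filmrheo <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "filmrheo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_validation <- function(msg, ...) stop_filmrheo(msg, "filmrheo_validation_error", ...)
stop_format     <- function(msg, ...) stop_filmrheo(msg, "filmrheo_format_error", ...)
stop_range      <- function(msg, ...) stop_filmrheo(msg, "filmrheo_range_error", ...)

assert_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L)
    stop_validation(sprintf("'%s' must be a non-empty numeric vector", name))
  if (finite && !all(is.finite(x)))
    stop_validation(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(sprintf("'%s' must be a single finite number", name))
  ok_lo <- if (open_lower) x > lower else x >= lower
  ok_hi <- if (open_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop_validation(sprintf("'%s' = %g is outside the admissible range", name, x))
  invisible(x)
}

assert_increasing <- function(x, name) {
  if (length(x) < 2L || any(diff(x) <= 0))
    stop_validation(sprintf("'%s' must be strictly increasing with at least 2 samples", name))
  invisible(x)
}

# Local maxima of a series with topographic prominence (lowest saddle to the
# nearer higher ground on each side). Returns indices and prominences.
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  idx <- integer(0); prom <- numeric(0)
  if (n < 3L) return(list(index = idx, prominence = prom))
  for (i in 2:(n - 1L)) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L]) {
      left <- y[seq_len(i - 1L)]
      right <- y[(i + 1L):n]
      hi_l <- which(left > y[i])
      valley_l <- if (length(hi_l)) min(left[max(hi_l):(i - 1L)]) else min(left)
      hi_r <- which(right > y[i])
      valley_r <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else min(right)
      p <- y[i] - max(valley_l, valley_r)
      if (p >= min_prominence) {
        idx <- c(idx, i)
        prom <- c(prom, p)
      }
    }
  }
  list(index = idx, prominence = prom)
}

# Linear interpolation of a (x, y) branch onto 'grid'; x need not be sorted.
interp_branch <- function(x, y, grid) {
  o <- order(x)
  stats::approx(x[o], y[o], xout = grid, ties = mean)$y
}

# Full-precision number formatting so written files round-trip exactly.
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.17g", v)
    # shortest representation that still round-trips
    for (d in 1:16) {
      c2 <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(c2) == v) return(c2)
    }
    s
  }, character(1))
}

# Evaluate an expression with a temporarily seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_scalar(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
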