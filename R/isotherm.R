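# pi-A isotherm cycle analytics.
#
# Compression branches (not expansion) feed shifts and squeeze-out detection,
# matching the reading of surfactant penetration upon compression; a `branch`
# argument switches where relevant. Area units are carried opaquely and must
# match between compared recordings - per-molecule normalization would need
# molecule counts the recording lacks, so no implicit conversion is done.

#' Split a trough recording into compression-expansion cycles
#'
#' Delimits cycles at local extrema of the area trace, ignoring jitter
#' through a minimum-excursion filter: a turning point is committed only
#' once the trace has moved away from it by at least `min_excursion` times
#' the total area range. A cycle runs from one area maximum to the next;
#' its compression branch has decreasing area, its expansion branch
#' increasing area. Samples before the first maximum or after the last
#' complete cycle are reported in the `partial` attribute. Every sample of
#' the recording belongs to exactly one branch of one cycle or to a partial
#' segment.
#'
#' @param x A [trough_recording()].
#' @param min_excursion Minimum turning-point excursion as a fraction of the
#'   recorded area range (default 0.05).
#' @return A list of `isotherm_cycle` objects (fields `index`,
#'   `compression`, `expansion`, each branch a data frame `time`, `area`,
#'   `pi`), with attributes `partial` (data frame of leftover samples) and
#'   `area_unit`. An empty list, with a warning, if no complete cycle
#'   exists.
#' @export
split_cycles <- function(x, min_excursion = 0.05) {
  stopifnot(inherits(x, "trough_recording"))
  assert_scalar(min_excursion, "min_excursion", lower = 0, upper = 1)
  a <- x$area
  n <- length(a)
  rng <- diff(range(a))
  thr <- min_excursion * rng
  if (rng <= 0) {
    warning("area trace is constant: no cycles")
    return(empty_cycles(x))
  }

  # zigzag turning-point scan with excursion hysteresis
  turns <- integer(0)       # committed turning-point indices
  kinds <- character(0)     # "max" or "min"
  imax <- 1L; imin <- 1L    # running extremum candidates
  dir <- 0L                 # +1 rising, -1 falling, 0 undecided
  commit_max <- function(i) {
    turns <<- c(turns, imax); kinds <<- c(kinds, "max"); dir <<- -1L; imin <<- i
  }
  commit_min <- function(i) {
    turns <<- c(turns, imin); kinds <<- c(kinds, "min"); dir <<- 1L; imax <<- i
  }
  for (i in 2:n) {
    if (a[i] > a[imax]) imax <- i
    if (a[i] < a[imin]) imin <- i
    if (dir == 0L) {
      if (a[imax] - a[i] >= thr) commit_max(i)
      else if (a[i] - a[imin] >= thr) commit_min(i)
    } else if (dir == -1L) {
      if (a[i] - a[imin] >= thr) commit_min(i)
    } else {
      if (a[imax] - a[i] >= thr) commit_max(i)
    }
  }
  # trailing extremum of the final ramp
  if (dir == -1L) { turns <- c(turns, imin); kinds <- c(kinds, "min") }
  else            { turns <- c(turns, imax); kinds <- c(kinds, "max") }

  maxima <- turns[kinds == "max"]
  cycles <- list()
  used <- rep(FALSE, n)
  ci <- 0L
  for (k in seq_along(maxima)) {
    if (k == length(maxima)) break
    i0 <- maxima[k]; i2 <- maxima[k + 1L]
    mins_between <- turns[kinds == "min" & turns > i0 & turns < i2]
    if (!length(mins_between)) next
    i1 <- mins_between[1L]
    ci <- ci + 1L
    start <- if (ci == 1L) i0 else i0 + 1L   # partition: no shared samples
    comp_idx <- start:i1
    exp_idx <- (i1 + 1L):i2
    used[c(comp_idx, exp_idx)] <- TRUE
    cycles[[ci]] <- structure(list(
      index = ci,
      compression = data.frame(time = x$time[comp_idx], area = x$area[comp_idx],
                               pi = x$pi[comp_idx]),
      expansion = data.frame(time = x$time[exp_idx], area = x$area[exp_idx],
                             pi = x$pi[exp_idx])),
      class = "isotherm_cycle")
  }

  if (!length(cycles)) {
    warning("no complete compression-expansion cycle found")
    return(empty_cycles(x, used))
  }
  attr(cycles, "partial") <- data.frame(time = x$time[!used], area = x$area[!used],
                                        pi = x$pi[!used])
  attr(cycles, "area_unit") <- x$area_unit
  cycles
}

empty_cycles <- function(x, used = rep(FALSE, length(x$time))) {
  out <- list()
  attr(out, "partial") <- data.frame(time = x$time[!used], area = x$area[!used],
                                     pi = x$pi[!used])
  attr(out, "area_unit") <- x$area_unit
  out
}

#' @export
print.isotherm_cycle <- function(x, ...) {
  cat(sprintf("Isotherm cycle %d: compression %d samples (area %.4g -> %.4g), expansion %d samples\n",
              x$index, nrow(x$compression), x$compression$area[1],
              x$compression$area[nrow(x$compression)], nrow(x$expansion)))
  invisible(x)
}

get_branch <- function(cycle_or_branch, branch = "compression") {
  if (inherits(cycle_or_branch, "isotherm_cycle"))
    return(cycle_or_branch[[branch]])
  b <- as.data.frame(cycle_or_branch)
  if (!all(c("area", "pi") %in% names(b)))
    stop_validation("an isotherm branch needs columns 'area' and 'pi'")
  b
}

# common area grid: intersection of ranges, sampled at the finer branch
common_grid <- function(branches) {
  lo <- max(vapply(branches, function(b) min(b$area), 0))
  hi <- min(vapply(branches, function(b) max(b$area), 0))
  if (lo >= hi)
    stop_filmrheo("isotherm branches do not overlap in area",
                  "filmrheo_overlap_error")
  counts <- vapply(branches, function(b) sum(b$area >= lo & b$area <= hi), 0L)
  fine <- branches[[which.max(counts)]]
  g <- sort(unique(fine$area[fine$area >= lo & fine$area <= hi]))
  if (length(g) < 2L) g <- seq(lo, hi, length.out = 16L)
  g
}

#' First cycle from which consecutive isotherms are stationary
#'
#' Repeated cycling reshapes a film until its pi(A) curve attains a
#' stationary shape. This detector returns the smallest cycle index `k`
#' such that every later pair of consecutive compression branches differs
#' by less than `tol`, where the distance between two branches is the
#' maximum absolute pressure difference over their common area grid.
#'
#' @param cycles A list of cycles from [split_cycles()].
#' @param tol Stationarity tolerance in mN/m; default 2 percent of the
#'   maximum pressure over all cycles (echoing the typical replicate
#'   spread of trough experiments).
#' @return The stationarity onset index (integer), or `NA` if the curves
#'   never become stationary. The vector of consecutive-pair distances is
#'   attached as attribute `distances`.
#' @export
stationarity_index <- function(cycles, tol = NULL) {
  if (length(cycles) < 2L)
    stop_validation("need at least 2 cycles to assess stationarity")
  if (is.null(tol))
    tol <- 0.02 * max(vapply(cycles, function(cy) max(cy$compression$pi), 0))
  assert_scalar(tol, "tol", lower = 0, open_lower = TRUE)
  d <- vapply(seq_len(length(cycles) - 1L), function(k) {
    b1 <- cycles[[k]]$compression
    b2 <- cycles[[k + 1L]]$compression
    g <- common_grid(list(b1, b2))
    max(abs(interp_branch(b1$area, b1$pi, g) - interp_branch(b2$area, b2$pi, g)))
  }, 0)
  ok <- rev(cumprod(rev(d < tol))) > 0   # d[k..end] all below tol
  idx <- if (any(ok)) which(ok)[1L] else NA_integer_
  structure(idx, distances = d)
}

#' Average replicate compression branches
#'
#' Interpolates two or more compression branches onto a common area grid
#' (linear interpolation; the grid is the intersection of the area ranges
#' sampled at the finest branch) and returns the pointwise mean and
#' standard deviation, plus the maximum pairwise relative deviation for
#' quality control against the typical replicate spread of a few percent.
#' The relative deviation of a pair at a grid point is their absolute
#' difference over the magnitude of their average.
#'
#' @param branches List of at least 2 branches (data frames with `area`,
#'   `pi`, or `isotherm_cycle` objects whose compression branch is taken).
#' @return An object of class `isotherm_average`: data frame `area`,
#'   `mean`, `sd` with attribute `max_pairwise_rel_dev`.
#' @export
average_isotherms <- function(branches) {
  if (length(branches) < 2L)
    stop_validation("need at least 2 branches to average")
  bs <- lapply(branches, get_branch)
  g <- common_grid(bs)
  mat <- vapply(bs, function(b) interp_branch(b$area, b$pi, g),
                numeric(length(g)))
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  maxdev <- 0
  for (i in seq_len(ncol(mat) - 1L)) for (j in (i + 1L):ncol(mat)) {
    denom <- pmax(abs(mat[, i] + mat[, j]) / 2, .Machine$double.eps)
    maxdev <- max(maxdev, abs(mat[, i] - mat[, j]) / denom)
  }
  structure(data.frame(area = g, mean = mu, sd = sdv),
            max_pairwise_rel_dev = maxdev, class = c("isotherm_average", "data.frame"))
}

#' Pressure shift between two isotherm branches
#'
#' Computes the condition-versus-control shift \eqn{\Delta\pi(A) =
#' \pi_{test}(A) - \pi_{ref}(A)} over the overlap of two compression
#' branches, interpolated linearly onto a common area grid. An upward
#' shift indicates that subphase material penetrates the film, increasing
#' its molecular packing.
#'
#' The shift is antisymmetric: swapping `ref` and `test` negates it
#' pointwise.
#'
#' @param ref,test Compression branches (data frames with `area`, `pi`, or
#'   `isotherm_cycle` objects) measured in the same area unit.
#' @param branch Which branch of a cycle to use (default `"compression"`).
#' @return An object of class `isotherm_comparison`: list with `area`
#'   (grid), `shift` (mN/m), `pi_ref`, `pi_test`, `mean_shift`,
#'   `max_shift`.
#' @export
pressure_shift <- function(ref, test, branch = "compression") {
  bref <- get_branch(ref, branch)
  btest <- get_branch(test, branch)
  g <- common_grid(list(bref, btest))
  pr <- interp_branch(bref$area, bref$pi, g)
  pt <- interp_branch(btest$area, btest$pi, g)
  shift <- pt - pr
  structure(list(area = g, shift = shift, pi_ref = pr, pi_test = pt,
                 mean_shift = mean(shift), max_shift = max(shift)),
            class = "isotherm_comparison")
}

#' @export
print.isotherm_comparison <- function(x, ...) {
  cat(sprintf("Isotherm comparison on %d grid points: mean shift %.3f mN/m, max shift %.3f mN/m\n",
              length(x$area), x$mean_shift, x$max_shift))
  invisible(x)
}

#' Squeeze-out pressure of an incorporated surfactant
#'
#' A surfactant that penetrates a film at low pressure but is expelled on
#' lateral compression shows up as a pressure shift that vanishes above a
#' characteristic surface pressure. Scanning the comparison in the
#' compression direction (decreasing area, increasing pressure), this
#' detector returns the lowest pressure on the test branch at and above
#' which the shift stays below `threshold` through the rest of the
#' compression. The sustained criterion (all remaining samples, not a
#' single crossing) makes the detector robust to noise. If the shift never
#' vanishes - persistent incorporation - the result is `NA`.
#'
#' A larger threshold never yields a larger detected pressure.
#'
#' @param cmp An [pressure_shift()] comparison.
#' @param threshold Shift-vanishing threshold in mN/m (default 0.5).
#' @return The squeeze-out pressure in mN/m, or `NA` if the shift persists
#'   to the end of compression. If the shift is below threshold
#'   everywhere, the lowest pressure of the test branch is returned.
#' @export
squeeze_out_pressure <- function(cmp, threshold = 0.5) {
  stopifnot(inherits(cmp, "isotherm_comparison"))
  assert_scalar(threshold, "threshold", lower = 0, open_lower = TRUE)
  o <- order(cmp$area, decreasing = TRUE)     # compression direction
  shift <- cmp$shift[o]
  pt <- cmp$pi_test[o]
  below <- rev(cumprod(rev(shift < threshold))) > 0  # sustained to the end
  if (!below[length(below)] || !any(below)) return(NA_real_)
  j <- which(below)[1L]
  pt[j]
}

#' Hysteresis loop area of a cycle
#'
#' The absolute area enclosed between the compression and expansion
#' branches of a cycle, in mN/m times the recording's area unit, computed
#' by trapezoidal integration of the surface pressure around the loop in
#' recorded order (equivalent to the shoelace formula for the loop
#' polygon). Identical branches give 0.
#'
#' @param cycle An `isotherm_cycle` from [split_cycles()].
#' @return The enclosed area (non-negative scalar).
#' @export
hysteresis_area <- function(cycle) {
  stopifnot(inherits(cycle, "isotherm_cycle"))
  a <- c(cycle$compression$area, cycle$expansion$area)
  p <- c(cycle$compression$pi, cycle$expansion$pi)
  # close the loop and integrate pi dA around it
  a2 <- c(a, a[1]); p2 <- c(p, p[1])
  abs(sum(diff(a2) * (p2[-length(p2)] + p2[-1]) / 2))
}
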