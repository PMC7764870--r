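#' Stress-relaxation transient
#'
#' A surface-pressure record following a small rapid compression of the film
#' area. Time zero marks the end of the area step; samples at negative times,
#' if supplied, are used only to estimate the pre-step baseline `pi0` (their
#' mean) and are then dropped from the record.
#'
#' @param time Time in seconds, strictly increasing.
#' @param pi Surface pressure in mN/m at each time.
#' @param strain Relative area step \eqn{\Delta A/A_0}, dimensionless, in
#'   (0, 0.2]. The experimental protocol uses 0.05 +/- 0.01.
#' @param pi0 Pre-step baseline surface pressure in mN/m. Required unless
#'   pre-step samples (`time < 0`) are present, in which case it defaults to
#'   their mean.
#' @param meta Named list of free-form labels (sample, subphase, temperature).
#'
#' @return An object of class `relaxation_transient`: a list with elements
#'   `time`, `pi`, `pi0`, `strain`, `meta`.
#' @examples
#' tr <- relaxation_transient(time = 0:100, pi = 20 + 10 * exp(-(0:100) / 25),
#'                            strain = 0.05, pi0 = 20)
#' tr
#' @export
relaxation_transient <- function(time, pi, strain, pi0 = NULL, meta = list()) {
  assert_numeric(time, "time")
  assert_numeric(pi, "pi")
  if (length(time) != length(pi))
    stop_validation("'time' and 'pi' must have equal length")
  assert_increasing(time, "time")
  assert_scalar(strain, "strain", lower = 0, upper = 0.2, open_lower = TRUE)

  pre <- time < 0
  if (any(pre)) {
    if (is.null(pi0)) pi0 <- mean(pi[pre])
    time <- time[!pre]
    pi <- pi[!pre]
    if (length(time) < 2L)
      stop_validation("fewer than 2 samples at time >= 0")
  }
  if (is.null(pi0))
    stop_validation("'pi0' is required when no pre-step (time < 0) samples are present")
  assert_scalar(pi0, "pi0")
  if (max(pi) < pi0 - 1e-9)
    stop_validation("max(pi) < pi0: not a compression step (pressure must rise above baseline)")

  structure(
    list(time = as.numeric(time), pi = as.numeric(pi),
         pi0 = as.numeric(pi0), strain = as.numeric(strain),
         meta = as.list(meta)),
    class = "relaxation_transient"
  )
}

#' @export
print.relaxation_transient <- function(x, ...) {
  cat(sprintf(
    "Relaxation transient: %d samples, t = [%g, %g] s\n  pi0 = %.3f mN/m, pi_max = %.3f mN/m, strain = %.3f\n",
    length(x$time), min(x$time), max(x$time), x$pi0, max(x$pi), x$strain))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Trough cycle recording
#'
#' A (time, area, surface pressure) record of repeated compression-expansion
#' cycling in a Langmuir trough. The area unit is carried opaquely
#' (e.g. `"cm^2"` for natural films, `"A^2/molecule"` for synthetic films);
#' comparisons between recordings require matching units.
#'
#' @param time Time in seconds.
#' @param area Trough surface area, positive everywhere.
#' @param pi Surface pressure in mN/m.
#' @param area_unit Unit tag for `area`.
#' @param meta Named list of free-form labels.
#' @return An object of class `trough_recording`.
#' @examples
#' a <- c(10:2, 3:10)
#' trough_recording(time = seq_along(a), area = a, pi = 30 - 2 * a)
#' @export
trough_recording <- function(time, area, pi, area_unit = "cm^2", meta = list()) {
  assert_numeric(time, "time")
  assert_numeric(area, "area")
  assert_numeric(pi, "pi")
  if (length(unique(c(length(time), length(area), length(pi)))) != 1L)
    stop_validation("'time', 'area' and 'pi' must have equal length")
  assert_increasing(time, "time")
  if (any(area <= 0))
    stop_validation("'area' must be positive everywhere")
  structure(
    list(time = as.numeric(time), area = as.numeric(area),
         pi = as.numeric(pi), area_unit = as.character(area_unit)[1],
         meta = as.list(meta)),
    class = "trough_recording"
  )
}

#' @export
print.trough_recording <- function(x, ...) {
  cat(sprintf(
    "Trough recording: %d samples, area = [%g, %g] %s, pi = [%.2f, %.2f] mN/m\n",
    length(x$time), min(x$area), max(x$area), x$area_unit, min(x$pi), max(x$pi)))
  invisible(x)
}

#' Penetration-kinetics trace
#'
#' A surface-pressure time series recorded after injecting a surfactant
#' beneath a pre-formed film. Time zero is the injection; samples at negative
#' times, if present, estimate the pre-injection equilibration pressure `pi0`.
#'
#' @param time Time in seconds since injection, strictly increasing.
#' @param pi Surface pressure in mN/m.
#' @param pi0 Pre-injection equilibration pressure in mN/m; defaults to the
#'   mean of pre-injection (`time < 0`) samples when present.
#' @param meta Named list of labels.
#' @return An object of class `kinetics_trace`.
#' @examples
#' t <- 0:600
#' kinetics_trace(t, 18 + 15 * (1 - exp(-t / 20)) * exp(-t / 300), pi0 = 18)
#' @export
kinetics_trace <- function(time, pi, pi0 = NULL, meta = list()) {
  assert_numeric(time, "time")
  assert_numeric(pi, "pi")
  if (length(time) != length(pi))
    stop_validation("'time' and 'pi' must have equal length")
  assert_increasing(time, "time")
  if (is.null(pi0)) {
    pre <- time < 0
    if (!any(pre))
      stop_validation("'pi0' is required when no pre-injection (time < 0) samples are present")
    pi0 <- mean(pi[pre])
  }
  assert_scalar(pi0, "pi0")
  structure(
    list(time = as.numeric(time), pi = as.numeric(pi),
         pi0 = as.numeric(pi0), meta = as.list(meta)),
    class = "kinetics_trace"
  )
}

#' @export
print.kinetics_trace <- function(x, ...) {
  cat(sprintf(
    "Kinetics trace: %d samples, t = [%g, %g] s, pi0 = %.3f mN/m, pi_max = %.3f mN/m\n",
    length(x$time), min(x$time), max(x$time), x$pi0, max(x$pi)))
  invisible(x)
}

#' Normalize a relaxation transient
#'
#' Expresses the relaxation in the dimensionless coordinates
#' \eqn{(\pi_t - \pi_0)/(\pi_{max} - \pi_0)} versus time, where
#' \eqn{\pi_{max}} is the maximum (starting) pressure of the transient. The
#' normalized series equals 1 at the sample where the pressure peaks and
#' tends toward \eqn{\Delta\pi_{EQ}/(\pi_{max} - \pi_0)} at long times.
#'
#' The result is invariant to adding a constant jointly to `pi` and `pi0`,
#' and to rescaling `pi - pi0` by any positive factor.
#'
#' @param x A [relaxation_transient()].
#' @return A data frame with columns `time` (s) and `value` (dimensionless).
#' @examples
#' tr <- relaxation_transient(0:50, 20 + 10 * exp(-(0:50) / 10), 0.05, pi0 = 20)
#' head(normalize_relaxation(tr))
#' @export
normalize_relaxation <- function(x) {
  stopifnot(inherits(x, "relaxation_transient"))
  pmax_ <- max(x$pi)
  if (pmax_ <= x$pi0)
    stop_filmrheo("degenerate step: max(pi) equals pi0, nothing to normalize",
                  "filmrheo_degenerate_step_error")
  data.frame(time = x$time, value = (x$pi - x$pi0) / (pmax_ - x$pi0))
}
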