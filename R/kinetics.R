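#' Penetration-kinetics features of a post-injection trace
#'
#' Summarizes the surface-pressure response of a pre-formed film to a
#' surfactant injected beneath it: the maximum pressure rise
#' \eqn{\Delta\pi_{max} = \max\pi - \pi_0}, the time of that maximum
#' (`t_peak`), and the re-equilibration time `t_requil` - the first time at
#' or after the peak from which \eqn{|\pi - \pi_0| < tol} holds through the
#' end of the record ("sustained"). A trace that never returns to within
#' `tol` of baseline (e.g. monotonically rising) has `t_requil = NA`;
#' a record with no samples after the peak yields `NA` with a warning.
#'
#' Only post-injection samples (`time >= 0`) enter the feature extraction;
#' pre-injection samples serve to estimate `pi0` (see [kinetics_trace()]).
#' `delta_pi_max` is invariant to adding a constant jointly to `pi` and
#' `pi0`.
#'
#' @param x A [kinetics_trace()].
#' @param tol Re-equilibration tolerance in mN/m (default 0.5).
#' @return An object of class `kinetics_features`: list with
#'   `delta_pi_max` (mN/m), `t_peak` (s), `t_requil` (s or `NA`), `tol`,
#'   `pi0`.
#' @examples
#' t <- 0:2000
#' k <- kinetics_trace(t, 18 + 15 * (1 - exp(-t / 20)) * exp(-t / 300), pi0 = 18)
#' penetration_features(k)
#' @export
penetration_features <- function(x, tol = 0.5) {
  stopifnot(inherits(x, "kinetics_trace"))
  assert_scalar(tol, "tol", lower = 0, open_lower = TRUE)
  post <- x$time >= 0
  if (!any(post)) stop_validation("trace has no post-injection (time >= 0) samples")
  t <- x$time[post]
  p <- x$pi[post]

  ipk <- which.max(p)
  delta_pi_max <- p[ipk] - x$pi0
  t_peak <- t[ipk]

  idx <- ipk:length(p)
  if (length(idx) < 2L && abs(p[ipk] - x$pi0) >= tol) {
    warning("no samples after the pressure peak: re-equilibration time unavailable")
    t_requil <- NA_real_
  } else {
    near <- abs(p[idx] - x$pi0) < tol
    sustained <- rev(cumprod(rev(near))) > 0
    t_requil <- if (any(sustained)) t[idx[which(sustained)[1L]]] else NA_real_
  }

  structure(list(delta_pi_max = delta_pi_max, t_peak = t_peak,
                 t_requil = t_requil, tol = tol, pi0 = x$pi0),
            class = "kinetics_features")
}

#' @export
print.kinetics_features <- function(x, ...) {
  cat(sprintf("Penetration kinetics: dpi_max = %.3f mN/m at t = %.1f s; re-equilibration %s (tol %.2g mN/m)\n",
              x$delta_pi_max, x$t_peak,
              if (is.na(x$t_requil)) "not reached" else sprintf("at t = %.1f s", x$t_requil),
              x$tol))
  invisible(x)
}
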