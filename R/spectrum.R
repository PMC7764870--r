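#' Viscoelastic spectrum container
#'
#' The frequency-domain twin of a relaxation transient: the real (storage,
#' elastic) and imaginary (loss, dissipative) parts of the complex
#' dilatational viscoelasticity modulus \eqn{E^*(\nu) = E_R(\nu) + i E_{IM}(\nu)}
#' on a frequency grid, together with the relative area strain used in the
#' normalization.
#'
#' @param freq Frequencies \eqn{\nu} in Hz, strictly increasing, positive.
#' @param e_real Storage modulus \eqn{E_R(\nu)} in mN/m.
#' @param e_imag Loss modulus \eqn{E_{IM}(\nu)} in mN/m.
#' @param strain Relative area step \eqn{\Delta A/A_0} used in the
#'   normalization.
#' @return An object of class `viscoelastic_spectrum`.
#' @seealso [compute_spectrum()], [analytic_spectrum()],
#'   [dilatational_viscosity()]
#' @export
viscoelastic_spectrum <- function(freq, e_real, e_imag, strain) {
  assert_numeric(freq, "freq")
  if (any(freq <= 0)) stop_validation("'freq' must be positive")
  assert_increasing(freq, "freq")
  assert_numeric(e_real, "e_real")
  assert_numeric(e_imag, "e_imag")
  if (length(e_real) != length(freq) || length(e_imag) != length(freq))
    stop_validation("'e_real' and 'e_imag' must match 'freq' in length")
  assert_scalar(strain, "strain", lower = 0, open_lower = TRUE)
  structure(list(freq = as.numeric(freq), e_real = as.numeric(e_real),
                 e_imag = as.numeric(e_imag), strain = as.numeric(strain)),
            class = "viscoelastic_spectrum")
}

#' @export
print.viscoelastic_spectrum <- function(x, ...) {
  cat(sprintf(
    "Viscoelastic spectrum: %d frequencies in [%.3g, %.3g] Hz (strain %.3f)\n  E_R in [%.4g, %.4g] mN/m, E_IM in [%.4g, %.4g] mN/m\n",
    length(x$freq), min(x$freq), max(x$freq), x$strain,
    min(x$e_real), max(x$e_real), min(x$e_imag), max(x$e_imag)))
  invisible(x)
}

#' @export
as.data.frame.viscoelastic_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$freq, e_real_mn_per_m = x$e_real,
             e_imag_mn_per_m = x$e_imag)
}

#' Default logarithmic frequency grid
#'
#' Log-spaced frequencies (default 60 points per decade) over the band in
#' which step stress-relaxation experiments resolve the modulus, clipped to
#' the band resolvable from a record of duration `duration` sampled at
#' interval `dt`: \eqn{[1/(10 T), 1/(4 \Delta t)]}. The upper clip sits at
#' half the Nyquist frequency because the piecewise-linear quadrature of
#' sampled transients attenuates the transform by more than a percent once
#' \eqn{\omega \Delta t} exceeds about \eqn{\pi/2}.
#'
#' @param duration Record duration in s (optional; clips the low end).
#' @param dt Sampling interval in s (optional; clips the high end).
#' @param fmin,fmax Requested band limits in Hz.
#' @param per_decade Grid points per decade.
#' @return Numeric vector of frequencies in Hz.
#' @export
frequency_grid <- function(duration = NULL, dt = NULL,
                           fmin = 1e-4, fmax = 1, per_decade = 60) {
  if (!is.null(duration)) fmin <- max(fmin, 1 / (10 * duration))
  if (!is.null(dt)) fmax <- min(fmax, 1 / (4 * dt))
  if (fmin >= fmax) stop_range("empty frequency band after clipping to the resolvable range")
  10^seq(log10(fmin), log10(fmax), by = 1 / per_decade)
}

#' Closed-form spectrum of a generalized Maxwell film
#'
#' The exact complex dilatational modulus of a film whose relaxation is a sum
#' of decaying exponentials plus a plateau. With \eqn{\omega = 2\pi\nu} and
#' strain \eqn{s = \Delta A/A_0}:
#' \deqn{E_R(\nu) = \left[\Delta\pi_{EQ} + \sum_i A_i \frac{\omega^2\tau_i^2}{1+\omega^2\tau_i^2}\right] / s,\qquad
#'       E_{IM}(\nu) = \left[\sum_i A_i \frac{\omega\tau_i}{1+\omega^2\tau_i^2}\right] / s.}
#' No numerical integration is involved; this is the oracle against which the
#' transform of sampled transients is validated.
#'
#' @param components Two-column matrix or data frame with columns
#'   `amplitude` (\eqn{A_i}, mN/m) and `tau` (\eqn{\tau_i}, s); may have zero
#'   rows.
#' @param plateau Plateau \eqn{\Delta\pi_{EQ}} in mN/m.
#' @param strain Relative area step \eqn{\Delta A/A_0}.
#' @param freqs Frequency grid in Hz.
#' @return A [viscoelastic_spectrum()].
#' @examples
#' sp <- analytic_spectrum(data.frame(amplitude = 10, tau = 100),
#'                         plateau = 0, strain = 0.05,
#'                         freqs = frequency_grid(fmin = 1e-4, fmax = 0.1))
#' # loss peak at nu = 1/(2*pi*tau), height (A/strain)/2
#' sp$freq[which.max(sp$e_imag)]
#' @export
analytic_spectrum <- function(components, plateau, strain, freqs) {
  comps <- normalize_components(components)
  assert_scalar(plateau, "plateau")
  assert_scalar(strain, "strain", lower = 0, open_lower = TRUE)
  assert_numeric(freqs, "freqs")
  om <- 2 * pi * freqs
  er <- rep(plateau, length(om))
  ei <- rep(0, length(om))
  for (k in seq_len(nrow(comps))) {
    wt <- om * comps$tau[k]
    er <- er + comps$amplitude[k] * wt^2 / (1 + wt^2)
    ei <- ei + comps$amplitude[k] * wt / (1 + wt^2)
  }
  viscoelastic_spectrum(freqs, er / strain, ei / strain, strain)
}

# Long-time plateau estimate from the record tail. "tailfit" (default)
# least-squares fits c + b exp(-t/tau) over the trailing window (tau profiled
# on a log grid, linear solve for c and b), which separates the plateau from a
# slow decaying component far better than a plain mean; "tailmean" is the mean
# of the last tail_frac of samples.
estimate_plateau <- function(t, dp, tail_frac = 0.1,
                             method = c("tailfit", "tailmean")) {
  method <- match.arg(method)
  n <- length(t)
  k <- max(2L, ceiling(tail_frac * n))
  if (method == "tailmean")
    return(mean(dp[(n - k + 1L):n]))
  kw <- max(8L, ceiling(min(3 * tail_frac, 0.5) * n))
  if (kw >= n) return(mean(dp[(n - k + 1L):n]))
  idx <- (n - kw + 1L):n
  tw <- t[idx] - t[idx[1]]
  yw <- dp[idx]
  span <- tw[length(tw)]
  if (span <= 0) return(mean(yw))
  taus <- exp(seq(log(span / 50), log(2 * span), length.out = 40L))
  best_c <- mean(yw); best_sse <- sum((yw - best_c)^2)
  for (tau in taus) {
    X <- cbind(1, exp(-tw / tau))
    fit <- stats::lm.fit(X, yw)
    if (anyNA(fit$coefficients)) next
    sse <- sum(fit$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best_c <- fit$coefficients[1]
    }
  }
  unname(best_c)
}

# coerce components input to a validated data.frame(amplitude, tau)
normalize_components <- function(components) {
  if (is.null(components) || (is.data.frame(components) && nrow(components) == 0L) ||
      (is.matrix(components) && nrow(components) == 0L) ||
      (!is.data.frame(components) && !is.matrix(components) && length(components) == 0L))
    return(data.frame(amplitude = numeric(0), tau = numeric(0)))
  comps <- as.data.frame(components)
  if (!all(c("amplitude", "tau") %in% names(comps))) {
    if (ncol(comps) == 2L) names(comps) <- c("amplitude", "tau")
    else stop_validation("'components' needs columns 'amplitude' and 'tau'")
  }
  assert_numeric(comps$amplitude, "amplitude")
  assert_numeric(comps$tau, "tau")
  if (any(comps$tau <= 0)) stop_validation("relaxation times 'tau' must be positive")
  comps[, c("amplitude", "tau")]
}

#' Complex dilatational modulus from a relaxation transient
#'
#' Transforms a sampled stress-relaxation transient \eqn{\Delta\pi(t) =
#' \pi(t) - \pi_0} into the complex dilatational viscoelasticity modulus via
#' the one-sided Fourier transform
#' \deqn{E^*(\nu) = \left[\Delta\pi_{EQ} + i\,2\pi\nu \int_0^\infty
#'   (\Delta\pi(t) - \Delta\pi_{EQ})\, e^{-i 2\pi\nu t}\, dt\right]
#'   \Big/ (\Delta A/A_0).}
#' The long-time plateau \eqn{\Delta\pi_{EQ}} is estimated from the record
#' tail - by default an exponential-plus-constant least-squares fit over the
#' trailing window, which separates the plateau from a slow decaying
#' component; `plateau_method = "tailmean"` uses the plain mean of the last
#' `tail_frac` of samples instead. The plateau is transformed analytically
#' (the one-sided integral of a constant does not converge numerically);
#' only the decaying remainder is integrated, by piecewise-linear quadrature
#' that is exact for the linear interpolant of the samples and therefore
#' robust to irregular sampling. In the zero-frequency limit \eqn{E_R \to
#' \Delta\pi_{EQ}/(\Delta A/A_0)}, the equilibrium elasticity.
#'
#' For noisy records intended for Cole-Cole peak counting, `denoise =
#' "spline"` first smooths the transient with a cross-validated smoothing
#' spline fitted in log-time (exponential decays vary on a log-time scale, so
#' the spline tracks fast early decay while averaging heavily over the slow
#' tail); the raw samples are never altered for fitting purposes.
#'
#' @param x A [relaxation_transient()].
#' @param freqs Frequency grid in Hz; defaults to [frequency_grid()] clipped
#'   to the resolvable band \eqn{[1/(10 T), 1/(2\Delta t)]}. Requested
#'   frequencies outside that band are an error.
#' @param tail_frac Trailing fraction of samples anchoring the plateau
#'   estimate (default 0.1; the tail-fit window spans three times this, at
#'   most half the record).
#' @param denoise `"none"` (default) or `"spline"`.
#' @param plateau_method `"tailfit"` (default) or `"tailmean"`.
#' @return A [viscoelastic_spectrum()] with attribute `plateau_est`, the
#'   estimated \eqn{\Delta\pi_{EQ}} in mN/m.
#' @examples
#' tr <- gen_relaxation(components = data.frame(amplitude = 10, tau = 100),
#'                      plateau = 0, noise_sd = 0, dt = 1, duration = 1000)
#' sp <- compute_spectrum(tr)
#' @export
compute_spectrum <- function(x, freqs = NULL, tail_frac = 0.1,
                             denoise = c("none", "spline"),
                             plateau_method = c("tailfit", "tailmean")) {
  stopifnot(inherits(x, "relaxation_transient"))
  denoise <- match.arg(denoise)
  plateau_method <- match.arg(plateau_method)
  assert_scalar(tail_frac, "tail_frac", lower = 0, upper = 1,
                open_lower = TRUE, open_upper = TRUE)
  t <- x$time - x$time[1]
  dp <- x$pi - x$pi0
  n <- length(t)
  dur <- t[n]
  dt <- stats::median(diff(t))
  if (is.null(freqs)) {
    # span the record's full resolvable band
    freqs <- frequency_grid(fmin = 1 / (10 * dur), fmax = 1, dt = dt)
  } else {
    assert_numeric(freqs, "freqs")
    if (any(freqs < 1 / (10 * dur) * (1 - 1e-9)) || any(freqs > 1 / (2 * dt) * (1 + 1e-9)))
      stop_range(sprintf(
        "requested frequencies outside the resolvable band [%.3g, %.3g] Hz",
        1 / (10 * dur), 1 / (2 * dt)))
  }

  if (denoise == "spline") {
    lx <- log10(t + dt)  # offset keeps t = 0 finite; decades of log-time
    fit <- stats::smooth.spline(lx, dp)
    dp <- stats::predict(fit, lx)$y
  }

  dpeq <- estimate_plateau(t, dp, tail_frac = tail_frac, method = plateau_method)
  g <- dp - dpeq

  om <- 2 * pi * freqs
  t1 <- t[-n]; t2 <- t[-1]
  g1 <- g[-n]; g2 <- g[-1]
  slope <- (g2 - g1) / (t2 - t1)
  E <- vapply(om, function(w) {
    e1 <- exp(-1i * w * t1); e2 <- exp(-1i * w * t2)
    # exact integral of the linear interpolant on each interval
    seg <- (g1 * e1 - g2 * e2) / (1i * w) + slope * (e1 - e2) / (1i * w)^2
    (dpeq + 1i * w * sum(seg)) / x$strain
  }, complex(1))

  out <- viscoelastic_spectrum(freqs, Re(E), Im(E), x$strain)
  attr(out, "plateau_est") <- dpeq
  out
}

#' Dilatational viscosity from the loss modulus
#'
#' Recovers \eqn{\eta_d(\nu) = E_{IM}(\nu) / (2\pi\nu)} in mN s/m.
#'
#' @param spec A [viscoelastic_spectrum()].
#' @return Numeric vector of dilatational viscosities, one per frequency.
#' @export
dilatational_viscosity <- function(spec) {
  stopifnot(inherits(spec, "viscoelastic_spectrum"))
  spec$e_imag / (2 * pi * spec$freq)
}

#' Cole-Cole curve and relaxation-process count
#'
#' Orders the spectrum as a curve of \eqn{(E_R, E_{IM})} points and counts
#' the peaks of the loss modulus: each peak marks one relaxation process
#' contributing to the transient, and the count sets the number of
#' exponential terms used by [fit_relaxation()] in automatic mode. Peaks are
#' detected on \eqn{E_{IM}} as a function of \eqn{\log\nu} (equivalent
#' ordering to the \eqn{E_{IM}}-vs-\eqn{E_R} plot when \eqn{E_R} is
#' monotone), keeping maxima whose topographic prominence exceeds
#' `prominence` times the maximum loss modulus; ties break toward lower
#' frequency.
#'
#' @param spec A [viscoelastic_spectrum()] with at least 5 points.
#' @param prominence Minimum peak prominence as a fraction of
#'   \eqn{\max E_{IM}} (default 0.05).
#' @return An object of class `cole_cole` with elements `curve` (data frame
#'   `freq`, `e_real`, `e_imag`, ordered by frequency), `peaks` (data frame
#'   `freq`, `e_real`, `e_imag`, ordered by frequency) and `count`.
#' @examples
#' sp <- analytic_spectrum(data.frame(amplitude = c(5, 5), tau = c(10, 1000)),
#'                         plateau = 2, strain = 0.05,
#'                         freqs = frequency_grid(fmin = 1e-5, fmax = 1))
#' cole_cole(sp)$count
#' @export
cole_cole <- function(spec, prominence = 0.05) {
  stopifnot(inherits(spec, "viscoelastic_spectrum"))
  if (length(spec$freq) < 5L)
    stop_filmrheo("spectrum has fewer than 5 points: insufficient resolution for peak counting",
                  "filmrheo_resolution_error")
  assert_scalar(prominence, "prominence", lower = 0)
  mx <- max(spec$e_imag)
  # a loss modulus that is zero to numerical precision carries no process
  floor_ <- max(1e-9 * max(abs(spec$e_real)), .Machine$double.eps)
  pk <- if (mx > floor_) find_peaks(spec$e_imag, min_prominence = prominence * mx)
        else list(index = integer(0))
  idx <- sort(pk$index)
  structure(list(
    curve = data.frame(freq = spec$freq, e_real = spec$e_real,
                       e_imag = spec$e_imag),
    peaks = data.frame(freq = spec$freq[idx], e_real = spec$e_real[idx],
                       e_imag = spec$e_imag[idx]),
    count = length(idx)), class = "cole_cole")
}

#' @export
print.cole_cole <- function(x, ...) {
  cat(sprintf("Cole-Cole analysis: %d relaxation process(es)\n", x$count))
  if (x$count > 0) {
    cat("  peaks:\n")
    print(x$peaks, row.names = FALSE)
  }
  invisible(x)
}

#' Classify a film as predominantly elastic or viscous
#'
#' A film is predominantly elastic where the storage modulus exceeds the
#' loss modulus (\eqn{E_R > E_{IM}}) and predominantly viscous where the
#' reverse holds. The classification is made over a frequency band: if
#' \eqn{E_R > E_{IM}} on more than `frac` of the band's grid points the film
#' is `"predominantly_elastic"`, if \eqn{E_R < E_{IM}} on more than `frac`
#' it is `"predominantly_viscous"`, otherwise `"mixed"`.
#'
#' @param spec A [viscoelastic_spectrum()].
#' @param band Frequency interval (length-2, Hz) within the spectrum range.
#' @param frac Dominance fraction threshold (default 0.9).
#' @return A list with `class` (character), `fraction_elastic` (fraction of
#'   band grid points with \eqn{E_R > E_{IM}}) and `band`.
#' @export
classify_film <- function(spec, band = c(1e-4, 1e-3), frac = 0.9) {
  stopifnot(inherits(spec, "viscoelastic_spectrum"))
  assert_numeric(band, "band")
  if (length(band) != 2L || band[1] >= band[2])
    stop_range("'band' must be an increasing frequency interval")
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(sel))
    stop_range("empty band: no spectrum frequencies fall inside 'band'")
  fe <- mean(spec$e_real[sel] > spec$e_imag[sel])
  fv <- mean(spec$e_real[sel] < spec$e_imag[sel])
  cls <- if (fe > frac) "predominantly_elastic"
         else if (fv > frac) "predominantly_viscous"
         else "mixed"
  list(class = cls, fraction_elastic = fe, band = band)
}

#' Plot a viscoelastic spectrum or Cole-Cole curve
#'
#' @param x A `viscoelastic_spectrum`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.viscoelastic_spectrum <- function(x, ...) {
  graphics::plot(x$freq, x$e_real, log = "x", type = "l",
                 xlab = "frequency [Hz]", ylab = "modulus [mN/m]", ...)
  graphics::lines(x$freq, x$e_imag, lty = 2)
  graphics::legend("topleft", legend = c("E_R", "E_IM"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' @rdname plot.viscoelastic_spectrum
#' @export
plot.cole_cole <- function(x, ...) {
  graphics::plot(x$curve$e_real, x$curve$e_imag, type = "l",
                 xlab = "E_R [mN/m]", ylab = "E_IM [mN/m]", ...)
  if (x$count > 0)
    graphics::points(x$peaks$e_real, x$peaks$e_imag, pch = 19)
  invisible(x)
}
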