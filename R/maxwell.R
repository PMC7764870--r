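# Generalized-Maxwell fitting of stress-relaxation transients.
#
# The relaxation model is a sum of decaying exponentials plus a plateau,
#   dpi(t) = sum_i A_i exp(-t / tau_i) + dpi_EQ,
# each exponential corresponding to a Maxwell spring-and-dashpot element
# (E_i = A_i / strain, eta_i = tau_i E_i, so tau_i = eta_i / E_i) and the
# plateau to an equilibrium spring E_eq = dpi_EQ / strain. Sum-of-exponential
# least squares is notoriously ill-conditioned, so fitting works in log(tau),
# seeds amplitudes with a non-negative linear solve at fixed tau, and retries
# from deterministically jittered starts on failure.

eval_maxwell <- function(amplitude, tau, plateau, times) {
  out <- rep(plateau, length(times))
  for (k in seq_along(amplitude))
    out <- out + amplitude[k] * exp(-times / tau[k])
  out
}

#' Number of relaxation processes in a transient
#'
#' Automatic model-order selection: the number of exponential terms used to
#' fit a transient equals the number of peaks in its Cole-Cole plot. For
#' noisy records the raw transform amplifies measurement noise
#' proportionally to frequency, which would litter the loss modulus with
#' spurious maxima. The transient is therefore denoised before transforming
#' with a smoothing spline fitted in log-time (exponential decays vary on
#' the log-time scale, so the spline tracks the fast early decay while
#' averaging heavily over the slow tail) whose effective degrees of freedom
#' are capped at `df_cap`: a sum of a few exponentials plus a plateau has
#' only a handful of inflections in log-time, so the cap suppresses sample
#' noise without biasing any resolvable model order. As a safeguard for
#' very noisy records, the counting band is additionally truncated where
#' the residual noise propagated onto \eqn{E_{IM}} (white noise of
#' standard deviation \eqn{\sigma}, estimated from second differences of
#' the samples and attenuated by the spline's averaging factor
#' \eqn{\sqrt{df/n}}, maps to a loss-modulus standard deviation of about
#' \eqn{2\pi\nu\,\sigma\sqrt{df/n}\sqrt{\Delta t\,T/2}/s}) exceeds
#' `noise_cap` times the maximum loss modulus.
#'
#' @param x A [relaxation_transient()].
#' @param prominence Peak-prominence threshold forwarded to [cole_cole()].
#' @param noise_cap Band-truncation level as a fraction of
#'   \eqn{\max E_{IM}} (default 0.25).
#' @param df_cap Upper bound on the denoising spline's degrees of freedom.
#' @param tail_frac Plateau-estimation tail fraction, see
#'   [compute_spectrum()].
#' @return An object of class `cole_cole` (see [cole_cole()]); its `count`
#'   element is the selected model order.
#' @export
relaxation_order <- function(x, prominence = 0.05, noise_cap = 0.25,
                             df_cap = 20, tail_frac = 0.1) {
  stopifnot(inherits(x, "relaxation_transient"))
  t <- x$time - x$time[1]
  dp <- x$pi - x$pi0
  n <- length(t)
  dt <- stats::median(diff(t))
  dur <- t[n]

  lx <- log10(t + dt)
  fit <- stats::smooth.spline(lx, dp)
  if (fit$df > df_cap) fit <- stats::smooth.spline(lx, dp, df = df_cap)
  smoothed <- relaxation_transient(t, x$pi0 + stats::predict(fit, lx)$y,
                                   x$strain, pi0 = x$pi0)
  spec <- compute_spectrum(smoothed, tail_frac = tail_frac)

  sigma <- if (n >= 4L) stats::sd(diff(dp, differences = 2)) / sqrt(6) else 0
  sigma <- sigma * sqrt(fit$df / n)     # spline noise attenuation
  noise_sd <- 2 * pi * spec$freq * sigma * sqrt(dt * dur / 2) / x$strain
  keep <- noise_sd < noise_cap * max(spec$e_imag, 0)
  if (sum(keep) >= 5L && !all(keep))
    spec <- viscoelastic_spectrum(spec$freq[keep], spec$e_real[keep],
                                  spec$e_imag[keep], spec$strain)
  cole_cole(spec, prominence = prominence)
}

#' Fit the multi-exponential-plus-plateau relaxation model
#'
#' Least-squares fit of \eqn{\Delta\pi(t) = \sum_i A_i e^{-t/\tau_i} +
#' \Delta\pi_{EQ}} to a relaxation transient. With `n = "auto"` the number
#' of exponential terms equals the number of Cole-Cole peaks
#' ([relaxation_order()]). Relaxation times are initialized log-spaced
#' across the record duration, amplitudes by a non-negative linear solve at
#' fixed \eqn{\tau}, and the joint refinement uses Levenberg-Marquardt in
#' \eqn{(A_i, \log\tau_i, \Delta\pi_{EQ})} with the default constraints
#' \eqn{A_i \ge 0} (compression steps relax downward), free plateau, and
#' \eqn{\tau_i \in [\Delta t, 10 T]}. On failure the fit restarts from
#' deterministically jittered initial times (default 5 restarts).
#'
#' @param x A [relaxation_transient()].
#' @param n Number of exponential terms (integer >= 0) or `"auto"`.
#' @param nonneg Constrain amplitudes to be non-negative (default TRUE).
#' @param restarts Maximum jittered restarts after a failed attempt.
#' @param tail_frac Tail fraction for the plateau seed and, in auto mode,
#'   the order selection.
#' @param prominence Peak prominence for auto order selection.
#' @return An object of class `maxwell_fit`: components ordered by ascending
#'   \eqn{\tau} (columns `amplitude`, `tau`, `se_amplitude`, `se_tau`, `e`,
#'   `eta`), `plateau`, `se_plateau`, `e_eq`, `strain`, `rms` (residual
#'   root-mean-square, mN/m), `n_components`, `converged`, and `resolvable`
#'   (FALSE, with a warning, when neighbouring fitted times are closer than
#'   a factor 3). Equal-\eqn{\tau} components are merged by amplitude
#'   summation.
#' @examples
#' tr <- gen_relaxation(components = data.frame(amplitude = 10, tau = 100),
#'                      plateau = 2, noise_sd = 0, dt = 1, duration = 1000)
#' fit_relaxation(tr, n = 1)
#' @export
fit_relaxation <- function(x, n = "auto", nonneg = TRUE, restarts = 5,
                           tail_frac = 0.1, prominence = 0.05) {
  stopifnot(inherits(x, "relaxation_transient"))
  t <- x$time - x$time[1]
  dp <- x$pi - x$pi0
  nobs <- length(t)
  dt <- stats::median(diff(t))
  dur <- t[nobs]

  order_mode <- "fixed"
  if (identical(n, "auto")) {
    n <- relaxation_order(x, prominence = prominence, tail_frac = tail_frac)$count
    order_mode <- "auto"
  }
  n <- as.integer(n)
  if (n < 0L) stop_validation("'n' must be >= 0 or \"auto\"")

  settings <- list(n = n, order_mode = order_mode, nonneg = nonneg,
                   restarts = restarts, tail_frac = tail_frac)

  if (n == 0L) {
    plateau <- mean(dp)
    rms <- sqrt(mean((dp - plateau)^2))
    return(new_maxwell_fit(
      amplitude = numeric(0), tau = numeric(0),
      se_amplitude = numeric(0), se_tau = numeric(0),
      plateau = plateau, se_plateau = stats::sd(dp) / sqrt(nobs),
      strain = x$strain, rms = rms, converged = TRUE, resolvable = TRUE,
      settings = settings))
  }

  k <- max(2L, ceiling(tail_frac * nobs))
  plateau0 <- mean(dp[(nobs - k + 1L):nobs])
  ltau_lo <- log(dt)
  ltau_hi <- log(10 * dur)
  # initial taus: interior points of a log-spaced division of the record
  ltau0 <- seq(log(max(dt, dur * 1e-3)), log(dur), length.out = n + 2L)[2:(n + 1L)]
  # deterministic jitter schedule (decades of log-tau), fixed across runs
  jitter <- with_seed(20201214, matrix(stats::rnorm(restarts * n, 0, 0.6),
                                       nrow = restarts))

  residual_fun <- function(par) {
    a <- par[seq_len(n)]
    tau <- exp(par[n + seq_len(n)])
    pl <- par[2L * n + 1L]
    dp - eval_maxwell(a, tau, pl, t)
  }

  attempt <- function(ltau_init) {
    X <- exp(-outer(t, 1 / exp(ltau_init)))
    a0 <- tryCatch(pracma::lsqnonneg(X, dp - plateau0)$x,
                   error = function(e) rep(max(dp[1] - plateau0, 1e-3) / n, n))
    if (!nonneg) a0 <- as.vector(qr.solve(X, dp - plateau0))
    par0 <- c(a0, ltau_init, plateau0)
    lower <- c(if (nonneg) rep(0, n) else rep(-Inf, n), rep(ltau_lo, n), -Inf)
    upper <- c(rep(Inf, n), rep(ltau_hi, n), Inf)
    tryCatch(
      minpack.lm::nls.lm(par = par0, fn = residual_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }

  best <- NULL
  for (r in 0:restarts) {
    init <- if (r == 0L) ltau0 else pmin(pmax(ltau0 + jitter[r, ], ltau_lo), ltau_hi)
    fit <- attempt(init)
    ok <- !is.null(fit) && fit$info %in% 1:4
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
    if (ok && r == 0L) break          # first start converged: accept
    if (ok && !is.null(best) && best$info %in% 1:4) break
  }
  if (is.null(best) || !(best$info %in% 1:4))
    stop_filmrheo(
      sprintf("relaxation fit did not converge after %d restart(s)", restarts),
      "filmrheo_fit_error", best_attempt = best)

  par <- best$par
  a <- par[seq_len(n)]
  tau <- exp(par[n + seq_len(n)])
  plateau <- par[2L * n + 1L]

  # parameter uncertainty from the fit covariance (delta method for tau)
  p <- length(par)
  sigma2 <- best$deviance / max(nobs - p, 1L)
  se <- tryCatch(sqrt(diag(solve(best$hessian)) * sigma2),
                 error = function(e) rep(NA_real_, p))
  se_a <- se[seq_len(n)]
  se_tau <- tau * se[n + seq_len(n)]
  se_plateau <- se[2L * n + 1L]

  # ascending tau; merge (near-)equal relaxation times by amplitude summation
  o <- order(tau)
  a <- a[o]; tau <- tau[o]; se_a <- se_a[o]; se_tau <- se_tau[o]
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    if (keep[i] && tau[i + 1L] / tau[i] < 1 + 1e-6) {
      a[i + 1L] <- a[i + 1L] + a[i]
      keep[i] <- FALSE
    }
  }
  a <- a[keep]; tau <- tau[keep]; se_a <- se_a[keep]; se_tau <- se_tau[keep]

  resolvable <- length(tau) < 2L || all(tau[-1] / tau[-length(tau)] >= 3)
  if (!resolvable)
    warning("fitted relaxation times are closer than a factor 3: model order may exceed what the data resolve")

  rms <- sqrt(best$deviance / nobs)
  new_maxwell_fit(amplitude = a, tau = tau, se_amplitude = se_a,
                  se_tau = se_tau, plateau = plateau, se_plateau = se_plateau,
                  strain = x$strain, rms = rms, converged = TRUE,
                  resolvable = resolvable, settings = settings)
}

new_maxwell_fit <- function(amplitude, tau, se_amplitude, se_tau, plateau,
                            se_plateau, strain, rms, converged, resolvable,
                            settings) {
  comp <- data.frame(amplitude = amplitude, tau = tau,
                     se_amplitude = se_amplitude, se_tau = se_tau,
                     e = amplitude / strain, eta = tau * amplitude / strain)
  structure(list(components = comp, plateau = plateau,
                 se_plateau = se_plateau, strain = strain,
                 e_eq = plateau / strain, rms = rms,
                 n_components = nrow(comp), converged = converged,
                 resolvable = resolvable, settings = settings),
            class = "maxwell_fit")
}

#' @export
print.maxwell_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Generalized Maxwell fit: %d element(s) + equilibrium spring\n",
              x$n_components))
  if (x$n_components > 0) {
    df <- x$components
    df$e <- signif(df$e, digits); df$eta <- signif(df$eta, digits)
    print(signif(df, digits), row.names = FALSE)
  }
  cat(sprintf("  plateau dpi_EQ = %.4g mN/m, E_eq = %.4g mN/m, residual RMS = %.3g mN/m\n",
              x$plateau, x$e_eq, x$rms))
  if (!x$resolvable) cat("  note: neighbouring relaxation times closer than 3x\n")
  invisible(x)
}

#' Evaluate a fitted relaxation model
#'
#' Forward evaluation of \eqn{\Delta\pi(t) = \sum_i A_i e^{-t/\tau_i} +
#' \Delta\pi_{EQ}}: \eqn{\Delta\pi(0) = \sum_i A_i + \Delta\pi_{EQ}} and
#' \eqn{\Delta\pi(\infty) \to \Delta\pi_{EQ}}.
#'
#' @param fit A [fit_relaxation()] result.
#' @param times Evaluation times in s, finite and non-negative.
#' @return Numeric vector of \eqn{\Delta\pi(t)} in mN/m.
#' @export
predict_relaxation <- function(fit, times) {
  stopifnot(inherits(fit, "maxwell_fit"))
  assert_numeric(times, "times")
  if (any(times < 0)) stop_validation("'times' must be non-negative")
  eval_maxwell(fit$components$amplitude, fit$components$tau, fit$plateau, times)
}

#' Maxwell spring-and-dashpot elements of a fit
#'
#' Maps a fitted relaxation model onto generalized-Maxwell elements: each
#' exponential term yields a spring-dashpot element with elasticity
#' \eqn{E_i = A_i / (\Delta A/A_0)} (mN/m) and dilatational viscosity
#' \eqn{\eta_i = \tau_i E_i} (mN s/m), so \eqn{\tau_i = \eta_i / E_i}
#' identically; the plateau yields the equilibrium spring \eqn{E_{eq} =
#' \Delta\pi_{EQ} / (\Delta A/A_0)}.
#'
#' @param fit A [fit_relaxation()] result.
#' @return A list with `elements` (data frame `e`, `eta`, `tau`, ascending
#'   \eqn{\tau}) and `e_eq`.
#' @export
maxwell_elements <- function(fit) {
  stopifnot(inherits(fit, "maxwell_fit"))
  if (!is.numeric(fit$strain) || fit$strain <= 0)
    stop_validation("fit carries a non-positive strain")
  list(elements = data.frame(e = fit$components$e, eta = fit$components$eta,
                             tau = fit$components$tau),
       e_eq = fit$e_eq)
}
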