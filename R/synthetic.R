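# Seeded synthetic-data generators.
#
# Every generator attaches its true parameters as attribute "truth"
# (retrievable with synthetic_truth(), written as a JSON sidecar by
# write_timeseries()); recovery tests read truth only from there. Noise is
# iid Gaussian on the surface pressure; real trough traces show only minimal,
# uncharacterized noise, and no autocorrelation model is claimed. Defaults
# emulate measurements on meibomian-type films: a two-process relaxation
# (well-separated times) with an equilibrium plateau, a 5% area step,
# baselines of 18-19 mN/m, a ~15 mN/m penetration rise peaking inside 100 s
# with re-equilibration around 1000 s, and ten-cycle isotherm recordings that
# become stationary after the first few cycles.

#' Ground truth of a synthetic record
#'
#' @param x A record produced by one of the generators.
#' @return The list of true generator parameters, or `NULL` for measured
#'   data.
#' @export
synthetic_truth <- function(x) attr(x, "truth")

#' Generate a stress-relaxation transient
#'
#' Simulates the post-step surface pressure
#' \eqn{\pi(t) = \pi_0 + \sum_i A_i e^{-t/\tau_i} + \Delta\pi_{EQ} +
#' \varepsilon(t)}, with iid Gaussian noise \eqn{\varepsilon}. The default
#' parameters emulate a meibomian-type film: two relaxation processes with
#' a 30-fold separation of time scales, a plateau, a 5% area step and an
#' 18-20 mN/m baseline.
#'
#' @param components Data frame or matrix with columns `amplitude` (mN/m)
#'   and `tau` (s).
#' @param plateau Plateau \eqn{\Delta\pi_{EQ}} in mN/m.
#' @param strain Relative area step in (0, 0.2]; protocol default 0.05.
#' @param pi0 Pre-step baseline in mN/m.
#' @param noise_sd Gaussian noise standard deviation in mN/m.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#'   The global RNG state is left untouched.
#' @param dt,duration Sampling interval and record duration in s.
#' @param meta Metadata labels passed through to the record.
#' @return A [relaxation_transient()] carrying a `truth` attribute.
#' @examples
#' tr <- gen_relaxation(seed = 1)
#' synthetic_truth(tr)$components
#' @export
gen_relaxation <- function(components = data.frame(amplitude = c(5, 5),
                                                   tau = c(10, 300)),
                           plateau = 2, strain = 0.05, pi0 = 19,
                           noise_sd = 0, seed = NULL,
                           dt = 1, duration = 3000, meta = list()) {
  comps <- normalize_components(components)
  assert_scalar(plateau, "plateau")
  assert_scalar(noise_sd, "noise_sd", lower = 0)
  assert_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  assert_scalar(duration, "duration", lower = dt)
  t <- seq(0, duration, by = dt)
  dp <- eval_maxwell(comps$amplitude, comps$tau, plateau, t)
  eps <- if (noise_sd > 0) with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
         else numeric(length(t))
  out <- relaxation_transient(time = t, pi = pi0 + dp + eps,
                              strain = strain, pi0 = pi0, meta = meta)
  attr(out, "truth") <- list(kind = "relaxation",
                             components = comps, plateau = plateau,
                             strain = strain, pi0 = pi0, noise_sd = noise_sd,
                             seed = seed, dt = dt, duration = duration)
  out
}

#' Generate a reference/test pair of isotherm cycle recordings
#'
#' Builds two trough recordings with triangular area ramps: a reference
#' film and a test film whose isotherm is shifted toward higher pressures
#' by incorporation of subphase material. The base isotherm is a monotone
#' cubic through user waypoints (no physical equation of state is
#' claimed). The incorporation shift may vanish at a squeeze-out pressure:
#' the test isotherm follows \eqn{\pi_{test} = \min(\pi_{ref} + s_0,\,
#' \max(\pi_{ref},\, \pi_{so}))}, i.e. it runs `shift0` above the reference
#' at low pressure, plateaus at the squeeze-out pressure \eqn{\pi_{so}}
#' while the expelled material leaves the film, and rejoins the reference
#' on further compression - so the test branch never decreases under
#' compression. With `vanish_pressure = NULL` the shift is constant
#' (persistent incorporation). Expansion branches are offset downward by a
#' hysteresis
#' gap tapered to zero at the turning points so the loop closes; early
#' cycles carry a geometrically decaying pressure drift
#' (`drift0 * drift_factor^(cycle-1)`) emulating film consolidation before
#' the curves attain a stationary shape.
#'
#' @param waypoints Data frame with columns `area` (increasing) and `pi`
#'   (non-increasing in area) through which the base isotherm passes.
#' @param shift0 Incorporation shift at low pressure, mN/m.
#' @param vanish_pressure Squeeze-out pressure in mN/m, or `NULL` for a
#'   persistent shift.
#' @param hysteresis_gap Maximum compression-expansion gap in mN/m.
#' @param drift0 First-cycle pressure drift in mN/m.
#' @param drift_factor Per-cycle geometric decay factor of the drift in
#'   \[0, 1).
#' @param n_cycles Number of compression-expansion cycles.
#' @param noise_sd Gaussian noise sd on pressure, mN/m.
#' @param seed Integer seed (global RNG state untouched).
#' @param n_per_branch Samples per branch.
#' @param area_unit Area unit tag.
#' @return A list with elements `ref` and `test`, both
#'   [trough_recording()]s carrying `truth` attributes.
#' @examples
#' pair <- gen_isotherm_pair(vanish_pressure = 23, seed = 7)
#' length(split_cycles(pair$test))
#' @export
gen_isotherm_pair <- function(waypoints = data.frame(
                                area = c(40, 60, 80, 100, 120, 135),
                                pi = c(30, 21, 14, 8.5, 4.5, 3)),
                              shift0 = 8, vanish_pressure = NULL,
                              hysteresis_gap = 1,
                              drift0 = 4, drift_factor = 0.5,
                              n_cycles = 10, noise_sd = 0, seed = NULL,
                              n_per_branch = 200, area_unit = "cm^2") {
  wp <- as.data.frame(waypoints)
  if (!all(c("area", "pi") %in% names(wp)))
    stop_validation("'waypoints' needs columns 'area' and 'pi'")
  if (any(diff(wp$area) <= 0) || any(diff(wp$pi) > 0))
    stop_validation("'waypoints' must have increasing area and non-increasing pi")
  if (n_cycles < 1L) stop_validation("'n_cycles' must be >= 1")
  assert_scalar(noise_sd, "noise_sd", lower = 0)
  assert_scalar(drift_factor, "drift_factor", lower = 0, upper = 1, open_upper = TRUE)

  base <- stats::splinefun(wp$area, wp$pi, method = "hyman")
  a_dn <- seq(max(wp$area), min(wp$area), length.out = n_per_branch)
  a_up <- rev(a_dn)[-1]
  # assemble n_cycles triangular ramps: down, up, down, up, ...
  area <- a_dn
  for (k in seq_len(n_cycles - 1L)) area <- c(area, a_up, a_dn[-1])
  area <- c(area, a_up)
  n <- length(area)
  time <- seq_len(n) - 1

  # branch membership and within-branch position u in [0, 1]
  per <- 2L * (n_per_branch - 1L)
  pos <- (seq_len(n) - 1L) %% per
  on_comp <- pos < (n_per_branch - 1L) | seq_len(n) == n
  u_comp <- pos / (n_per_branch - 1L)
  u_exp <- (pos - (n_per_branch - 1L)) / (n_per_branch - 1L)
  u <- ifelse(on_comp, u_comp, u_exp)
  cyc <- pmin((seq_len(n) - 1L) %/% per + 1L, n_cycles)

  p_ref <- base(area)
  gap <- hysteresis_gap * 4 * u * (1 - u)     # tapered: loop closes
  p_ref[!on_comp] <- p_ref[!on_comp] - gap[!on_comp]
  p_ref <- p_ref + drift0 * drift_factor^(cyc - 1L)

  p_test <- if (is.null(vanish_pressure)) p_ref + shift0
            else pmin(p_ref + shift0, pmax(p_ref, vanish_pressure))

  eps <- if (noise_sd > 0) with_seed(seed, stats::rnorm(2L * n, 0, noise_sd))
         else numeric(2L * n)
  truth_common <- list(waypoints = wp, shift0 = shift0,
                       vanish_pressure = vanish_pressure,
                       hysteresis_gap = hysteresis_gap, drift0 = drift0,
                       drift_factor = drift_factor, n_cycles = n_cycles,
                       noise_sd = noise_sd, seed = seed,
                       n_per_branch = n_per_branch)
  ref <- trough_recording(time, area, p_ref + eps[seq_len(n)],
                          area_unit = area_unit)
  test <- trough_recording(time, area, p_test + eps[n + seq_len(n)],
                           area_unit = area_unit)
  attr(ref, "truth") <- c(list(kind = "isotherm_ref"), truth_common)
  attr(test, "truth") <- c(list(kind = "isotherm_test"), truth_common)
  list(ref = ref, test = test)
}

#' Generate a penetration-kinetics trace
#'
#' Simulates the surface-pressure response to surfactant injection beneath
#' a pre-formed film: a fast rise followed by slow re-equilibration,
#' \eqn{\pi(t) = \pi_0 + a\,(1 - e^{-t/\tau_r})\, e^{-t/\tau_d} +
#' \varepsilon(t)}. The defaults emulate a strong interaction with a
#' meibomian-type film pre-equilibrated at 18 mN/m: a 15 mN/m observed
#' peak rise (the default amplitude of 19.3 mN/m is chosen so the
#' noiseless curve peaks at 15.0 mN/m) within the first 100 s, relaxing
#' back to baseline within roughly 1000 s.
#'
#' @param amplitude Rise amplitude \eqn{a > 0} in mN/m.
#' @param rise_tau,decay_tau Rise and decay time constants in s
#'   (`rise_tau < decay_tau`).
#' @param pi0 Pre-injection equilibration pressure in mN/m.
#' @param noise_sd Gaussian noise sd in mN/m.
#' @param seed Integer seed (global RNG state untouched).
#' @param dt,duration Sampling interval and record duration in s.
#' @return A [kinetics_trace()] carrying a `truth` attribute.
#' @examples
#' k <- gen_kinetics(seed = 3)
#' penetration_features(k)
#' @export
gen_kinetics <- function(amplitude = 19.3, rise_tau = 20, decay_tau = 300,
                         pi0 = 18, noise_sd = 0, seed = NULL,
                         dt = 1, duration = 2000) {
  assert_scalar(amplitude, "amplitude", lower = 0, open_lower = TRUE)
  assert_scalar(rise_tau, "rise_tau", lower = 0, open_lower = TRUE)
  assert_scalar(decay_tau, "decay_tau", lower = 0, open_lower = TRUE)
  if (rise_tau >= decay_tau)
    stop_validation("'rise_tau' must be smaller than 'decay_tau'")
  assert_scalar(noise_sd, "noise_sd", lower = 0)
  t <- seq(0, duration, by = dt)
  p <- pi0 + amplitude * (1 - exp(-t / rise_tau)) * exp(-t / decay_tau)
  eps <- if (noise_sd > 0) with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
         else numeric(length(t))
  out <- kinetics_trace(time = t, pi = p + eps, pi0 = pi0)
  attr(out, "truth") <- list(kind = "kinetics", amplitude = amplitude,
                             rise_tau = rise_tau, decay_tau = decay_tau,
                             pi0 = pi0, noise_sd = noise_sd, seed = seed,
                             dt = dt, duration = duration)
  out
}
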