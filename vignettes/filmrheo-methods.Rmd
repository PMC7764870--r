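---
title: "Methods: dilatational rheology and isotherm analytics in filmrheo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dilatational rheology and isotherm analytics in filmrheo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmrheo)
```

# Scope

filmrheo analyses three kinds of Langmuir-trough measurements on
interfacial films: stress–relaxation transients after a small rapid area
step, repeated compression–expansion π–A isotherm cycles, and
post-injection penetration-kinetics traces. This vignette documents the
underlying models, the numerical choices, the tunable parameters with
their defaults, what the synthetic-data generators do and do not emulate,
and the known limitations.

# Stress–relaxation rheology

## Model and assumptions

A film pre-compressed to a baseline pressure $\pi_0$ (18–20 mN/m is
typical for duplex lipid films) is subjected to an essentially
instantaneous relative area compression $s = \Delta A / A_0$, by protocol
$5 \pm 1\%$. Linear response is assumed: at these small strains the
relaxation of $\Delta\pi(t) = \pi(t) - \pi_0$ encodes the complex
dilatational viscoelasticity modulus via the one-sided Fourier transform

$$E^*(\nu) = \frac{\Delta\pi_{EQ} + i\,2\pi\nu \int_0^\infty
  \left(\Delta\pi(t) - \Delta\pi_{EQ}\right) e^{-i 2\pi\nu t}\,dt}{s},$$

with $\Delta\pi_{EQ}$ the long-time plateau. Because the transform of a
step strain is the constant $s$, the modulus is obtained by *dividing* the
transformed pressure response by $s$ — the only dimensionally consistent
normalization, giving $E$ in mN/m. The storage part $E_R$ is the film's
elasticity, the loss part $E_{IM} = 2\pi\nu\,\eta_d$ its dissipation.

A film whose relaxation is a finite sum of exponential processes plus a
plateau is exactly a generalized Maxwell solid: parallel spring–dashpot
elements $(E_i, \eta_i)$ with relaxation times $\tau_i = \eta_i / E_i$,
plus an equilibrium spring $E_{eq} = \Delta\pi_{EQ}/s$. Its spectrum is a
sum of Debye/Lorentzian terms, implemented in closed form by
`analytic_spectrum()`; each element contributes one peak of $E_{IM}$, of
height $E_i/2$ at $\nu_i = 1/(2\pi\tau_i)$. Counting Cole–Cole peaks
therefore counts relaxation processes, and that count fixes the number of
exponential terms fitted by `fit_relaxation()`.

## Numerical transform

`compute_spectrum()` evaluates the transform by quadrature that is exact
for the piecewise-linear interpolant of the samples, which makes it
robust to irregular sampling; no windowing or detrending is applied. Two
numerical issues are handled explicitly:

* **Plateau.** The one-sided integral of a constant does not converge
  numerically, so $\Delta\pi_{EQ}$ is estimated from the record tail,
  subtracted, and transformed analytically. The default estimator
  (`plateau_method = "tailfit"`) least-squares fits
  $c + b\,e^{-t/\tau}$ over the trailing window (three times `tail_frac`,
  at most half the record), profiling $\tau$ on a log grid and solving
  linearly for $c$ and $b$. A plain tail mean (`"tailmean"`, last 10% of
  samples) is biased upward by any slow component still decaying through
  the window, which in turn biases $E_R$ at the lowest resolvable
  frequencies; the exponential tail fit removes that bias while reducing
  exactly to the mean when the tail is flat.
* **Band limits.** A record of duration $T$ sampled at interval
  $\Delta t$ resolves frequencies in $[1/(10\,T),\ 1/(2\Delta t)]$;
  requests outside this band are errors. The *default* grid (60 points
  per decade) stops earlier, at $1/(4\Delta t)$, because the
  piecewise-linear quadrature attenuates the transform by more than 1%
  once $\omega \Delta t \gtrsim \pi/2$. Users may still request
  frequencies up to Nyquist explicitly.

With these choices the numerical spectrum of noiseless multi-exponential
transients agrees with the closed form to better than 1% across the
default band for one to three components — the package's primary internal
oracle (see `tests/testthat/test-acceptance.R`).

## Model-order selection under noise

The transform multiplies white measurement noise by $\omega$, so a raw
noisy spectrum shows spurious loss-modulus maxima at high frequency.
`relaxation_order()` therefore denoises the transient before
transforming, with a cross-validated smoothing spline fitted in
*log-time*: exponential decays are sigmoidal steps of roughly one decade
width on the log-time axis, so the spline follows the fast early decay
with full resolution while averaging over thousands of samples in the
slow tail. The spline's effective degrees of freedom are capped
(`df_cap = 20`): any resolvable sum of a few exponentials plus a plateau
has only a handful of inflections in log-time, so the cap suppresses
noise wiggles without biasing the shape. As a safeguard for very noisy
records, the counting band is truncated where the propagated residual
noise on $E_{IM}$ — white noise of standard deviation $\sigma$ estimated
from second differences, attenuated by the spline's averaging factor
$\sqrt{df/n}$, amplified by $2\pi\nu\sqrt{\Delta t\,T/2}/s$ — exceeds
`noise_cap = 0.25` of the maximum loss modulus. Peaks are detected on
$E_{IM}$ versus $\log\nu$ (equivalent to the Cole–Cole ordering where
$E_R$ is monotone) with a topographic-prominence threshold of 5% of
$\max E_{IM}$, ties breaking toward lower frequency. A loss modulus that
is zero to numerical precision counts zero processes.

The *parameter fit* always uses the raw samples; denoising only informs
the order.

## Fitting

Sum-of-exponentials least squares is ill-conditioned, so
`fit_relaxation()`:

1. initializes $\tau_i$ log-spaced across the record duration;
2. seeds amplitudes by a non-negative linear solve at fixed $\tau$
   (`pracma::lsqnonneg`);
3. refines jointly with Levenberg–Marquardt (`minpack.lm::nls.lm`) in
   $(A_i, \log\tau_i, \Delta\pi_{EQ})$, with $A_i \ge 0$ by default
   (compression steps relax downward; a flag lifts this), free plateau,
   and $\tau_i \in [\Delta t, 10\,T]$;
4. on failure restarts (default 5 times) from jittered initial times; the
   jitter schedule is a fixed table, not drawn from the session RNG, so
   fits are bit-reproducible and never perturb the caller's random state.

Components are reported in ascending $\tau$; (near-)equal times are
merged by amplitude summation; parameter uncertainties come from the fit
covariance (delta method for $\tau$). Fitted neighbouring times closer
than a factor 3 are flagged as unresolved with a warning. Weighting is
uniform.

# Isotherm analytics

`split_cycles()` delimits cycles at area turning points found by a zigzag
scan with a minimum-excursion filter (default 5% of the area range), so
barrier jitter near a turning point cannot fabricate cycles. A cycle runs
from one area maximum to the next; every sample lands in exactly one
branch (or in a reported partial segment), so the recording can be
reconstructed exactly.

Compression branches (not expansion) feed all comparisons, matching the
reading of surfactant penetration upon compression; arguments allow
switching. Branch comparisons interpolate linearly onto the intersection
of the area ranges sampled at the finer branch. Area units are carried
opaquely and must match — converting trough area to per-molecule area
would require molecule counts the recording lacks.

* `stationarity_index()` returns the first cycle from which all later
  consecutive compression branches differ by less than `tol` in maximum
  absolute pressure difference; the default `tol` is 2% of the maximum
  pressure, echoing the typical replicate spread of repeated trough
  measurements.
* `average_isotherms()` reports the pointwise mean ± sd of replicate
  branches plus the maximum pairwise relative deviation as a QC figure
  against that same few-percent spread.
* `squeeze_out_pressure()` scans the comparison in the compression
  direction and returns the lowest test-branch pressure at and above
  which the shift stays below the threshold *through the rest of the
  compression*. The sustained criterion (rather than a first crossing)
  is deliberate noise robustness: physical squeeze-out is a one-way
  disappearance of the shift. The threshold default, 0.5 mN/m, is a
  package decision — no standard numeric criterion exists for "the shift
  disappears" — and is exposed as an argument everywhere.
* `hysteresis_area()` integrates $\pi\,dA$ around the recorded loop
  (trapezoidal, algebraically identical to the shoelace polygon area).

# Penetration kinetics

`penetration_features()` reduces a post-injection trace to
$\Delta\pi_{max} = \max\pi - \pi_0$, the peak time, and the
re-equilibration time — the first time at or after the peak from which
$|\pi - \pi_0| < tol$ holds to the end of the record, with the same
sustained logic and a 0.5 mN/m default tolerance (the re-equilibration
band has no standard definition either). Pre-injection samples
($t < 0$), when present, set $\pi_0$ by their mean; otherwise $\pi_0$
must be supplied. A constant trace re-equilibrates at its first sample; a
trace that never returns (or ends at its peak) yields `NA`, the latter
with a warning.

# Synthetic data: what is and is not emulated

The generators stand in for raw trough recordings and define the study
conditions used throughout the tests:

* `gen_relaxation()` — two relaxation processes with a 30-fold time-scale
  separation ($\tau$ = 10 and 300 s, amplitudes 5 mN/m each), a 2 mN/m
  plateau, a 5% area step, baseline 19 mN/m, sampled at 1 Hz for 10 times
  the slowest $\tau$. Two well-separated processes with a substantial
  equilibrium spring reflect the elastic-dominated, two-peak phenotype of
  meibomian-type films.
* `gen_isotherm_pair()` — a monotone-cubic base isotherm through
  waypoints (no equation of state is claimed), triangular area ramps, ten
  cycles, a geometrically decaying early-cycle drift (4 mN/m halving each
  cycle, so curves become stationary after the third cycle), a tapered
  hysteresis gap so loops close, and an incorporation shift of 8 mN/m
  that either persists or plateaus out at a squeeze-out pressure
  (default example: 23 mN/m) via
  $\pi_{test} = \min(\pi_{ref} + s_0, \max(\pi_{ref}, \pi_{so}))$ — the
  test branch never decreases under compression, as a real film's
  pressure cannot.
* `gen_kinetics()` — $\pi_0 + a(1 - e^{-t/\tau_r})e^{-t/\tau_d}$ with
  $\tau_r = 20$ s, $\tau_d = 300$ s, baseline 18 mN/m and amplitude
  19.3 mN/m, chosen so the noiseless curve peaks at 15.0 mN/m inside the
  first 100 s and returns to baseline on a $\sim$1000 s scale.

Noise is iid Gaussian on the pressure. Real trough traces differ in ways
the generators do not attempt: noise may be autocorrelated or
heteroscedastic, relaxations need not be finite sums of exponentials,
films can leak or collapse, evaporation drifts the baseline, and natural
secretions show compositional heterogeneity. Passing recovery tests
therefore demonstrates correctness of the *computations* under the
assumed signal models, not that any particular laboratory film follows
those models. Every generator records its true parameters (attribute
`truth`, JSON sidecar on write); recovery tests read truth only from
there.

Seeded generation is bit-reproducible and restores the caller's RNG
state.

# Defaults at a glance

| Parameter | Default | Where | Why |
|---|---|---|---|
| strain $\Delta A/A_0$ | 0.05 | generators, configs | step-compression protocol (5 ± 1%) |
| frequency grid | 60 pts/decade, $[1/(10T),\ 1/(4\Delta t)]$ | `compute_spectrum` | full resolvable band; quadrature accurate to <1% |
| plateau estimate | exponential tail fit, window 3 × `tail_frac` | `compute_spectrum` | unbiased against slow components |
| peak prominence | 5% of $\max E_{IM}$ | `cole_cole` | ignores numerical/noise ripple, keeps genuine shoulders |
| classification band | $10^{-4}$–$10^{-3}$ Hz, 90% dominance | `classify_film` | low-frequency regime where elastic/viscous character is discussed |
| order-selection spline | log-time, GCV, df ≤ 20 | `relaxation_order` | few inflections in log-time for any resolvable order |
| $\tau$ bounds | $[\Delta t, 10\,T]$ | `fit_relaxation` | outside these the data carry no information |
| restarts | 5, fixed jitter table | `fit_relaxation` | ill-conditioned fits; reproducibility |
| min excursion | 5% of area range | `split_cycles` | barrier jitter immunity |
| stationarity tol | 2% of max $\pi$ | `stationarity_index` | replicate-spread scale |
| squeeze-out threshold | 0.5 mN/m | `squeeze_out_pressure` | no standard criterion; exposed as argument |
| kinetics tol | 0.5 mN/m | `penetration_features` | same rationale |

# Problem sizes used in the tests

The shipped test-suite and the acceptance script work at the generators'
default scales: relaxation records of 1 001–10 001 samples, 100 seeded
noisy transients for the recovery and model-order properties, ten-cycle
isotherm recordings of ~4 000 samples, and 2 001-sample kinetics traces —
sizes representative of real trough exports while keeping a full run in
the tens of seconds on one CPU.

# Limitations

* No oscillatory-barrier (sinusoidal) rheology protocol; only step
  stress–relaxation.
* No continuous relaxation-spectrum (inverse-Laplace) estimation; the
  model order is a discrete Cole–Cole peak count.
* Model-order selection for three or more noisy processes degrades when
  the slowest relaxation time approaches the record duration — its loss
  peak then sits at the edge of the resolvable band. Two well-separated
  processes are detected essentially always at the 1% noise level; see
  the seeded property tests.
* No equation-of-state fitting, collapse detection, or mixing
  thermodynamics for isotherms; no adsorption-model (e.g. diffusive)
  fitting for kinetics.
* Delimited text only; no instrument-vendor binary formats.
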