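# Fixture builders shared across test files. All synthetic, built in code.

# closed-form loss/storage moduli of a generalized Maxwell film
lorentzian_er <- function(freq, amplitude, tau, plateau, strain) {
  om <- 2 * pi * freq
  (plateau + Reduce(`+`, Map(function(a, tt) a * (om * tt)^2 / (1 + (om * tt)^2),
                             amplitude, tau), accumulate = FALSE)) / strain
}
lorentzian_ei <- function(freq, amplitude, tau, strain) {
  om <- 2 * pi * freq
  Reduce(`+`, Map(function(a, tt) a * (om * tt) / (1 + (om * tt)^2),
                  amplitude, tau)) / strain
}

# a minimal triangular-ramp recording: n_cycles full excursions
triangle_recording <- function(n_cycles = 3, a_max = 10, a_min = 2,
                               n_per_branch = 9, pi_of_a = function(a) 30 - 2 * a) {
  dn <- seq(a_max, a_min, length.out = n_per_branch)
  up <- rev(dn)[-1]
  area <- dn
  for (k in seq_len(n_cycles - 1)) area <- c(area, up, dn[-1])
  area <- c(area, up)
  trough_recording(seq_along(area), area, pi_of_a(area))
}
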