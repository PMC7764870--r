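# Fourier-transform viscoelastic spectra and Cole-Cole analysis.

test_that("analytic spectrum matches the closed form and its limit cases", {
  f <- frequency_grid(fmin = 1e-5, fmax = 10, per_decade = 30)
  A <- c(4, 7); tau <- c(12, 900); plateau <- 3; s <- 0.05
  sp <- analytic_spectrum(data.frame(amplitude = A, tau = tau), plateau, s, f)
  expect_equal(sp$e_real, lorentzian_er(f, A, tau, plateau, s), tolerance = 1e-12)
  expect_equal(sp$e_imag, lorentzian_ei(f, A, tau, s), tolerance = 1e-12)
  # limits: E_R(0) -> plateau/s, E_R(inf) -> (plateau + sum A)/s
  expect_lt(abs(sp$e_real[1] - plateau / s), 0.01 * plateau / s)
  expect_lt(abs(rev(sp$e_real)[1] - (plateau + sum(A)) / s),
            0.01 * (plateau + sum(A)) / s)
  # empty component list: constant elastic spectrum
  flat <- analytic_spectrum(NULL, plateau = 2, strain = 0.05, freqs = f)
  expect_equal(flat$e_real, rep(40, length(f)))
  expect_equal(flat$e_imag, rep(0, length(f)))
})

test_that("single-element loss modulus peaks at nu = 1/(2*pi*tau) with height (A/s)/2", {
  A <- 10; tau <- 100; s <- 0.05
  f <- frequency_grid(fmin = 1e-5, fmax = 1, per_decade = 200)
  sp <- analytic_spectrum(data.frame(amplitude = A, tau = tau), 0, s, f)
  ipk <- which.max(sp$e_imag)
  expect_equal(sp$freq[ipk], 1 / (2 * pi * tau), tolerance = 10^(1 / 200) - 1)
  expect_equal(max(sp$e_imag), (A / s) / 2, tolerance = 1e-4)
})

test_that("transform of sampled transients matches the analytic oracle within 1%", {
  s <- 0.05
  cases <- list(
    list(A = 10, tau = 100, plateau = 0, dt = 1, dur = 1000),
    list(A = c(5, 5), tau = c(10, 300), plateau = 2, dt = 1, dur = 3000),
    list(A = c(4, 3, 3), tau = c(5, 50, 500), plateau = 2, dt = 0.5, dur = 5000))
  for (cs in cases) {
    tr <- gen_relaxation(data.frame(amplitude = cs$A, tau = cs$tau),
                         plateau = cs$plateau, strain = s,
                         noise_sd = 0, dt = cs$dt, duration = cs$dur)
    sp <- compute_spectrum(tr)
    ref <- analytic_spectrum(data.frame(amplitude = cs$A, tau = cs$tau),
                             cs$plateau, s, sp$freq)
    expect_lt(max(abs(sp$e_real - ref$e_real) / pmax(abs(ref$e_real), 1e-9)), 0.01)
    expect_lt(max(abs(sp$e_imag - ref$e_imag) / pmax(abs(ref$e_imag), 1e-9)), 0.01)
  }
})

test_that("the single-exponential example band is reproduced within 1%", {
  A <- 10; tau <- 100; s <- 0.05
  tr <- gen_relaxation(data.frame(amplitude = A, tau = tau), plateau = 0,
                       strain = s, noise_sd = 0, dt = 1, duration = 1000)
  f <- frequency_grid(fmin = 1.6e-4, fmax = 1.6e-2, per_decade = 40)
  sp <- compute_spectrum(tr, freqs = f)
  expect_lt(max(abs(sp$e_real - lorentzian_er(f, A, tau, 0, s)) /
                  lorentzian_er(f, A, tau, 0, s)), 0.01)
  expect_lt(max(abs(sp$e_imag - lorentzian_ei(f, A, tau, s)) /
                  lorentzian_ei(f, A, tau, s)), 0.01)
})

test_that("zero and pure-plateau transients transform exactly", {
  t <- seq(0, 500, by = 1)
  zero <- relaxation_transient(t, rep(20, length(t)) + c(1e-12, numeric(length(t) - 1)),
                               0.05, pi0 = 20)
  sp0 <- compute_spectrum(zero)
  expect_lt(max(abs(sp0$e_real)), 1e-9)
  expect_lt(max(abs(sp0$e_imag)), 1e-9)
  plat <- gen_relaxation(NULL, plateau = 3, strain = 0.05, noise_sd = 0,
                         dt = 1, duration = 500)
  spp <- compute_spectrum(plat)
  expect_equal(spp$e_real, rep(3 / 0.05, length(spp$freq)), tolerance = 1e-9)
  expect_lt(max(abs(spp$e_imag)), 1e-9)
})

test_that("requested frequencies outside the resolvable band raise a range error", {
  tr <- gen_relaxation(noise_sd = 0, dt = 1, duration = 1000)
  expect_error(compute_spectrum(tr, freqs = c(1e-6, 1e-3)),
               class = "filmrheo_range_error")
  expect_error(compute_spectrum(tr, freqs = c(0.01, 5)),
               class = "filmrheo_range_error")
})

test_that("the transform is linear in the relaxation amplitudes", {
  s <- 0.05
  mk <- function(scale) gen_relaxation(
    data.frame(amplitude = scale * c(4, 3), tau = c(20, 400)),
    plateau = scale * 1.5, strain = s, noise_sd = 0, dt = 1, duration = 2000)
  sp1 <- compute_spectrum(mk(1))
  sp2 <- compute_spectrum(mk(2))
  expect_equal(sp2$e_real, 2 * sp1$e_real, tolerance = 1e-9)
  expect_equal(sp2$e_imag, 2 * sp1$e_imag, tolerance = 1e-9)
})

test_that("analytic storage modulus is non-decreasing and loss non-negative", {
  f <- frequency_grid(fmin = 1e-5, fmax = 10, per_decade = 25)
  set.seed(42)
  for (r in 1:20) {
    n <- sample(1:3, 1)
    sp <- analytic_spectrum(
      data.frame(amplitude = runif(n, 0, 10), tau = 10^runif(n, 0, 3)),
      plateau = runif(1, 0, 5), strain = 0.05, freqs = f)
    expect_true(all(diff(sp$e_real) >= -1e-12))
    expect_true(all(sp$e_imag >= -1e-12))
  }
})

test_that("Cole-Cole curve of one element lies on the half-circle of radius E/2", {
  A <- 10; tau <- 100; s <- 0.05; E <- A / s
  f <- frequency_grid(fmin = 1e-5, fmax = 1, per_decade = 60)
  sp <- analytic_spectrum(data.frame(amplitude = A, tau = tau), 0, s, f)
  radial <- sqrt((sp$e_real - E / 2)^2 + sp$e_imag^2)
  expect_lt(max(abs(radial - E / 2)) / (E / 2), 1e-6)
  # numerical pipeline within 2%
  tr <- gen_relaxation(data.frame(amplitude = A, tau = tau), plateau = 0,
                       strain = s, noise_sd = 0, dt = 1, duration = 1000)
  spn <- compute_spectrum(tr)
  radn <- sqrt((spn$e_real - E / 2)^2 + spn$e_imag^2)
  expect_lt(max(abs(radn - E / 2)) / (E / 2), 0.02)
})

test_that("Cole-Cole peak counting resolves the number of relaxation processes", {
  f <- frequency_grid(fmin = 1e-6, fmax = 10, per_decade = 60)
  one <- cole_cole(analytic_spectrum(data.frame(amplitude = 8, tau = 50),
                                     2, 0.05, f))
  expect_equal(one$count, 1)
  two <- cole_cole(analytic_spectrum(
    data.frame(amplitude = c(5, 5), tau = c(3, 300)), 2, 0.05, f))
  expect_equal(two$count, 2)
  expect_true(all(diff(two$peaks$freq) > 0))
  flat <- cole_cole(analytic_spectrum(NULL, 3, 0.05, f))
  expect_equal(flat$count, 0)
  expect_error(cole_cole(viscoelastic_spectrum(1:4, rep(1, 4), rep(0, 4), 0.05)),
               class = "filmrheo_resolution_error")
})

test_that("films classify as elastic, viscous or mixed by E_R vs E_IM dominance", {
  f <- frequency_grid(fmin = 1e-4, fmax = 1e-2, per_decade = 60)
  # plateau only: purely elastic
  expect_equal(classify_film(analytic_spectrum(NULL, 3, 0.05, f))$class,
               "predominantly_elastic")
  # single element with no plateau, band centred on its peak: E_R ~ E_IM
  tau <- 1 / (2 * pi * 1e-3)
  sp <- analytic_spectrum(data.frame(amplitude = 10, tau = tau), 0, 0.05,
                          frequency_grid(fmin = 1e-4, fmax = 1e-2, per_decade = 60))
  cls <- classify_film(sp, band = c(0.8e-3, 1.25e-3))
  expect_equal(cls$class, "mixed")
  expect_error(classify_film(sp, band = c(0.5, 1)), class = "filmrheo_range_error")
})

test_that("dilatational viscosity is recovered as E_IM / (2 pi nu)", {
  A <- 10; tau <- 100; s <- 0.05
  f <- frequency_grid(fmin = 1e-4, fmax = 0.1, per_decade = 20)
  sp <- analytic_spectrum(data.frame(amplitude = A, tau = tau), 0, s, f)
  eta <- dilatational_viscosity(sp)
  om <- 2 * pi * f
  expect_equal(eta, (A / s) * tau / (1 + om^2 * tau^2), tolerance = 1e-12)
})
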