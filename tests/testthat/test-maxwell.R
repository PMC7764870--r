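# Generalized-Maxwell fitting of relaxation transients.

test_that("noiseless single-component parameters are recovered almost exactly", {
  tr <- gen_relaxation(data.frame(amplitude = 10, tau = 100), plateau = 2,
                       strain = 0.05, noise_sd = 0, dt = 1, duration = 1000)
  f <- fit_relaxation(tr, n = 1)
  expect_equal(f$components$amplitude, 10, tolerance = 1e-6)
  expect_equal(f$components$tau, 100, tolerance = 1e-6)
  expect_equal(f$plateau, 2, tolerance = 1e-6)
  expect_lt(f$rms, 1e-6)
})

test_that("noiseless two-component fit with automatic order recovers the generator", {
  tr <- gen_relaxation(data.frame(amplitude = c(5, 5), tau = c(10, 1000)),
                       plateau = 2, strain = 0.05, noise_sd = 0,
                       dt = 1, duration = 10000)
  f <- fit_relaxation(tr, n = "auto")
  expect_equal(f$settings$order_mode, "auto")
  expect_equal(f$n_components, 2)
  expect_equal(f$components$amplitude, c(5, 5), tolerance = 0.01)
  expect_equal(f$components$tau, c(10, 1000), tolerance = 0.01)
  expect_equal(f$plateau, 2, tolerance = 0.01)
})

test_that("a zero transient fits to an empty model with zero plateau", {
  t <- seq(0, 100, by = 1)
  tr <- relaxation_transient(t, rep(20, length(t)), 0.05, pi0 = 20)
  f <- fit_relaxation(tr, n = 0)
  expect_equal(nrow(f$components), 0)
  expect_equal(f$plateau, 0)
  expect_equal(f$rms, 0)
})

test_that("prediction evaluates the model exactly, including its limits", {
  tr <- gen_relaxation(data.frame(amplitude = 10, tau = 100), plateau = 2,
                       strain = 0.05, noise_sd = 0, dt = 1, duration = 1000)
  f <- fit_relaxation(tr, n = 1)
  expect_equal(predict_relaxation(f, 100), 10 / exp(1) + 2, tolerance = 1e-5)
  expect_equal(predict_relaxation(f, 0),
               sum(f$components$amplitude) + f$plateau)
  expect_equal(predict_relaxation(f, 1e9), f$plateau, tolerance = 1e-8)
  expect_error(predict_relaxation(f, -1), class = "filmrheo_validation_error")
  # empty model: constant plateau
  flat <- fit_relaxation(relaxation_transient(0:10, rep(21, 11), 0.05, pi0 = 20),
                         n = 0)
  expect_equal(predict_relaxation(flat, c(0, 50)), c(1, 1))
})

test_that("fit-predict-fit round trip is self-consistent", {
  tr <- gen_relaxation(data.frame(amplitude = c(4, 6), tau = c(20, 600)),
                       plateau = 1.5, strain = 0.05, noise_sd = 0,
                       dt = 1, duration = 6000)
  f1 <- fit_relaxation(tr, n = 2)
  tr2 <- relaxation_transient(tr$time, tr$pi0 + predict_relaxation(f1, tr$time),
                              tr$strain, pi0 = tr$pi0)
  f2 <- fit_relaxation(tr2, n = 2)
  expect_equal(f2$components$amplitude, f1$components$amplitude, tolerance = 1e-4)
  expect_equal(f2$components$tau, f1$components$tau, tolerance = 1e-4)
  expect_equal(f2$plateau, f1$plateau, tolerance = 1e-4)
})

test_that("Maxwell elements obey E_i = A_i/strain, eta_i = tau_i E_i, tau = eta/E", {
  tr <- gen_relaxation(data.frame(amplitude = 10, tau = 100), plateau = 2,
                       strain = 0.05, noise_sd = 0, dt = 1, duration = 1000)
  f <- fit_relaxation(tr, n = 1)
  el <- maxwell_elements(f)
  expect_equal(el$elements$e, 200, tolerance = 1e-5)
  expect_equal(el$elements$eta, 20000, tolerance = 1e-4)
  expect_equal(el$elements$eta / el$elements$e, el$elements$tau, tolerance = 1e-12)
  expect_equal(el$e_eq, 40, tolerance = 1e-5)
  # plateau-only fit: no elements, equilibrium spring only
  flat <- fit_relaxation(relaxation_transient(0:20, rep(22, 21), 0.05, pi0 = 20),
                         n = 0)
  elf <- maxwell_elements(flat)
  expect_equal(nrow(elf$elements), 0)
  expect_equal(elf$e_eq, 2 / 0.05)
})

test_that("spectrum built from fitted elements reproduces the transient's spectrum", {
  tr <- gen_relaxation(data.frame(amplitude = c(5, 5), tau = c(10, 300)),
                       plateau = 2, strain = 0.05, noise_sd = 0,
                       dt = 1, duration = 3000)
  f <- fit_relaxation(tr, n = 2)
  spn <- compute_spectrum(tr)
  spa <- analytic_spectrum(f$components[, c("amplitude", "tau")], f$plateau,
                           f$strain, spn$freq)
  expect_lt(max(abs(spn$e_real - spa$e_real) / pmax(abs(spa$e_real), 1e-9)), 0.011)
  expect_lt(max(abs(spn$e_imag - spa$e_imag) / pmax(abs(spa$e_imag), 1e-9)), 0.011)
})

test_that("parameters are recovered from noisy transients within 10% median error", {
  nrep <- 30
  errs <- matrix(NA_real_, nrep, 5)
  resid_ratio <- numeric(nrep)
  sigma <- 0.01 * 12   # 1% of dpi(0) = A1 + A2 + plateau
  for (r in seq_len(nrep)) {
    tr <- gen_relaxation(data.frame(amplitude = c(5, 5), tau = c(10, 300)),
                         plateau = 2, noise_sd = sigma, seed = 1000 + r)
    f <- fit_relaxation(tr, n = 2)
    tru <- synthetic_truth(tr)
    errs[r, ] <- abs(c(f$components$amplitude / tru$components$amplitude - 1,
                       f$components$tau / tru$components$tau - 1,
                       f$plateau / tru$plateau - 1))
    resid_ratio[r] <- f$rms / sigma
  }
  expect_true(all(apply(errs, 2, median) <= 0.10))
  # a correct-order fit absorbs almost no noise: residual RMS close to sigma
  expect_lt(mean(resid_ratio), 1.2)
})

test_that("automatic order selection matches the generating order when separated", {
  nrep <- 30
  hit <- 0L
  for (r in seq_len(nrep)) {
    tr <- gen_relaxation(data.frame(amplitude = c(5, 5), tau = c(10, 300)),
                         plateau = 2, noise_sd = 0.12, seed = 2000 + r)
    if (relaxation_order(tr)$count == 2L) hit <- hit + 1L
  }
  expect_gte(hit / nrep, 0.9)
})

test_that("unresolvably close relaxation times are flagged", {
  tr <- gen_relaxation(data.frame(amplitude = c(5, 5), tau = c(80, 120)),
                       plateau = 2, noise_sd = 0, dt = 1, duration = 2000)
  expect_warning(f <- fit_relaxation(tr, n = 2), "factor 3")
  expect_false(f$resolvable)
})
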