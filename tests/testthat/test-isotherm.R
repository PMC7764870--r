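# pi-A isotherm cycle analytics.

test_that("a triangular recording splits into the expected number of cycles", {
  rec <- triangle_recording(n_cycles = 10)
  cycles <- split_cycles(rec)
  expect_length(cycles, 10)
  expect_true(all(vapply(cycles, function(cy) all(diff(cy$compression$area) < 0), TRUE)))
  expect_true(all(vapply(cycles, function(cy) all(diff(cy$expansion$area) > 0), TRUE)))
  # compression and expansion meet at the shared area endpoints
  for (cy in cycles) {
    expect_equal(min(cy$compression$area), min(cy$expansion$area),
                 tolerance = 1.01 * max(abs(diff(rec$area))))
  }
})

test_that("a monotone compression yields no cycle but reports the partial segment", {
  rec <- trough_recording(1:10, seq(10, 1), 30 - seq(10, 1))
  expect_warning(cycles <- split_cycles(rec), "no complete")
  expect_length(cycles, 0)
  expect_equal(nrow(attr(cycles, "partial")), 10)
})

test_that("jitter near a turning point does not create spurious cycles", {
  dn <- seq(10, 2, by = -0.5)
  up <- seq(2, 10, by = 0.5)[-1]
  jit <- c(2, 2.05, 1.98, 2.03)            # wobble at the minimum, << excursion
  area <- c(dn, jit, up)
  rec <- trough_recording(seq_along(area), area, 30 - 2 * area)
  expect_length(split_cycles(rec), 1)
})

test_that("splitting partitions every sample into exactly one branch", {
  pair <- gen_isotherm_pair(seed = 21, noise_sd = 0.05, n_cycles = 4,
                            n_per_branch = 60)
  rec <- pair$ref
  cycles <- split_cycles(rec)
  got <- c(unlist(lapply(cycles, function(cy) c(cy$compression$time, cy$expansion$time))),
           attr(cycles, "partial")$time)
  expect_setequal(got, rec$time)
  expect_length(got, length(rec$time))
})

test_that("stationarity onset follows the generator's geometric drift schedule", {
  # drift halves each cycle from 4 mN/m; consecutive distances 2, 1, 0.5, ...
  pair <- gen_isotherm_pair(drift0 = 4, drift_factor = 0.5, n_cycles = 8,
                            noise_sd = 0, seed = 1)
  cycles <- split_cycles(pair$ref)
  expect_identical(as.integer(stationarity_index(cycles, tol = 1)), 3L)
  d <- attr(stationarity_index(cycles, tol = 1), "distances")
  expect_equal(d[1:3], c(2, 1, 0.5), tolerance = 1e-6)
  # identical cycles are stationary from the start
  flat <- split_cycles(gen_isotherm_pair(drift0 = 0, n_cycles = 5, seed = 1)$ref)
  expect_identical(as.integer(stationarity_index(flat, tol = 1)), 1L)
  # constant large drift never stabilizes
  drifty <- split_cycles(gen_isotherm_pair(drift0 = 5, drift_factor = 0.999,
                                           n_cycles = 5, seed = 1)$ref)
  expect_true(is.na(stationarity_index(drifty, tol = 0.001)))
})

test_that("replicate averaging reduces to the branch itself for identical input", {
  b <- data.frame(area = seq(10, 2, by = -0.25), pi = 30 - 2 * seq(10, 2, by = -0.25))
  avg <- average_isotherms(list(b, b, b))
  expect_equal(avg$mean, interp_grid <- b$pi[match(avg$area, b$area)])
  expect_equal(avg$sd, rep(0, nrow(avg)))
  expect_equal(attr(avg, "max_pairwise_rel_dev"), 0)
  # symmetric offsets cancel in the mean
  up <- b; up$pi <- b$pi + 1
  dn <- b; dn$pi <- b$pi - 1
  avg2 <- average_isotherms(list(up, dn))
  expect_equal(avg2$mean, b$pi[match(avg2$area, b$area)], tolerance = 1e-12)
})

test_that("averaging across different grids matches a brute-force interpolation", {
  f <- function(a) 35 - 3 * a + 0.05 * a^2
  b1 <- data.frame(area = seq(10, 2, length.out = 41))
  b1$pi <- f(b1$area)
  b2 <- data.frame(area = seq(9.5, 1.5, length.out = 23))
  b2$pi <- f(b2$area) + 0.5
  avg <- average_isotherms(list(b1, b2))
  # oracle: explicit linear interpolation of both branches on the same grid
  oracle <- (approx(rev(b1$area), rev(b1$pi), xout = avg$area)$y +
             approx(rev(b2$area), rev(b2$pi), xout = avg$area)$y) / 2
  expect_equal(avg$mean, oracle, tolerance = 1e-12)
  expect_error(average_isotherms(list(b1, data.frame(area = c(20, 30), pi = c(1, 0)))),
               class = "filmrheo_overlap_error")
})

test_that("pressure shift recovers constant offsets and is antisymmetric", {
  b <- data.frame(area = seq(10, 2, by = -0.2), pi = 30 - 2 * seq(10, 2, by = -0.2))
  up <- b; up$pi <- b$pi + 3
  cmp <- pressure_shift(b, up)
  expect_equal(cmp$shift, rep(3, length(cmp$area)), tolerance = 1e-12)
  expect_equal(pressure_shift(b, b)$shift, rep(0, length(cmp$area)))
  fwd <- pressure_shift(b, up)
  bwd <- pressure_shift(up, b)
  expect_equal(fwd$shift, -bwd$shift, tolerance = 1e-12)
})

test_that("an area-dependent generator shift is recovered on the grid", {
  pair <- gen_isotherm_pair(shift0 = 6, vanish_pressure = NULL, drift0 = 0,
                            noise_sd = 0, n_cycles = 2, seed = 3)
  cyr <- split_cycles(pair$ref)
  cyt <- split_cycles(pair$test)
  cmp <- pressure_shift(cyr[[2]], cyt[[2]])
  expect_equal(cmp$shift, rep(6, length(cmp$area)), tolerance = 1e-9)
})

test_that("squeeze-out pressure is recovered from a vanishing-shift pair", {
  pair <- gen_isotherm_pair(shift0 = 8, vanish_pressure = 23,
                            drift0 = 0, noise_sd = 0, n_cycles = 2, seed = 5)
  cmp <- pressure_shift(split_cycles(pair$ref)[[2]], split_cycles(pair$test)[[2]])
  sop <- squeeze_out_pressure(cmp, threshold = 0.5)
  expect_lt(abs(sop - 23), 0.5)
  # persistent incorporation: no squeeze-out
  pers <- gen_isotherm_pair(shift0 = 6, vanish_pressure = NULL, drift0 = 0,
                            noise_sd = 0, n_cycles = 2, seed = 6)
  cmp2 <- pressure_shift(split_cycles(pers$ref)[[2]], split_cycles(pers$test)[[2]])
  expect_true(is.na(squeeze_out_pressure(cmp2, threshold = 0.5)))
  # zero shift everywhere: detector returns the lowest pressure of the branch
  same <- split_cycles(pers$ref)[[2]]
  cmp3 <- pressure_shift(same, same)
  expect_equal(squeeze_out_pressure(cmp3, threshold = 0.5), min(cmp3$pi_test))
})

test_that("squeeze-out detection is monotone in the threshold", {
  pair <- gen_isotherm_pair(shift0 = 8, vanish_pressure = 23,
                            drift0 = 0, noise_sd = 0, n_cycles = 2, seed = 7)
  cmp <- pressure_shift(split_cycles(pair$ref)[[2]], split_cycles(pair$test)[[2]])
  thr <- c(0.2, 0.5, 1, 2, 4)
  sop <- vapply(thr, function(th) squeeze_out_pressure(cmp, th), 0)
  expect_true(all(diff(sop) <= 1e-12))
})

test_that("hysteresis area matches geometry and a shoelace brute force", {
  # rectangle loop: height 2 mN/m over width 10 area units -> area 20
  comp <- data.frame(time = 1:11, area = seq(20, 10, by = -1), pi = rep(12, 11))
  expn <- data.frame(time = 12:22, area = seq(10, 20, by = 1), pi = rep(10, 11))
  rect <- structure(list(index = 1, compression = comp, expansion = expn),
                    class = "isotherm_cycle")
  expect_equal(hysteresis_area(rect), 20)
  # identical branches enclose nothing
  flatcy <- split_cycles(triangle_recording(n_cycles = 1))[[1]]
  expect_equal(hysteresis_area(flatcy), 0)
  # synthetic loop vs shoelace polygon area
  cy <- split_cycles(gen_isotherm_pair(hysteresis_gap = 1.5, drift0 = 0,
                                       noise_sd = 0, n_cycles = 1, seed = 8)$ref)[[1]]
  xs <- c(cy$compression$area, cy$expansion$area)
  ys <- c(cy$compression$pi, cy$expansion$pi)
  m <- length(xs)
  shoelace <- abs(sum(xs * ys[c(2:m, 1)] - xs[c(2:m, 1)] * ys)) / 2
  expect_equal(hysteresis_area(cy), shoelace, tolerance = 1e-9)
})
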