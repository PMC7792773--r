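test_that("velocity kick follows the impulse formula exactly", {
  expect_equal(water_velocity_kick(0, 1e-16, 2.99e-26, 1000), 0)
  expect_equal(water_velocity_kick(1e-5, 1e-16, 2.99e-26, 1000),
               1e-5 * 1e-16 / (2.99e-26 * 1000))
  expect_equal(round(water_velocity_kick(1e-5, 1e-16, 2.99e-26, 1000), 1),
               33.4)
  ## homogeneity: linear in I and A, inverse in m and N
  base <- water_velocity_kick(2e-5, 1e-16, 2.99e-26, 500)
  expect_equal(water_velocity_kick(4e-5, 1e-16, 2.99e-26, 500), 2 * base)
  expect_equal(water_velocity_kick(2e-5, 2e-16, 2.99e-26, 500), 2 * base)
  expect_equal(water_velocity_kick(2e-5, 1e-16, 2 * 2.99e-26, 500), base / 2)
  expect_equal(water_velocity_kick(2e-5, 1e-16, 2.99e-26, 1000), base / 2)
  expect_error(water_velocity_kick(1e-5, -1, 2.99e-26, 10), "positive")
  expect_error(water_velocity_kick(1e-5, 1e-16, 2.99e-26, 0), "N must")
})

test_that("binned profiles reproduce flat and sinusoidal membranes", {
  set.seed(6)
  flat <- data.frame(x = runif(5000, 0, 30), z = 5)
  pr <- bin_membrane_profile(flat, 50, 30)
  expect_true(all(pr$z == 5))
  expect_false(any(pr$interpolated))
  ## dense deterministic sine sampling: bin means deviate from the sine at
  ## the bin centres only by the discretisation (Taylor) error
  xs <- seq(0, 30, by = 30 / 4e4)[-1]
  sine <- data.frame(x = xs, z = sin(2 * pi * xs / 30))
  pr2 <- bin_membrane_profile(sine, 50, 30)
  expect_lt(max(abs(pr2$z - sin(2 * pi * pr2$x / 30))), (pi / 50)^2 / 2)
  ## particles confined to half the box at fine binning
  half <- data.frame(x = runif(200, 0, 15), z = 1)
  expect_error(bin_membrane_profile(half, 50, 30), "empty")
})

test_that("sine fitting inverts exact and noisy profiles", {
  x <- (1:50 - 0.5) * 30 / 50
  exact <- tibble::tibble(x = x, z = 2 * sin(2 * pi * x / 30))
  f <- fit_sine_profile(exact, 30)
  expect_equal(f$amplitude, 2, tolerance = 1e-8)
  expect_equal(f$wavelength, 30, tolerance = 1e-6)
  expect_false(f$degenerate)
  ## noisy with offset and phase, Monte-Carlo over seeds
  errs <- vapply(1:5, function(s) {
    set.seed(s)
    noisy <- tibble::tibble(x = x,
                            z = 1 * sin(2 * pi * x / 30 + 0.7) + 3 +
                              rnorm(50, sd = 0.05))
    abs(fit_sine_profile(noisy, 30)$amplitude - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
  ## flat profile is flagged degenerate
  flat <- tibble::tibble(x = x, z = rep(4, 50))
  ff <- fit_sine_profile(flat, 30)
  expect_true(ff$degenerate)
  expect_equal(ff$amplitude, 0)
  expect_true(is.na(ff$wavelength))
})

test_that("amplitude tracking recovers the damped-oscillation envelope", {
  cf <- wave_config(amplitude0 = 1, damping_tau = 500, omega = 0.05,
                    noise = 0, n_frames = 300, n_atoms = 3000, seed = 10)
  ws <- amplitude_evolution(gen_wave_trajectory(cf))
  ## A(t) matches the analytic envelope
  expected <- with(ws$amplitude,
                   1 * exp(-time / 500) * abs(cos(0.05 * time)))
  expect_lt(max(abs(ws$amplitude$amplitude - expected)), 0.03)
  ## extrema alternate and maxima sit at k pi / omega within one frame
  expect_true(all(ws$extrema$type[-1] != head(ws$extrema$type, -1)))
  mx <- ws$extrema$time[ws$extrema$type == "max"]
  k <- round(mx * 0.05 / pi)
  expect_lt(max(abs(mx - k * pi / 0.05)), cf$dt + 1e-9)
  ## nonlinear envelope fit: (A0, tau, omega) within (5%, 5%, 2%)
  env <- recover_wave_envelope(ws)
  expect_equal(env$amplitude0, 1, tolerance = 0.05)
  expect_equal(env$damping_tau, 500, tolerance = 0.05)
  expect_equal(env$omega, 0.05, tolerance = 0.02)
})

test_that("a static flat membrane yields no extrema", {
  cf <- wave_config(amplitude0 = 0, noise = 0, n_frames = 30, n_atoms = 500)
  ws <- amplitude_evolution(gen_wave_trajectory(cf))
  expect_equal(nrow(ws$extrema), 0)
  expect_true(all(ws$profiles$degenerate | ws$profiles$amplitude < 1e-8))
})

test_that("wave comparison reports lags and rate ratios", {
  mk <- function(omega, tau = 800, noise = 0, seed = 1) amplitude_evolution(
    gen_wave_trajectory(wave_config(omega = omega, damping_tau = tau,
                                    noise = noise, n_frames = 250,
                                    n_atoms = 1500, seed = seed)))
  a <- mk(0.05)
  ## identical series: zero lags, equal counts
  self <- compare_wave_response(a, a)
  expect_true(all(self$maxima$lag == 0))
  expect_equal(self$rate_ratio, 1)
  ## faster oscillator: first-maximum lag ~ pi/omega_a - pi/omega_b,
  ## extrema rate ratio ~ 1.3
  b <- mk(0.065)
  cmp <- compare_wave_response(a, b)
  expect_equal(cmp$maxima$lag[1], pi / 0.065 - pi / 0.05, tolerance = 0.35)
  expect_equal(cmp$rate_ratio, 1.3, tolerance = 0.15)
  ## heavy damping: the envelope decays below the detection floor early,
  ## so fewer extrema are found over the same span
  a_noisy <- mk(0.05, noise = 0.05)
  c_fast_decay <- mk(0.05, tau = 60, noise = 0.05)
  cmp2 <- compare_wave_response(a_noisy, c_fast_decay)
  expect_lt(cmp2$rate_b, cmp2$rate_a)
  ## degenerate when one series has no extrema
  flat <- amplitude_evolution(gen_wave_trajectory(
    wave_config(amplitude0 = 0, noise = 0, n_frames = 30, n_atoms = 500)))
  deg <- compare_wave_response(a, flat)
  expect_true(deg$degenerate)
})
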