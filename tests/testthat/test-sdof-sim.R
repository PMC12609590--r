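test_that("frequency response has unit static gain and inertial rolloff", {
  p <- ppg_params()
  fr0 <- sdof_frequency_response(p, 0)
  expect_equal(fr0$gain, 1)
  expect_equal(fr0$phase, 0)
  # tactile static gain is k0 / (k0 + ks)
  pt <- sdof_params()
  expect_equal(sdof_frequency_response(pt, 0)$gain,
               pt$k0 / (pt$k0 + pt$ks))
  # far above the natural frequency the mass cannot follow
  hi <- sdof_frequency_response(p, 1e6 * sqrt(p$k0 / p$m0))
  expect_lt(hi$gain, 1e-6)
  expect_error(sdof_frequency_response(p, -1), "omega")
})

test_that("closed-form gain matches the integrated oscillator", {
  # natural frequency 10 Hz, damping ratio 0.3, driven at 1.2 Hz:
  # steady-state amplitude/phase from the ODE within 0.5 %
  p <- ppg_params()
  fs <- 500
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  u <- tibble::tibble(time = tt, value = sin(2 * pi * 1.2 * tt),
                      deriv = 2 * pi * 1.2 * cos(2 * pi * 1.2 * tt))
  x <- sdof_solve(p, u, forcing = "pulse", oversample = 2)
  w <- tt > 5
  basis <- cbind(sin(2 * pi * 1.2 * tt[w]), cos(2 * pi * 1.2 * tt[w]))
  cf <- stats::coef(stats::lm(x$value[w] ~ basis - 1))
  fr <- sdof_frequency_response(p, 2 * pi * 1.2)
  expect_equal(sqrt(sum(cf^2)), fr$gain, tolerance = 0.005)
  expect_equal(atan2(cf[2], cf[1]), fr$phase, tolerance = 0.005,
               ignore_attr = TRUE)
})

test_that("forced solve honours zero input and the quasi-static limit", {
  p <- sdof_params()
  fs <- 100
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  zero <- tibble::tibble(time = tt, value = 0, deriv = 0)
  expect_true(all(sdof_solve(p, zero)$value == 0))
  # slow drift through the sensor gains settles at ks / (k0 + ks)
  u <- tibble::tibble(time = tt, value = sin(2 * pi * 0.1 * tt),
                      deriv = 2 * pi * 0.1 * cos(2 * pi * 0.1 * tt))
  xs <- sdof_solve(p, u, forcing = "sensor")
  w <- tt > 5
  expect_equal(max(abs(xs$value[w])), p$ks / (p$k0 + p$ks),
               tolerance = 0.01)
})

test_that("TVSP solve reduces to LTI at zero coupling and makes sidebands", {
  p <- ppg_params()
  fs <- 100
  tt <- seq(0, 40 - 1 / fs, by = 1 / fs)
  y <- tibble::tibble(time = tt, value = sin(2 * pi * 3.6 * tt),
                      deriv = 2 * pi * 3.6 * cos(2 * pi * 3.6 * tt))
  xb <- tibble::tibble(time = tt, value = sin(2 * pi * 0.2 * tt))
  x0 <- sdof_solve(p, y, forcing = "pulse")
  expect_equal(sdof_solve_tvsp(p, tvsp_coupling(0, 0, 0), xb, y)$value,
               x0$value, tolerance = 1e-12)
  # small staggered coupling: distortion concentrates in sidebands at
  # 3.6 +/- multiples of 0.2 Hz
  d <- sdof_solve_tvsp(p, tvsp_coupling(0.05, 0.1, 0.2), xb, y)$value -
    x0$value
  w <- tt > 5
  a2 <- Mod(stats::fft(d[w]))^2
  freq <- (seq_along(a2) - 1) * fs / length(a2)
  half <- freq <= fs / 2
  near <- half & abs(freq - 3.6) <= 0.6
  expect_gt(sum(a2[near]) / sum(a2[half]), 0.9)  # sideband law
  top <- freq[half][which.max(a2[half] * !(abs(freq[half] - 3.6) < 0.05))]
  expect_lt(abs(abs(top - 3.6) - 0.2), 0.06)  # first-order sideband wins
})

test_that("distortion is first-order in the coupling", {
  p <- ppg_params()
  fs <- 100
  tt <- seq(0, 40 - 1 / fs, by = 1 / fs)
  y <- tibble::tibble(time = tt, value = sin(2 * pi * 3.6 * tt),
                      deriv = 2 * pi * 3.6 * cos(2 * pi * 3.6 * tt))
  xb <- tibble::tibble(time = tt, value = sin(2 * pi * 0.2 * tt))
  x0 <- sdof_solve(p, y, forcing = "pulse")$value
  w <- tt > 5 & tt < 35
  d1 <- sdof_solve_tvsp(p, tvsp_coupling(0.05, 0.075, 0.1), xb, y)$value - x0
  d2 <- sdof_solve_tvsp(p, tvsp_coupling(0.025, 0.0375, 0.05), xb, y)$value - x0
  expect_equal(max(abs(d1[w])) / max(abs(d2[w])), 2, tolerance = 0.1)
})

test_that("equal fractional coupling is distortion-free when ks = cs = 0", {
  # the common factor (1 + alpha xhat_b) cancels from both sides of the
  # equation of motion: a degenerate direction of the model
  p <- ppg_params()
  fs <- 100
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  y <- tibble::tibble(time = tt, value = sin(2 * pi * 3.6 * tt),
                      deriv = 2 * pi * 3.6 * cos(2 * pi * 3.6 * tt))
  xb <- tibble::tibble(time = tt, value = sin(2 * pi * 0.2 * tt))
  d <- sdof_solve_tvsp(p, tvsp_coupling(0.5, 0.5, 0.5), xb, y)$value -
    sdof_solve(p, y, forcing = "pulse")$value
  expect_lt(max(abs(d)), 1e-10)
})

test_that("measurement bundles satisfy their construction identities", {
  spec <- three_harmonic_spec(duration = 60)
  y <- synth_pulse(spec)
  ma <- gen_ma_rest(100, 60, rms_amplitude = 0.3, seed = 2)

  # ppg: measured = y + x_tvsp + baseline; zero artifact returns y itself
  pb <- simulate_measurement("ppg", ppg_params(), tvsp_coupling(), y, ma)
  expect_equal(pb$measured, y$value + pb$x_tvsp + pb$baseline)
  expect_equal(pb$x_tvsp, pb$x_m - pb$x_c)
  clean <- simulate_measurement("ppg", ppg_params(),
                                tvsp_coupling(0, 0, 0), y, ma = NULL)
  expect_equal(clean$measured, y$value)

  # tactile: measured = x_m + (x_b - z_b); zero artifact returns x_c
  tb <- simulate_measurement("tactile", sdof_params(), tvsp_coupling(),
                             y, ma)
  expect_equal(tb$measured, tb$x_m + tb$baseline)
  tclean <- simulate_measurement("tactile", sdof_params(),
                                 tvsp_coupling(0, 0, 0), y, ma = NULL)
  expect_equal(tclean$measured, tclean$x_c)

  expect_error(
    simulate_measurement("ppg", sdof_params(), tvsp_coupling(), y, ma),
    "ks = cs = 0"
  )
})

test_that("response is linear in the pulse excitation", {
  spec <- three_harmonic_spec(duration = 40)
  y <- synth_pulse(spec)
  y2 <- dplyr::mutate(y, value = 2 * value, deriv = 2 * deriv)
  ma <- gen_ma_rest(100, 40, rms_amplitude = 0.3, seed = 4)
  p <- ppg_params()
  b1 <- simulate_measurement("ppg", p, tvsp_coupling(), y, ma)
  b2 <- simulate_measurement("ppg", p, tvsp_coupling(), y2, ma)
  expect_equal(b2$x_c, 2 * b1$x_c, tolerance = 1e-12)
  w <- y$time > 5
  expect_equal(b2$x_m[w], 2 * b1$x_m[w], tolerance = 0.02)
})

test_that("activity-band artifact distorts on and far off the harmonic", {
  # artifact at 3 f_c lands on the 3rd harmonic: the distortion has a
  # small component there plus larger components far off the pulse line
  spec <- eq27_spec(duration = 60)
  y <- synth_pulse(spec)
  ma <- gen_ma_activity(3 * 1.2, 100, 60)
  bun <- simulate_measurement("ppg", ppg_params(),
                              tvsp_coupling(0.1, 0.4, 0.8), y, ma)
  w <- y$time > 5
  a <- Mod(stats::fft(bun$x_tvsp[w]))
  freq <- (seq_along(a) - 1) * 100 / length(a)
  half <- freq <= 50
  on_line <- half & abs(freq - 3.6) < 0.1
  far_off <- half & (abs(freq - 3.6) > 1) & freq > 0.2
  expect_gt(max(a[on_line]), 0)
  expect_gt(max(a[far_off]), max(a[on_line]))
})

test_that("parameter validation catches bad oscillators and couplings", {
  expect_error(sdof_params(m0 = -1), "m0 > 0")
  expect_error(sdof_params(f_natural = Inf), "finite")
  expect_error(sdof_params(ks_ratio = 0.2, sensor_kind = "ppg"), "PPG")
  expect_error(tvsp_coupling(1.2, 0, 0), "too large")
})
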