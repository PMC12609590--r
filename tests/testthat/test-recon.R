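# a minimal hand-built harmonic track for unit-testing the summaries
make_track <- function(tt, amplitude, frequency, phi0, i = 1, f_c = 1.2,
                       fs = 100) {
  out <- tibble::tibble(
    time = tt,
    amplitude = amplitude,
    frequency = frequency,
    phi0 = phi0,
    component = amplitude * cos(2 * pi * frequency * tt + phi0),
    valid = TRUE
  )
  attr(out, "harmonic") <- i
  attr(out, "f_c") <- f_c
  attr(out, "fs") <- fs
  class(out) <- c("harmonic_track", class(out))
  out
}

test_that("amplitude regression is exact least squares", {
  tt <- seq(0, 60, by = 0.01)
  tr <- make_track(tt, 2, 1.2, 0)
  reg <- amplitude_regression(tr)
  expect_equal(reg$slope, 0, tolerance = 1e-10)
  expect_equal(reg$intercept, 2, tolerance = 1e-10)
  tr2 <- make_track(tt, 1 + 0.01 * tt, 1.2, 0)
  reg2 <- amplitude_regression(tr2)
  expect_equal(reg2$slope, 0.01, tolerance = 1e-6)
  expect_equal(reg2$intercept, 1, tolerance = 1e-6)
  # a zero-mean oscillation, even about the window midpoint, is
  # orthogonal to the time regressor over integer periods
  tt3 <- seq(0, 40 - 0.01, by = 0.01)  # two 20 s periods
  tr3 <- make_track(tt3, 2 + 0.5 * cos(2 * pi * 0.05 * tt3), 1.2, 0)
  reg3 <- amplitude_regression(tr3)
  expect_equal(reg3$slope, 0, tolerance = 1e-3)
  expect_equal(reg3$intercept, 2, tolerance = 5e-3)
  expect_error(amplitude_regression(make_track(1:5 / 100, 1, 1.2, 0)),
               "10 valid samples")
})

test_that("phase mean behaves on constants and zero-mean oscillations", {
  tt <- seq(0, 40 - 0.01, by = 0.01)
  expect_equal(phase_mean(make_track(tt, 1, 1.2, 5.78)), 5.78)
  # mean over integer respiration periods returns the offset
  osc <- make_track(tt, 1, 1.2, 1.3 + 0.3 * sin(2 * pi * 0.2 * tt))
  expect_equal(phase_mean(osc), 1.3, tolerance = 1e-6)
  # the regression line through A evaluated midwindow equals mean(A)
  tr <- make_track(tt, 1 + 0.02 * tt, 1.2, 0)
  reg <- amplitude_regression(tr)
  expect_equal(reg$intercept + reg$slope * mean(tt),
               mean(tr$amplitude), tolerance = 1e-9)
})

test_that("tf and cf reconstructions coincide for constant frequency", {
  tt <- seq(0, 60 - 0.01, by = 0.01)
  tracks <- list(
    make_track(tt, 1.0, 1.2, 0.4, i = 1),
    make_track(tt, 0.5, 2.4, 1.1, i = 2)
  )
  tracks[[2]]$phi0 <- rep(1.1, length(tt))
  tracks[[1]]$phi0 <- rep(0.4, length(tt))
  s <- harmonic_summaries(tracks)
  tf <- reconstruct_pulse(tracks, s, "tf", f_c = 1.2)
  cf <- reconstruct_pulse(tracks, s, "cf", f_c = 1.2)
  expect_equal(tf$value, cf$value, tolerance = 1e-6)
})

test_that("the pipeline's tf reconstruction rebuilds a clean pulse", {
  spec <- three_harmonic_spec()
  fit <- quiet_analysis(synth_pulse(spec)[1:2],
                        analysis_config(n_harmonics = 3, f_c = 1.2))
  v <- fit$track_list[[1]]$valid
  expect_lt(rel_rmse(fit$recon$x_tf[v], fit$recon$x0[v]), 0.05)
  # cf output is periodic at 1/f_c up to the slow amplitude trend
  lag <- round(fit$fs / fit$f_c)
  xcf <- fit$recon$x_cf[v]
  expect_lt(rel_rmse(xcf[-(1:lag)], xcf[seq_len(length(xcf) - lag)]),
            0.05)
})

test_that("distortion estimate is the elementwise residual", {
  tt <- seq(0, 1, by = 0.01)
  a <- tibble::tibble(time = tt, value = sin(tt))
  expect_true(all(tvsp_estimate(a, a)$value == 0))
  b <- tibble::tibble(time = tt, value = 0.5 * sin(tt))
  expect_equal(tvsp_estimate(a, b)$value, 0.5 * sin(tt))
  expect_error(tvsp_estimate(a, b[1:50, ]), "length")
})

test_that("the distortion estimate tracks the simulated ground truth", {
  # a soft stack (natural frequency 4 Hz) with default coupling and slow
  # drift, no respiration: the regime where the multiplicative
  # distortion dominates the reconstruction floor.  The residual-based
  # estimate can only capture the envelope-borne part of the distortion
  # -- the phase-borne part is deliberately absorbed into the
  # time-varying-frequency reconstruction (heart-rate variability must
  # be preserved) -- which caps the attainable correlation below ~0.7.
  spec <- pulse_spec(f_c = 1.5, amplitudes = c(1, 0.457, 0.407),
                     phases = c(0, 5.781, 5.420), fs = 100, duration = 80)
  y <- synth_pulse(spec)
  p <- sdof_params(f_natural = 4, ks_ratio = 0, cs_ratio = 0,
                   sensor_kind = "ppg")
  cors <- vapply(1:3, function(s) {
    ma <- gen_ma_rest(100, 80, cutoff = 0.5, rms_amplitude = 0.3,
                      seed = s)
    bun <- simulate_measurement("ppg", p, tvsp_coupling(), y, ma)
    fit <- quiet_analysis(
      tibble::tibble(time = bun$time, value = bun$measured),
      analysis_config(n_harmonics = 3, f_c = 1.5)
    )
    v <- fit$track_list[[1]]$valid
    stats::cor(fit$recon$x_tvsp[v], bun$x_tvsp[v])
  }, numeric(1))
  expect_true(all(cors > 0.6))
})

test_that("waveform summary recovers generator amplitude ratios", {
  spec <- pulse_spec(f_c = 1.2, amplitudes = c(1, 0.5, 0.25),
                     resp_amplitude = 0.1, resp_rate = 0.2,
                     fs = 100, duration = 80)
  y <- synth_pulse(spec)
  fit <- quiet_analysis(y[1:2], analysis_config(n_harmonics = 3,
                                                f_c = 1.2))
  truth <- c(1, 0.5, 0.25)
  for (col in c("a_bar_ratio", "a_x0_ratio", "a_tf_ratio", "a_cf_ratio")) {
    expect_equal(fit$apw[[col]], truth, tolerance = 0.03)
  }
  expect_equal(fit$apw$phase_diff[1], 0)
  expect_equal(fit$apw$a_bar_ratio[1], 1)

  # worked-example-level respiration (0.3 rad) must not disturb the
  # ratios either: the sharp baseline separator keeps the first
  # harmonic and its sidebands intact
  spec3 <- pulse_spec(f_c = 1.2, amplitudes = c(1, 0.5, 0.25),
                      resp_amplitude = 0.3, resp_rate = 0.2,
                      fs = 100, duration = 80)
  fit3 <- quiet_analysis(synth_pulse(spec3)[1:2],
                         analysis_config(n_harmonics = 3, f_c = 1.2))
  expect_equal(fit3$apw$a_cf_ratio, truth, tolerance = 0.03)

  # single-harmonic degenerate case
  spec1 <- pulse_spec(f_c = 1.2, amplitudes = 1, fs = 100, duration = 80)
  fit1 <- quiet_analysis(synth_pulse(spec1)[1:2],
                         analysis_config(n_harmonics = 1, f_c = 1.2))
  expect_equal(fit1$apw$a_cf_ratio, 1)
  expect_equal(fit1$apw$phase_diff, 0)
})

test_that("cleaned amplitude ratios survive motion artifacts", {
  spec <- pulse_spec(f_c = 1.2, amplitudes = c(1, 0.5, 0.25),
                     resp_amplitude = 0.3, resp_rate = 0.2,
                     fs = 100, duration = 80)
  y <- synth_pulse(spec)
  ma <- gen_ma_rest(100, 80, rms_amplitude = 0.3, seed = 3)
  bun <- simulate_measurement("ppg", ppg_params(), tvsp_coupling(), y, ma)
  noise <- withr::with_seed(11, stats::rnorm(nrow(bun), sd = 0.05))
  fit <- quiet_analysis(
    tibble::tibble(time = bun$time, value = bun$measured + noise),
    analysis_config(n_harmonics = 3, f_c = 1.2)
  )
  truth <- c(1, 0.5, 0.25)
  expect_equal(fit$apw$a_cf_ratio, truth, tolerance = 0.05)
  # mean-amplitude and constant-frequency routes agree closely
  expect_equal(fit$apw$a_bar_ratio, fit$apw$a_cf_ratio, tolerance = 0.02)
  # energy sanity on the decomposition identity
  nrm <- function(x) sqrt(sum(x^2))
  expect_lte(nrm(fit$recon$x_tf),
             nrm(fit$recon$x_hvd) + nrm(fit$recon$x_tvsp) + 1e-9)
})
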