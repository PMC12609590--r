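# shared fixtures: everything is generated in code at test time

# the single-3rd-harmonic worked example: unit amplitude, f_c = 1.2 Hz,
# respiration R = 0.3 rad at 0.2 Hz
eq27_spec <- function(duration = 80, fs = 100) {
  pulse_spec(
    f_c = 1.2, amplitudes = c(0, 0, 1),
    resp_amplitude = 0.3, resp_rate = 0.2,
    fs = fs, duration = duration
  )
}

# three-harmonic pulse with the measured pre-exercise amplitude ratios
three_harmonic_spec <- function(resp_amplitude = 0.3, resp_rate = 0.2,
                                f_c = 1.2, duration = 80, fs = 100) {
  pulse_spec(
    f_c = f_c, amplitudes = c(1, 0.457, 0.407),
    phases = c(0, 5.781, 5.420),
    resp_amplitude = resp_amplitude, resp_rate = resp_rate,
    fs = fs, duration = duration
  )
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
rel_rmse <- function(a, b) rmse(a, b) / sqrt(mean(b^2))

# oscillation amplitude of a (nearly) sinusoidal series
osc_amp <- function(x) sqrt(2) * stats::sd(x)

quiet_analysis <- function(...) suppressMessages(run_analysis(...))

ppg_params <- function(...) {
  sdof_params(ks_ratio = 0, cs_ratio = 0, sensor_kind = "ppg", ...)
}

# run split + instant-parameter extraction for one harmonic
one_track <- function(data, i, f_c, n = i) {
  prep <- preprocess_pulse(data[c("time", "value")], f_c = f_c)
  hs <- split_harmonics(prep, f_c = f_c, n = n)
  harmonic_instant_params(
    hs[hs$harmonic == i, c("time", "value")], i = i, f_c = f_c
  )
}
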