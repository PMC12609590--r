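# Ground-truth generators: multi-harmonic pulse waves with respiratory
# phase modulation, the matching respiration reference, and the two
# motion-artifact families (band-limited drift at rest; decaying tone
# during activities).  All generators are pure functions of (spec, seed)
# and return closed-form derivatives where one exists, so the SDOF
# simulator never has to differentiate numerically.

#' Specify a synthetic arterial pulse
#'
#' An arterial pulse is modelled as a sum of harmonics of the constant
#' heart rate `f_c`, all sharing one respiratory phase modulation
#' `psi(t) = R sin(2 pi f_r t + alpha0)` (respiratory sinus arrhythmia
#' acting on the heart rate):
#' `y(t) = sum_i A_i cos(2 pi i f_c t + phi0_i + psi(t))`.
#'
#' @param f_c Fundamental (heart-rate) frequency in Hz; must exceed 0.2 Hz
#'   so the per-harmonic bandwidth rule `BW = f_c - 0.2` stays positive.
#' @param amplitudes Numeric vector of harmonic amplitudes `A_i` (a.u.),
#'   one per harmonic in order.
#' @param phases Initial phases in rad; recycled to the number of harmonics.
#' @param resp_amplitude Phase-modulation amplitude `R` in rad (>= 0).
#' @param resp_rate Respiration frequency `f_r` in Hz; must lie in
#'   (0, 0.7) when `resp_amplitude > 0`.
#' @param resp_phase Respiration initial phase `alpha0` in rad.
#' @param fs Sampling rate in Hz; must exceed twice the highest harmonic.
#' @param duration Record length in seconds.
#' @return A `pulse_spec` list.
#' @examples
#' # the single-3rd-harmonic worked example: f from respiration is
#' # 3.6 - 0.06 cos(2 pi 0.2 t) Hz
#' spec <- pulse_spec(
#'   f_c = 1.2, amplitudes = c(0, 0, 1),
#'   resp_amplitude = 0.3, resp_rate = 0.2
#' )
#' @export
pulse_spec <- function(f_c = 1.2, amplitudes = 1, phases = 0,
                       resp_amplitude = 0, resp_rate = 0.2,
                       resp_phase = 0, fs = 100, duration = 80) {
  stopifnot(is.numeric(amplitudes), length(amplitudes) >= 1,
            all(is.finite(amplitudes)), all(amplitudes >= 0))
  n <- length(amplitudes)
  phases <- rep_len(phases, n)
  if (!is.finite(f_c) || f_c <= 0.2) {
    stop("`f_c` must exceed 0.2 Hz (band-width rule BW = f_c - 0.2)",
         call. = FALSE)
  }
  if (fs <= 2 * (n + 1) * f_c) {
    stop("`fs` = ", fs, " Hz violates the Nyquist margin for ", n,
         " harmonics of ", f_c, " Hz", call. = FALSE)
  }
  if (resp_amplitude < 0) stop("`resp_amplitude` must be >= 0", call. = FALSE)
  if (resp_amplitude > 0 && (resp_rate <= 0 || resp_rate >= 0.7)) {
    stop("`resp_rate` must lie in (0, 0.7) Hz when modulation is present",
         call. = FALSE)
  }
  structure(
    list(
      f_c = f_c, amplitudes = amplitudes, phases = phases,
      resp_amplitude = resp_amplitude, resp_rate = resp_rate,
      resp_phase = resp_phase, fs = fs, duration = duration
    ),
    class = "pulse_spec"
  )
}

spec_time <- function(spec) {
  seq(0, spec$duration - 1 / spec$fs, by = 1 / spec$fs)
}

#' Synthesize a multi-harmonic pulse wave
#'
#' Evaluates the harmonic-sum model of a [pulse_spec()] in closed form,
#' including its time derivative (needed as the base-excitation velocity
#' by the SDOF simulator).
#'
#' @param spec A [pulse_spec()].
#' @return Tibble with columns `time`, `value`, `deriv`.
#' @export
synth_pulse <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  tt <- spec_time(spec)
  psi <- spec$resp_amplitude *
    sin(2 * pi * spec$resp_rate * tt + spec$resp_phase)
  dpsi <- 2 * pi * spec$resp_rate * spec$resp_amplitude *
    cos(2 * pi * spec$resp_rate * tt + spec$resp_phase)
  value <- deriv <- numeric(length(tt))
  for (i in seq_along(spec$amplitudes)) {
    arg <- 2 * pi * i * spec$f_c * tt + spec$phases[i] + psi
    value <- value + spec$amplitudes[i] * cos(arg)
    deriv <- deriv - spec$amplitudes[i] *
      (2 * pi * i * spec$f_c + dpsi) * sin(arg)
  }
  tibble::tibble(time = tt, value = value, deriv = deriv)
}

#' Respiration signal embedded in the harmonic frequency
#'
#' The phase modulation `psi(t) = R sin(2 pi f_r t + alpha0)` shifts the
#' frequency of every harmonic by a respiration signal
#' `r(t) = B cos(2 pi f_r t + alpha0)` with modulation depth
#' `B = -R f_r` (in Hz) -- the ground truth that frequency-based
#' respiration extraction should recover (up to sign convention).
#'
#' @param spec A [pulse_spec()].
#' @return Tibble with columns `time`, `value`; the modulation depth `B`
#'   is attached as attribute `"B"`.
#' @export
resp_reference <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  tt <- spec_time(spec)
  b <- -spec$resp_amplitude * spec$resp_rate
  out <- tibble::tibble(
    time = tt,
    value = b * cos(2 * pi * spec$resp_rate * tt + spec$resp_phase)
  )
  attr(out, "B") <- b
  out
}

#' Band-limited baseline drift: motion artifact at rest
#'
#' At rest, motion artifacts manifest as baseline drift below 0.7 Hz.
#' This generator draws zero-mean Gaussian noise, band-limits it below
#' `cutoff` in the frequency domain (raised-cosine rolloff from 90 % of
#' the cutoff), and rescales to the requested RMS; it is bitwise
#' reproducible for a fixed seed.  The derivative is obtained by central
#' differences (the drift has no closed form).
#'
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds.
#' @param cutoff Drift band edge in Hz (default 0.7).
#' @param rms_amplitude Target RMS of the drift (a.u.); 0 gives zeros.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Tibble with columns `time`, `value`, `deriv`.
#' @export
gen_ma_rest <- function(fs, duration, cutoff = 0.7, rms_amplitude = 0.3,
                        seed = 1L) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  if (rms_amplitude == 0) {
    return(tibble::tibble(time = tt, value = 0, deriv = 0))
  }
  raw <- withr::with_seed(seed, stats::rnorm(length(tt)))
  # brick-wall band limitation with a raised-cosine rolloff starting at
  # 90 % of the cutoff: the drift is genuinely confined below `cutoff`
  n <- length(raw)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided
  lo <- 0.9 * cutoff
  mask <- ifelse(freq <= lo, 1,
                 ifelse(freq >= cutoff, 0,
                        0.5 * (1 + cos(pi * (freq - lo) / (cutoff - lo)))))
  drift <- Re(stats::fft(stats::fft(raw) * mask, inverse = TRUE)) / n
  drift <- drift - mean(drift)
  drift <- drift * rms_amplitude / sqrt(mean(drift^2))
  tibble::tibble(time = tt, value = drift,
                 deriv = numeric_deriv(drift, fs))
}

#' Decaying-tone motion artifact during activities
#'
#' Activity-band motion artifacts are modelled as a slowly decaying
#' cosine `exp(-0.01 t) cos(2 pi f t)` whose frequency falls inside the
#' pulse band itself (e.g. on or near the 3rd harmonic), so it cannot be
#' removed by low-pass separation.
#'
#' @param f Artifact frequency in Hz (f < fs/2).
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds.
#' @return Tibble with columns `time`, `value`, `deriv` (closed form).
#' @export
gen_ma_activity <- function(f, fs, duration) {
  stopifnot(f < fs / 2)
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  env <- exp(-0.01 * tt)
  tibble::tibble(
    time = tt,
    value = env * cos(2 * pi * f * tt),
    deriv = env * (-0.01 * cos(2 * pi * f * tt) -
                     2 * pi * f * sin(2 * pi * f * tt))
  )
}
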