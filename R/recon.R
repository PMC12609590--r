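# Motion-artifact removal by per-harmonic regularization: artifacts enter
# each harmonic multiplicatively through its instant amplitude and leave
# the instant initial phase essentially untouched, so replacing A_i(t) by
# its regression line and phi0_i(t) by its mean strips the artifact while
# keeping the physiology (the heart-rate variability lives in f_i(t)).
# Two reconstructions follow: x_tf keeps the time-varying frequency,
# x_cf rebuilds the waveform at constant heart rate -- the latter is the
# extracted arterial pulse waveform used for harmonic indices.

#' Regression line of a harmonic's instant amplitude
#'
#' Ordinary least squares of `amplitude` on `time` over the valid window.
#'
#' @param track A [harmonic_instant_params()] result.
#' @return One-row tibble with columns `slope` (a.u./s) and `intercept`
#'   (a.u., at t = 0).
#' @export
amplitude_regression <- function(track) {
  d <- track[track$valid, ]
  if (nrow(d) < 10L) {
    stop("fewer than 10 valid samples for the amplitude regression",
         call. = FALSE)
  }
  fit <- stats::lm(amplitude ~ time, data = d)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1])
  )
}

#' Mean instant initial phase of a harmonic
#'
#' Arithmetic mean of the (unwrapped) `phi0` over the valid window.
#' Values are reported unwrapped, so means outside `[-pi, pi]` are
#' expected and meaningful as relative quantities.
#'
#' @param track A [harmonic_instant_params()] result.
#' @return Mean initial phase in rad.
#' @export
phase_mean <- function(track) {
  mean(track$phi0[track$valid])
}

#' Per-harmonic summaries for artifact-free reconstruction
#'
#' @param tracks A list of [harmonic_instant_params()] tracks (one per
#'   harmonic, in order).
#' @return Tibble with one row per harmonic: `harmonic`, `slope`,
#'   `intercept`, `phi_bar`, `a_bar` (mean instant amplitude).
#' @export
harmonic_summaries <- function(tracks) {
  purrr::map_dfr(tracks, function(tr) {
    reg <- amplitude_regression(tr)
    tibble::tibble(
      harmonic = attr(tr, "harmonic"),
      slope = reg$slope,
      intercept = reg$intercept,
      phi_bar = phase_mean(tr),
      a_bar = mean(tr$amplitude[tr$valid])
    )
  })
}

# regression-line amplitude evaluated on the track grid
.amp_line <- function(summary_row, tt) {
  summary_row$intercept + summary_row$slope * tt
}

#' Reconstruct the pulse signal free of motion artifacts
#'
#' `mode = "tf"` rebuilds each harmonic as
#' `A~_i(t) cos(2 pi int f_i dt + phi_bar_i)`, keeping heart-rate
#' variability; the integration constant is anchored so the phase at the
#' valid-window midpoint matches the observed unwrapped phase there
#' (which keeps `x_hvd - x_tf` meaningful instead of being dominated by
#' an arbitrary phase offset).  `mode = "cf"` rebuilds at constant
#' frequency, `A~_i(t) cos(2 pi i f_c t + phi_bar_i)`: the extracted
#' arterial pulse waveform.
#'
#' @param tracks List of [harmonic_instant_params()] tracks.
#' @param summaries Matching [harmonic_summaries()] tibble.
#' @param mode `"tf"` (time-varying frequency) or `"cf"` (constant
#'   frequency).
#' @param f_c Fundamental frequency in Hz (required for `"cf"`).
#' @return Signal tibble (`time`, `value`).
#' @export
reconstruct_pulse <- function(tracks, summaries, mode = c("tf", "cf"),
                              f_c = attr(tracks[[1]], "f_c")) {
  mode <- match.arg(mode)
  stopifnot(length(tracks) == nrow(summaries))
  tt <- tracks[[1]]$time
  rel <- tt - tt[1]
  total <- numeric(length(tt))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    s <- summaries[summaries$harmonic == attr(tr, "harmonic"), ]
    amp <- .amp_line(s, tt)
    if (mode == "cf") {
      arg <- 2 * pi * attr(tr, "harmonic") * f_c * rel + s$phi_bar
    } else {
      cum <- 2 * pi * as.numeric(pracma::cumtrapz(tt, tr$frequency))
      mid <- which(tr$valid)
      mid <- mid[ceiling(length(mid) / 2)]
      obs_phase <- tr$phi0[mid] +
        2 * pi * attr(tr, "harmonic") * f_c * rel[mid]
      arg <- cum - cum[mid] + obs_phase
    }
    total <- total + amp * cos(arg)
  }
  tibble::tibble(time = tt, value = total)
}

#' Estimate the multiplicative artifact distortion
#'
#' The part of the decomposed signal not explained by the regularized
#' reconstruction: `x_tvsp = x_hvd - x_tf`.
#'
#' @param x_hvd,x_tf Signal tibbles on the same grid.
#' @return Signal tibble (`time`, `value`).
#' @export
tvsp_estimate <- function(x_hvd, x_tf) {
  if (nrow(x_hvd) != nrow(x_tf)) {
    stop("`x_hvd` and `x_tf` differ in length", call. = FALSE)
  }
  tibble::tibble(time = x_hvd$time,
                 value = sig_values(x_hvd) - sig_values(x_tf))
}

#' Arterial-pulse-waveform summary of harmonic indices
#'
#' Normalized harmonic amplitudes relative to the first harmonic, by four
#' routes -- mean instant amplitude, FFT peak of the pulse-band signal
#' `x0`, FFT peak of the time-varying reconstruction, FFT peak of the
#' constant-frequency reconstruction -- plus the initial-phase difference
#' `phi_bar_i - phi_bar_1`.  The `x0` route is contaminated by broadband
#' noise, heart-rate variability and artifact distortion; the
#' constant-frequency route is the cleaned waveform index.
#'
#' @param tracks List of harmonic tracks.
#' @param summaries Matching [harmonic_summaries()] tibble.
#' @param x0,x_tf,x_cf Signal tibbles (pulse band, time-varying and
#'   constant-frequency reconstructions).
#' @param f_c Fundamental frequency in Hz.
#' @param bw Band width around each harmonic for the FFT peak search
#'   (default `f_c - 0.2`).
#' @return `apw_summary` tibble with one row per harmonic.
#' @export
apw_summary <- function(tracks, summaries, x0, x_tf, x_cf, f_c,
                        bw = f_c - 0.2) {
  stopifnot(length(tracks) >= 1)
  fs <- sig_fs(x0)
  vw <- tracks[[1]]$valid
  peak_ratios <- function(x) {
    a <- vapply(summaries$harmonic, function(i) {
      fft_peak_amp(x[vw], fs, i * f_c, bw / 2)
    }, numeric(1))
    a / a[1]
  }
  out <- tibble::tibble(
    harmonic = summaries$harmonic,
    a_bar_ratio = summaries$a_bar / summaries$a_bar[1],
    a_x0_ratio = peak_ratios(sig_values(x0, if ("x0" %in% names(x0)) "x0" else "value")),
    a_tf_ratio = peak_ratios(sig_values(x_tf)),
    a_cf_ratio = peak_ratios(sig_values(x_cf)),
    # reported on [0, 2 pi): relative initial phases are circular
    phase_diff = (summaries$phi_bar - summaries$phi_bar[1]) %% (2 * pi)
  )
  class(out) <- c("apw_summary", class(out))
  out
}
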