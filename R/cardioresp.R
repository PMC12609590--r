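# Heart rate, respiration, and the heart-rate-variability partition.
# Each harmonic carries the heart rhythm twice: its instant frequency
# f_i(t) (respiration + other physiological factors + a little artifact
# leakage) and its instant initial phase phi0_i(t) (respiration only,
# nearly artifact-immune).  Extracting the respiration signal from both
# and comparing the resulting heart-rate variability (RMSE about the
# mean) splits total HRV into a respiratory part and a remainder
# attributed to other physiological factors:
#   RMSE(HR_PF) = RMSE(HR) - RMSE(HR_phi).

#' Heart-rate track of a harmonic
#'
#' `HR_i(t) = f_i(t) / i * 60` in beats per minute.
#'
#' @param track A [harmonic_instant_params()] result.
#' @return Tibble with columns `time`, `hr`, `valid`; attribute
#'   `harmonic`.
#' @export
hr_track <- function(track) {
  i <- attr(track, "harmonic")
  out <- tibble::tibble(time = track$time,
                        hr = track$frequency / i * 60,
                        valid = track$valid)
  attr(out, "harmonic") <- i
  out
}

# one-component HVD tuned for the 0.1-0.5 Hz respiration band, run on an
# already-trimmed slow signal.  The signal is band-passed (gentle order-2
# edges keep the 0.05-0.65 Hz band flat) before the analytic signal so
# Hilbert end effects and residual trends do not corrupt the envelope;
# an inner trim guards the remaining ends.
.resp_hvd <- function(x, fs, band, smooth, inner_trim) {
  x <- x - mean(x)
  xb <- bp_vec(x, fs, band[1], band[2], order = 2, pad_s = 20,
               check_len = FALSE)
  z <- analytic_signal(xb)
  b <- Mod(z)
  ph <- as.numeric(signal::unwrap(Arg(z)))
  # the phase derivative spikes wherever the envelope dips; smoothing is
  # therefore envelope-squared weighted, which suppresses those samples
  fr_raw <- numeric_deriv(ph, fs) / (2 * pi)
  w <- b^2
  lp_s <- function(v) lp_vec(v, fs, smooth, order = 2, pad_s = 20,
                             check_len = FALSE)
  fr <- lp_s(w * fr_raw) / pmax(lp_s(w), .Machine$double.eps)
  k <- min(round(inner_trim * fs), floor((length(x) - 2) / 2))
  valid <- seq_along(x) > k & seq_along(x) <= length(x) - k
  alpha <- ph - 2 * pi * as.numeric(pracma::cumtrapz((seq_along(x) - 1) / fs, fr))
  list(r = xb, B = b, f_resp = fr, alpha = alpha, valid = valid)
}

.resp_track <- function(slow, tt, fs, band, smooth, inner_trim, source,
                        harmonic) {
  if (sqrt(mean(slow^2)) < 1e-12) {
    warning("respiration signal below numerical noise; ",
            "returning a zero-amplitude track", call. = FALSE)
    out <- tibble::tibble(time = tt, r = 0, B = 0,
                          f_resp = NA_real_, alpha = NA_real_,
                          valid = TRUE)
  } else {
    h <- .resp_hvd(slow, fs, band, smooth, inner_trim)
    out <- tibble::tibble(time = tt, r = h$r, B = h$B,
                          f_resp = h$f_resp, alpha = h$alpha,
                          valid = h$valid)
  }
  attr(out, "source") <- source
  attr(out, "harmonic") <- harmonic
  class(out) <- c("resp_track", class(out))
  out
}

#' Respiration track from the instant frequency
#'
#' The respiration signal embedded in harmonic `i`'s frequency is
#' `r_f(t) = f_i(t) - i f_c`; one-component HVD with respiration-band
#' settings yields its instant modulation depth `B` (Hz), instant
#' respiration frequency `f_resp`, and instant initial phase `alpha`.
#'
#' @param track A [harmonic_instant_params()] result.
#' @param f_c Fundamental frequency in Hz.
#' @param band Respiration band in Hz (default `c(0.05, 0.65)`).
#' @param smooth Low-pass cutoff for the respiration instantaneous
#'   frequency (default 0.1 Hz).
#' @param inner_trim Additional seconds trimmed at each end of the track
#'   before statistics (default 5).
#' @return A `resp_track` tibble (`time`, `r`, `B`, `f_resp`, `alpha`,
#'   `valid`); attributes `source = "frequency"` and `harmonic`.
#' @export
resp_from_frequency <- function(track, f_c = attr(track, "f_c"),
                                band = c(0.05, 0.65), smooth = 0.1,
                                inner_trim = 5) {
  i <- attr(track, "harmonic")
  d <- track[track$valid, ]
  .resp_track(d$frequency - i * f_c, d$time, attr(track, "fs"),
              band, smooth, inner_trim, "frequency", i)
}

#' Respiration track from the instant initial phase
#'
#' The instant initial phase is itself the respiration signal (in rad),
#' riding on a slowly wandering offset; it is linearly detrended over the
#' valid window and decomposed with the same respiration-band HVD.
#' Because motion artifacts barely touch `phi0`, this source is the more
#' accurate of the two.
#'
#' @inheritParams resp_from_frequency
#' @return A `resp_track` tibble with `source = "phase"` (`B` in rad).
#' @export
resp_from_phase <- function(track, band = c(0.05, 0.65), smooth = 0.1,
                            inner_trim = 5) {
  d <- track[track$valid, ]
  detr <- stats::residuals(stats::lm(d$phi0 ~ d$time))
  .resp_track(as.numeric(detr), d$time, attr(track, "fs"),
              band, smooth, inner_trim, "phase", attr(track, "harmonic"))
}

#' Heart rate accounting for respiration only
#'
#' `HR(t) = (r(t) + f_c) * 60` bpm, applied literally to either
#' respiration source.  For the phase source this adds radians to a
#' frequency before scaling; the convention is dimensionally loose but is
#' the one the heart-rate tables are built on.  `convert = "pm_to_fm"`
#' instead differentiates the phase-source respiration signal
#' (`r'/2 pi`), converting phase modulation into its equivalent frequency
#' modulation before the formula is applied.
#'
#' @param resp A `resp_track`.
#' @param f_c Fundamental frequency in Hz.
#' @param convert `"none"` (literal, default) or `"pm_to_fm"`.
#' @return Tibble with columns `time`, `hr`, `valid`.
#' @export
hr_with_resp <- function(resp, f_c, convert = c("none", "pm_to_fm")) {
  convert <- match.arg(convert)
  r <- resp$r
  if (convert == "pm_to_fm" &&
      identical(attr(resp, "source"), "phase") && length(r) > 2) {
    fs <- sig_fs(resp)
    r <- numeric_deriv(r, fs) / (2 * pi)
  }
  tibble::tibble(time = resp$time, hr = (r + f_c) * 60,
                 valid = resp$valid)
}

# RMS deviation about the series' own mean
rms_about_mean <- function(x) sqrt(mean((x - mean(x))^2))

#' Heart-rate and respiration report with an HRV partition
#'
#' One row per harmonic: mean and RMSE (about the mean) of the total
#' heart-rate track, the frequency-source and phase-source respiration
#' rates (`mean(f_resp) * 60` breaths/min), modulation depths, derived
#' heart rates, and the partition
#' `rmse_hr_pf = rmse_hr - rmse_hr_phi`, which may legitimately be
#' negative when artifacts depress the total-HRV estimate while the
#' respiratory part is large.  All statistics are computed over each
#' respiration track's inner valid window.
#'
#' @param tracks List of [harmonic_instant_params()] tracks.
#' @param resp_f,resp_phi Lists of matching [resp_from_frequency()] and
#'   [resp_from_phase()] tracks.
#' @param f_c Fundamental frequency in Hz.
#' @return An `hrv_report` tibble.
#' @export
hrv_report <- function(tracks, resp_f, resp_phi, f_c) {
  stopifnot(length(tracks) == length(resp_f),
            length(tracks) == length(resp_phi))
  purrr::pmap_dfr(
    list(tracks, resp_f, resp_phi),
    function(tr, rf, rp) {
      i <- attr(tr, "harmonic")
      hr <- hr_track(tr)
      hrf <- hr_with_resp(rf, f_c)
      hrp <- hr_with_resp(rp, f_c)
      # align the total-HR track onto the respiration tracks' grid
      vr <- rf$valid & rp$valid
      hr_sub <- hr$hr[match(round(rf$time[vr], 9), round(hr$time, 9))]
      rmse_hr <- rms_about_mean(hr_sub)
      rmse_hr_phi <- rms_about_mean(hrp$hr[vr])
      tibble::tibble(
        harmonic = i,
        mean_hr = mean(hr_sub),
        rmse_hr = rmse_hr,
        mean_rr_f = mean(rf$f_resp[vr]) * 60,
        mean_b_f = mean(rf$B[vr]),
        mean_hr_f = mean(hrf$hr[vr]),
        mean_rr_phi = mean(rp$f_resp[vr]) * 60,
        mean_b_phi = mean(rp$B[vr]),
        mean_hr_phi = mean(hrp$hr[vr]),
        rmse_hr_phi = rmse_hr_phi,
        rmse_hr_pf = rmse_hr - rmse_hr_phi
      )
    }
  )
}
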