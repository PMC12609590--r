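# Zero-phase Butterworth filtering.  All pipeline filters are 4th-order
# Butterworth applied forward-backward (effective 8th order, zero phase):
# a maximally flat passband keeps the harmonic amplitudes that later become
# waveform indices.  Records are padded by reflection before filtering so
# start-up transients die inside the pad, then cropped.

# odd (point-symmetric) reflection padding keeps the signal continuous at
# the joins; pad_n is clamped to the record length
.reflect_pad <- function(x, pad_n) {
  n <- length(x)
  pad_n <- min(pad_n, n - 1L)
  if (pad_n < 1L) return(list(x = x, pad = 0L))
  head_pad <- 2 * x[1] - x[(pad_n + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad_n)]
  list(x = c(head_pad, x, tail_pad), pad = pad_n)
}

.check_stable <- function(filt) {
  r <- Mod(polyroot(rev(filt$a)))
  if (any(!is.finite(r)) || max(r) >= 1) {
    stop("designed filter is numerically unstable for this band at this ",
         "sampling rate; decimate the record (the pipeline analyses at ",
         "~100 Hz) or widen the band", call. = FALSE)
  }
  invisible(filt)
}

# forward-backward filter a numeric vector with reflection padding
.zp_filter <- function(x, filt, pad_n) {
  p <- .reflect_pad(x, pad_n)
  y <- as.numeric(signal::filter(filt, p$x))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(p$pad + 1L):(p$pad + length(x))]
}

.zp_filter_complex <- function(x, filt, pad_n) {
  complex(
    real = .zp_filter(Re(x), filt, pad_n),
    imaginary = .zp_filter(Im(x), filt, pad_n)
  )
}

# vector-level filters used throughout the package ---------------------------

lp_vec <- function(x, fs, cutoff, order = 4, pad_s = 10,
                   check_len = TRUE) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  if (check_len && length(x) / fs < 6 / cutoff) {
    stop("record too short for a ", cutoff,
         " Hz low-pass filter (needs >= ", signif(6 / cutoff, 3), " s)",
         call. = FALSE)
  }
  filt <- .check_stable(signal::butter(order, cutoff / (fs / 2)))
  .zp_filter(x, filt, round(pad_s * fs))
}

bp_vec <- function(x, fs, f_lo, f_hi, order = 4, pad_s = 10,
                   check_len = TRUE) {
  stopifnot(f_lo > 0, f_lo < f_hi, f_hi < fs / 2)
  if (check_len && length(x) / fs < 6 / (f_hi - f_lo)) {
    stop("record too short for a [", f_lo, ", ", f_hi,
         "] Hz band-pass filter (needs >= ", signif(6 / f_lo, 3), " s)",
         call. = FALSE)
  }
  filt <- .check_stable(
    signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  )
  .zp_filter(x, filt, round(pad_s * fs))
}

# zero-phase FFT low-pass with a raised-cosine transition band ending at
# `cutoff`.  The baseline separator needs a far sharper transition than
# any realizable IIR at these sampling rates: the first pulse harmonic
# sits only 0.4 Hz above the drift cutoff, and a Butterworth that close
# would absorb several percent of the harmonic itself.  Reflection
# padding suppresses the wrap-around edge effects.
lp_fft_vec <- function(x, fs, cutoff, trans = 0.1, pad_s = 10) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  p <- .reflect_pad(x, round(pad_s * fs))
  n <- length(p$x)
  # taper the padded ends to the record mean so the circular (FFT) view
  # of the signal is continuous: an untapered wrap discontinuity rings
  # back into the record through the sharp mask
  if (p$pad > 1L) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(p$pad) - 1) / (p$pad - 1)))
    m <- mean(x)
    w <- c(ramp, rep(1, n - 2L * p$pad), rev(ramp))
    px <- m + (p$x - m) * w
  } else {
    px <- p$x
  }
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  lo <- max(cutoff - trans, 0)
  mask <- ifelse(freq <= lo, 1,
                 ifelse(freq >= cutoff, 0,
                        0.5 * (1 + cos(pi * (freq - lo) / (cutoff - lo)))))
  y <- Re(stats::fft(stats::fft(px) * mask, inverse = TRUE)) / n
  y[(p$pad + 1L):(p$pad + length(x))]
}

#' Zero-phase low-pass filter
#'
#' Filters every value column of a signal tibble with a 4th-order
#' Butterworth low-pass applied forward and backward, so the passband
#' incurs no group delay (pulse landmarks keep their timing).
#'
#' @param data Signal tibble with a `time` column.
#' @param cutoff Cutoff frequency in Hz (0 < cutoff < fs/2).
#' @param order Butterworth order of each pass (default 4).
#' @param pad Reflection-padding length in seconds used to absorb filter
#'   transients before cropping (default 10).
#' @return A tibble of the same shape with filtered value columns.
#' @export
lowpass_zero_phase <- function(data, cutoff, order = 4, pad = 10) {
  fs <- sig_fs(data)
  out <- data
  for (col in sig_value_cols(data)) {
    out[[col]] <- lp_vec(data[[col]], fs, cutoff, order, pad)
  }
  out
}

#' Zero-phase band-pass filter
#'
#' @param data Signal tibble with a `time` column.
#' @param f_lo,f_hi Band edges in Hz (0 < f_lo < f_hi < fs/2).
#' @inheritParams lowpass_zero_phase
#' @return A tibble of the same shape with filtered value columns.
#' @export
bandpass_zero_phase <- function(data, f_lo, f_hi, order = 4, pad = 10) {
  fs <- sig_fs(data)
  out <- data
  for (col in sig_value_cols(data)) {
    out[[col]] <- bp_vec(data[[col]], fs, f_lo, f_hi, order, pad)
  }
  out
}
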