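# Preprocessing front end: a measured record decomposes as
#   x_mea(t) = x0(t) + x_b(t) + x_hf(t)
# with x_hf the >15 Hz noise, x_b the sub-(f_c - 0.4) Hz baseline drift,
# and x0 the pulse-band signal.  The fundamental f_c is read off the FFT
# inside a configurable search band (defaults 0.7-3.0 Hz, i.e. 42-180 bpm,
# covering resting through post-exercise heart rates), and the harmonics
# are separated by zero-phase band-passes at i f_c +/- (f_c - 0.2)/2.

# one-sided amplitude spectrum (rectangular window)
.amp_spectrum <- function(x, fs) {
  n <- length(x)
  half <- seq_len(floor(n / 2) + 1L)
  tibble::tibble(
    freq = (half - 1L) * fs / n,
    amp = Mod(stats::fft(x))[half] * 2 / n
  )
}

# largest spectral amplitude within f0 +/- half_bw
fft_peak_amp <- function(x, fs, f0, half_bw) {
  sp <- .amp_spectrum(x, fs)
  inb <- sp$amp[sp$freq >= f0 - half_bw & sp$freq <= f0 + half_bw]
  if (!length(inb)) return(NA_real_)
  max(inb)
}

#' Estimate the fundamental (heart-rate) frequency
#'
#' Finds the largest FFT magnitude peak inside the search band and refines
#' it by quadratic interpolation of the log-magnitude across the peak bin
#' and its neighbours.  A record shorter than 20 cycles of the lower band
#' edge is rejected: the bin spacing would be too coarse for a reliable
#' estimate.
#'
#' @param data Signal tibble (`time`, `value`).
#' @param search_band Two-element band in Hz to search (default
#'   `c(0.7, 3)`).
#' @return The fundamental frequency in Hz.
#' @export
estimate_fundamental <- function(data, search_band = c(0.7, 3)) {
  fs <- sig_fs(data)
  x <- sig_values(data)
  if (length(x) / fs < 20 / search_band[1]) {
    stop("record too short to estimate the fundamental (need >= ",
         signif(20 / search_band[1], 3), " s)", call. = FALSE)
  }
  sp <- .amp_spectrum(x - mean(x), fs)
  band <- sp$freq >= search_band[1] & sp$freq <= search_band[2]
  amps <- sp$amp[band]
  freqs <- sp$freq[band]
  k <- which.max(amps)
  prominence <- 20 * log10(amps[k] / stats::median(amps))
  if (!is.finite(prominence) || prominence < 3) {
    stop("no fundamental found: strongest in-band peak is not 3 dB above ",
         "the band's median spectrum", call. = FALSE)
  }
  # quadratic interpolation on log magnitude around the peak bin
  kk <- which(sp$freq == freqs[k])
  if (kk > 1L && kk < nrow(sp)) {
    la <- log(pmax(sp$amp[(kk - 1L):(kk + 1L)], .Machine$double.xmin))
    denom <- la[1] - 2 * la[2] + la[3]
    delta <- if (abs(denom) > 0) 0.5 * (la[1] - la[3]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    freqs[k] + delta * fs / length(x)
  } else {
    freqs[k]
  }
}

#' Split a measured record into pulse band and baseline drift
#'
#' Applies the 15 Hz zero-phase low-pass to shed high-frequency noise,
#' estimates the fundamental `f_c`, extracts the baseline drift with a
#' sharp zero-phase low-pass at `f_c - 0.4` Hz (FFT-domain,
#' raised-cosine transition), and returns the pulse-band signal
#' `x0 = (15 Hz-filtered input) - x_b`, so `x0 + xb` reproduces the
#' band-limited input to machine accuracy.
#'
#' @param data Signal tibble (`time`, `value`).
#' @param f_c Optional known fundamental in Hz; estimated when `NULL`.
#' @param hf_cutoff High-frequency cutoff in Hz (default 15).
#' @param baseline_offset The drift cutoff is `f_c - baseline_offset`
#'   (default 0.4 Hz).
#' @param search_band Passed to [estimate_fundamental()].
#' @return A `pulse_preprocess` tibble with columns `time`, `x0`, `xb`;
#'   attributes `f_c` and `fs`.
#' @export
preprocess_pulse <- function(data, f_c = NULL, hf_cutoff = 15,
                             baseline_offset = 0.4,
                             search_band = c(0.7, 3)) {
  fs <- sig_fs(data)
  x <- sig_values(data)
  lp <- if (hf_cutoff < fs / 2) lp_vec(x, fs, hf_cutoff) else x
  if (is.null(f_c)) {
    f_c <- estimate_fundamental(
      tibble::tibble(time = data$time, value = lp), search_band
    )
  }
  drift_cut <- f_c - baseline_offset
  if (drift_cut <= 0.1) {
    stop("baseline cutoff f_c - ", baseline_offset, " = ",
         signif(drift_cut, 3), " Hz is too low to realize", call. = FALSE)
  }
  # sharp zero-phase separator: the fundamental is only `baseline_offset`
  # above this cutoff, so the transition must be much narrower than any
  # realizable IIR allows
  xb <- lp_fft_vec(lp, fs, drift_cut)
  out <- tibble::tibble(time = data$time, x0 = lp - xb, xb = xb)
  attr(out, "f_c") <- f_c
  attr(out, "fs") <- fs
  class(out) <- c("pulse_preprocess", class(out))
  out
}

#' Separate the pulse harmonics by band-pass filtering
#'
#' Harmonic `i` is the zero-phase band-pass of the pulse-band signal over
#' `i f_c +/- BW/2` with `BW = f_c - bw_offset`; the band-width rule keeps
#' neighbouring harmonics (spaced `f_c` apart) out of each band.
#'
#' @param data A [preprocess_pulse()] result, or any tibble with `time`
#'   and `x0` (or `value`) columns.
#' @param f_c Fundamental frequency in Hz (taken from the preprocess
#'   attribute when present).
#' @param n Number of harmonics to separate.
#' @param bw_offset Band-width rule offset in Hz (default 0.2).
#' @param hf_cutoff All bands must sit below this frequency (default 15).
#' @return Long tibble with columns `time`, `harmonic`, `value`;
#'   attributes `f_c` and `bw`.
#' @export
split_harmonics <- function(data, f_c = attr(data, "f_c"), n = 5,
                            bw_offset = 0.2, hf_cutoff = 15) {
  fs <- sig_fs(data)
  x <- if ("x0" %in% names(data)) data$x0 else sig_values(data)
  if (is.null(f_c)) stop("`f_c` is required", call. = FALSE)
  if (f_c <= bw_offset) {
    stop("band-width rule needs f_c > ", bw_offset, " Hz", call. = FALSE)
  }
  bw <- f_c - bw_offset
  limit <- min(hf_cutoff, fs / 2)
  n_max <- floor((limit - bw / 2) / f_c)
  if (n > n_max) {
    stop("n = ", n, " harmonics exceed the ", limit,
         " Hz band limit at f_c = ", signif(f_c, 4),
         " Hz; the maximum admissible n is ", n_max, call. = FALSE)
  }
  out <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      time = data$time,
      harmonic = i,
      value = bp_vec(x, fs, i * f_c - bw / 2, i * f_c + bw / 2)
    )
  })
  attr(out, "f_c") <- f_c
  attr(out, "bw") <- bw
  out
}
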