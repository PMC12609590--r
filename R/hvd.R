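# Hilbert vibration decomposition (HVD).  The analytic signal provides a
# raw envelope and unwrapped phase; HVD iterates: smooth the instantaneous
# frequency, synchronously demodulate to recover a slow complex envelope,
# refine, and reconstruct the component.  Because the demodulation
# low-pass also rejects everything off-carrier, broadband noise is
# strongly alleviated in the extracted component, and the per-harmonic
# instant amplitude A_i(t), instant frequency f_i(t) and instant initial
# phase phi0_i(t) come out directly.
#
# The Hilbert transform is unreliable near the record ends; every
# downstream statistic therefore works on a trimmed "valid" window.

# analytic signal via the frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Envelope and unwrapped phase of the analytic signal
#'
#' The raw substrate of HVD: for a band-limited input, the analytic
#' signal's modulus is the instant amplitude and the derivative of its
#' unwrapped phase the instant angular frequency.
#'
#' @param data Signal tibble (`time`, `value`), already band-limited.
#' @return Tibble with columns `time`, `amplitude`, `phase` (rad,
#'   continuous/unwrapped).
#' @export
analytic_tracks <- function(data) {
  x <- sig_values(data)
  if (all(x == 0)) stop("input signal is identically zero", call. = FALSE)
  z <- analytic_signal(x)
  tibble::tibble(
    time = data$time,
    amplitude = Mod(z),
    phase = as.numeric(signal::unwrap(Arg(z)))
  )
}

# one HVD component: smoothed IF -> synchronous demodulation -> refine.
# Returns amplitude, instantaneous frequency, total unwrapped phase and
# the reconstructed component, all on the full grid.
.hvd_component <- function(x, fs, cutoff, n_iter) {
  tt <- (seq_along(x) - 1) / fs
  z <- analytic_signal(x)
  ph <- as.numeric(signal::unwrap(Arg(z)))
  fi <- lp_vec(numeric_deriv(ph, fs) / (2 * pi), fs, cutoff)
  demod <- function(fi) {
    theta <- 2 * pi * as.numeric(pracma::cumtrapz(tt, fi))
    s <- .zp_filter_complex(
      x * exp(-1i * theta),
      .check_stable(signal::butter(4, cutoff / (fs / 2))),
      round(10 * fs)
    )
    list(theta = theta, s = s,
         delta = as.numeric(signal::unwrap(Arg(s))))
  }
  for (j in seq_len(n_iter)) {
    d <- demod(fi)
    fi <- fi + lp_vec(numeric_deriv(d$delta, fs) / (2 * pi), fs, cutoff)
  }
  d <- demod(fi)
  phase <- d$theta + d$delta
  list(
    amplitude = 2 * Mod(d$s),
    frequency = lp_vec(numeric_deriv(phase, fs) / (2 * pi), fs, cutoff),
    phase = phase,
    component = 2 * Re(d$s * exp(1i * d$theta))
  )
}

#' Iterative Hilbert vibration decomposition
#'
#' Extracts `n_components` quasi-harmonic components one at a time: the
#' smoothed instantaneous frequency of the residual locks onto its
#' dominant component, synchronous demodulation recovers that component's
#' slow envelope and residual phase, the reconstruction is subtracted,
#' and the process repeats.  Components are returned ordered by energy.
#' If subtracting a component fails to reduce the residual energy the
#' iteration stops with a warning.
#'
#' @param data Signal tibble (`time`, `value`).
#' @param n_components Number of components to extract (>= 1).
#' @param freq_smooth_cutoff Low-pass cutoff in Hz applied to the
#'   instantaneous frequency and to the demodulated envelope (default
#'   0.6 Hz, wide enough to pass the 0.1-0.5 Hz respiration band).
#' @param n_iter Frequency-refinement iterations per component
#'   (default 2).
#' @return Long tibble with columns `time`, `component` (energy rank),
#'   `value` (the reconstruction), `amplitude`, `frequency`, `phase`.
#' @export
hvd_extract <- function(data, n_components = 1, freq_smooth_cutoff = 0.6,
                        n_iter = 2) {
  stopifnot(n_components >= 1)
  fs <- sig_fs(data)
  x <- sig_values(data)
  if (all(x == 0)) stop("input signal is identically zero", call. = FALSE)
  res <- x
  comps <- list()
  for (k in seq_len(n_components)) {
    cmp <- .hvd_component(res, fs, freq_smooth_cutoff, n_iter)
    new_res <- res - cmp$component
    if (sum(new_res^2) > sum(res^2)) {
      warning("residual energy increased at component ", k,
              "; stopping extraction", call. = FALSE)
      break
    }
    comps[[k]] <- cmp
    res <- new_res
  }
  if (!length(comps)) {
    stop("no component could be extracted", call. = FALSE)
  }
  energy <- vapply(comps, function(cmp) sum(cmp$component^2), numeric(1))
  ord <- order(energy, decreasing = TRUE)
  purrr::imap_dfr(comps[ord], function(cmp, rank) {
    tibble::tibble(
      time = data$time, component = rank, value = cmp$component,
      amplitude = cmp$amplitude, frequency = cmp$frequency,
      phase = cmp$phase
    )
  })
}

#' Instant parameters of one separated harmonic
#'
#' Runs one-component HVD on a band-passed harmonic and expresses its
#' phase two ways: the instant frequency `f(t)` (smoothed phase
#' derivative / 2 pi) carries respiration as frequency modulation, while
#' the instant initial phase `phi0(t) = phase - 2 pi i f_c t` (referenced
#' to the constant-heart-rate ramp) carries it as phase modulation.  The
#' phase reference is what makes `phi0` nearly immune to motion
#' artifacts, which enter multiplicatively through the amplitude.
#'
#' @param data One harmonic from [split_harmonics()] (tibble `time`,
#'   `value`), or a long tibble filtered to one harmonic.
#' @param i Harmonic order.
#' @param f_c Fundamental frequency in Hz.
#' @param trim Seconds discarded at each end for the valid window
#'   (default `max(3 / f_c, 5)`; the Hilbert end effects and the
#'   zero-phase smoothing transients both die inside it).
#' @param freq_smooth_cutoff,n_iter Passed to the HVD core.
#' @return A `harmonic_track` tibble with columns `time`, `amplitude`,
#'   `frequency`, `phi0`, `component`, `valid` (logical window);
#'   attributes `harmonic`, `f_c`, `fs`.
#' @export
harmonic_instant_params <- function(data, i, f_c,
                                    trim = NULL,
                                    freq_smooth_cutoff = 0.6,
                                    n_iter = 2) {
  fs <- sig_fs(data)
  x <- sig_values(data)
  tt <- data$time
  if (is.null(trim)) trim <- max(3 / f_c, 5)
  dur <- (length(x) - 1) / fs
  if (2 * trim >= dur) {
    stop("trim of ", trim, " s per end exceeds half the ",
         signif(dur, 4), " s record", call. = FALSE)
  }
  cmp <- .hvd_component(x, fs, freq_smooth_cutoff, n_iter)
  rel <- tt - tt[1]
  valid <- rel >= trim & rel <= (dur - trim)
  phi0 <- cmp$phase - 2 * pi * i * f_c * rel
  # end effects can slip whole turns into the unwrapped phase before the
  # valid window opens; re-anchor so the in-window median lies in (-pi, pi]
  phi0 <- phi0 - 2 * pi * round(stats::median(phi0[valid]) / (2 * pi))
  out <- tibble::tibble(
    time = tt,
    amplitude = cmp$amplitude,
    frequency = cmp$frequency,
    phi0 = phi0,
    component = cmp$component,
    valid = valid
  )
  attr(out, "harmonic") <- i
  attr(out, "f_c") <- f_c
  attr(out, "fs") <- fs
  class(out) <- c("harmonic_track", class(out))
  out
}
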