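# broom-style accessors for the fitted analysis object.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pulse analysis
#'
#' @param x A `pulse_analysis`.
#' @param what Which table to return: `"hrv"` (default), `"apw"`,
#'   `"summaries"`, `"tracks"` (long instant-parameter tibble), `"snr"`,
#'   or `"recon"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pulse_analysis <- function(x, what = c("hrv", "apw", "summaries",
                                            "tracks", "snr", "recon"),
                                ...) {
  what <- match.arg(what)
  tibble::as_tibble(x[[what]])
}

#' One-row summary of a pulse analysis
#'
#' @param x A `pulse_analysis`.
#' @param ... Unused.
#' @return One-row tibble: record length, sampling rate, fundamental,
#'   number of harmonics, first-harmonic heart rate, phase-source
#'   respiration rate and modulation, and the HRV partition.
#' @export
glance.pulse_analysis <- function(x, ...) {
  tibble::tibble(
    duration_s = nrow(x$record) / x$fs,
    fs = x$fs,
    f_c = x$f_c,
    n_harmonics = max(x$summaries$harmonic),
    mean_hr_bpm = x$hrv$mean_hr[1],
    mean_rr_phi_bpm = x$hrv$mean_rr_phi[1],
    mean_b_phi = x$hrv$mean_b_phi[1],
    rmse_hr_bpm = x$hrv$rmse_hr[1],
    rmse_hr_phi_bpm = x$hrv$rmse_hr_phi[1],
    rmse_hr_pf_bpm = x$hrv$rmse_hr_pf[1]
  )
}
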