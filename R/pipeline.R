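# End-to-end analysis: 15 Hz low-pass -> fundamental -> baseline removal
# -> per-harmonic band-pass -> HVD instant parameters -> regression/mean
# summaries -> artifact-free reconstructions -> waveform, heart-rate and
# respiration reports.  Deterministic given record + config: no stage
# consumes randomness.

#' Analysis configuration
#'
#' All tunable parameters of the pipeline in one list.  Defaults follow
#' the method's printed rules (15 Hz high-frequency cutoff, baseline
#' cutoff `f_c - 0.4`, band width `f_c - 0.2`) and the package's own
#' numerical choices (0.6 Hz instant-frequency smoothing so the
#' respiration band survives; end trim `max(3/f_c, 5)` s).
#'
#' @param n_harmonics Number of harmonics to analyse (default 5; reduced
#'   automatically, with a message, when the band limit allows fewer).
#' @param hf_cutoff High-frequency cutoff in Hz.
#' @param baseline_offset Baseline cutoff is `f_c - baseline_offset` Hz.
#' @param bw_offset Harmonic band width is `f_c - bw_offset` Hz.
#' @param search_band Fundamental search band in Hz.
#' @param freq_smooth_cutoff Instant-frequency smoothing cutoff in Hz.
#' @param n_iterations HVD refinement iterations per component.
#' @param trim End trim in seconds (`NULL` = `max(3/f_c, 5)`).
#' @param resp_band,resp_smooth_cutoff,resp_trim Respiration-band HVD
#'   settings (Hz, Hz, s).
#' @param f_c Optional known fundamental, skipping estimation.
#' @return An `sdoftf_config` list.
#' @export
analysis_config <- function(n_harmonics = 5, hf_cutoff = 15,
                            baseline_offset = 0.4, bw_offset = 0.2,
                            search_band = c(0.7, 3),
                            freq_smooth_cutoff = 0.6, n_iterations = 2,
                            trim = NULL, resp_band = c(0.05, 0.65),
                            resp_smooth_cutoff = 0.1, resp_trim = 5,
                            f_c = NULL) {
  structure(
    list(
      n_harmonics = n_harmonics, hf_cutoff = hf_cutoff,
      baseline_offset = baseline_offset, bw_offset = bw_offset,
      search_band = search_band,
      freq_smooth_cutoff = freq_smooth_cutoff,
      n_iterations = n_iterations, trim = trim,
      resp_band = resp_band, resp_smooth_cutoff = resp_smooth_cutoff,
      resp_trim = resp_trim, f_c = f_c
    ),
    class = "sdoftf_config"
  )
}

#' Run the full artifact-removal analysis on one record
#'
#' @param data Signal tibble (`time`, `value`), e.g. from
#'   [read_signal()], [synth_pulse()] or a simulated bundle's `measured`
#'   column.
#' @param config An [analysis_config()].
#' @return A `pulse_analysis` object: a list with the preprocessed
#'   signals (`prep`), per-harmonic instant-parameter `tracks` (long
#'   tibble) and `summaries`, the reconstructions (`recon`: `x0`,
#'   `x_hvd`, `x_tf`, `x_cf`, `x_tvsp`), the waveform summary (`apw`),
#'   respiration tracks (`resp`), the heart-rate/respiration report
#'   (`hrv`), per-harmonic spectral SNR (`snr`), `f_c` and the `config`.
#' @examples
#' \donttest{
#' spec <- pulse_spec(amplitudes = c(1, 0.5, 0.25),
#'                    resp_amplitude = 0.3, resp_rate = 0.2)
#' fit <- run_analysis(synth_pulse(spec),
#'                     analysis_config(n_harmonics = 3))
#' glance(fit)
#' }
#' @export
run_analysis <- function(data, config = analysis_config()) {
  stopifnot(inherits(config, "sdoftf_config"))
  fs <- sig_fs(data)
  if (nrow(data) / fs < 40) {
    stop("record shorter than 40 s: too few respiration cycles to ",
         "analyse", call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  prep <- stage("preprocess", preprocess_pulse(
    data[c("time", setdiff(names(data), "time")[1])] |>
      stats::setNames(c("time", "value")),
    f_c = config$f_c, hf_cutoff = config$hf_cutoff,
    baseline_offset = config$baseline_offset,
    search_band = config$search_band
  ))
  f_c <- attr(prep, "f_c")

  bw <- f_c - config$bw_offset
  n_max <- floor((min(config$hf_cutoff, fs / 2) - bw / 2) / f_c)
  n <- config$n_harmonics
  if (n > n_max) {
    message("reducing n_harmonics from ", n, " to ", n_max,
            " (band limit at f_c = ", signif(f_c, 4), " Hz)")
    n <- n_max
  }
  harmonics <- stage("split_harmonics", split_harmonics(
    prep, f_c = f_c, n = n, bw_offset = config$bw_offset,
    hf_cutoff = config$hf_cutoff
  ))

  tracks <- stage("instant_params", purrr::map(seq_len(n), function(i) {
    harmonic_instant_params(
      harmonics[harmonics$harmonic == i, c("time", "value")],
      i = i, f_c = f_c, trim = config$trim,
      freq_smooth_cutoff = config$freq_smooth_cutoff,
      n_iter = config$n_iterations
    )
  }))
  summaries <- stage("summaries", harmonic_summaries(tracks))

  x_hvd <- tibble::tibble(
    time = tracks[[1]]$time,
    value = Reduce(`+`, purrr::map(tracks, "component"))
  )
  x_tf <- stage("reconstruct",
                reconstruct_pulse(tracks, summaries, "tf", f_c))
  x_cf <- stage("reconstruct",
                reconstruct_pulse(tracks, summaries, "cf", f_c))
  x_tvsp <- tvsp_estimate(x_hvd, x_tf)
  recon <- tibble::tibble(
    time = prep$time, x0 = prep$x0, x_hvd = x_hvd$value,
    x_tf = x_tf$value, x_cf = x_cf$value, x_tvsp = x_tvsp$value
  )

  apw <- stage("apw_summary",
               apw_summary(tracks, summaries, prep, x_tf, x_cf, f_c,
                           bw = bw))

  resp_f <- stage("respiration", purrr::map(
    tracks, resp_from_frequency, f_c = f_c, band = config$resp_band,
    smooth = config$resp_smooth_cutoff, inner_trim = config$resp_trim
  ))
  resp_phi <- stage("respiration", purrr::map(
    tracks, resp_from_phase, band = config$resp_band,
    smooth = config$resp_smooth_cutoff, inner_trim = config$resp_trim
  ))
  hrv <- stage("hrv_report", hrv_report(tracks, resp_f, resp_phi, f_c))

  # per-harmonic spectral SNR: in-band peak over the off-band median, to
  # justify how many harmonics deserve analysis
  snr <- purrr::map_dfr(seq_len(n), function(i) {
    sp <- .amp_spectrum(prep$x0 - mean(prep$x0), fs)
    inb <- sp$freq >= i * f_c - bw / 2 & sp$freq <= i * f_c + bw / 2
    tibble::tibble(
      harmonic = i,
      snr_db = 20 * log10(max(sp$amp[inb]) /
                            stats::median(sp$amp[sp$freq > 0.5 &
                                                   sp$freq < config$hf_cutoff]))
    )
  })

  structure(
    list(
      record = data, fs = fs, f_c = f_c, prep = prep,
      harmonics = harmonics,
      tracks = purrr::map_dfr(tracks, function(tr) {
        dplyr::mutate(tibble::as_tibble(tr),
                      harmonic = attr(tr, "harmonic"),
                      .before = 1)
      }),
      track_list = tracks, summaries = summaries, recon = recon,
      apw = apw, resp_f = resp_f, resp_phi = resp_phi, hrv = hrv,
      snr = snr, config = config
    ),
    class = "pulse_analysis"
  )
}

#' @export
print.pulse_analysis <- function(x, ...) {
  cat("<pulse_analysis>\n")
  cat("  record:   ", nrow(x$record), " samples @ ", x$fs, " Hz (",
      signif(nrow(x$record) / x$fs, 4), " s)\n", sep = "")
  cat("  f_c:      ", signif(x$f_c, 4), " Hz (",
      signif(x$f_c * 60, 4), " bpm)\n", sep = "")
  cat("  harmonics:", max(x$summaries$harmonic), "\n")
  cat("  mean HR:  ", signif(x$hrv$mean_hr[1], 4), " bpm;  total HRV ",
      signif(x$hrv$rmse_hr[1], 3), " bpm;  respiratory HRV ",
      signif(x$hrv$rmse_hr_phi[1], 3), " bpm (harmonic 1)\n", sep = "")
  cat("  RR (phase source, harmonic 1): ",
      signif(x$hrv$mean_rr_phi[1], 4), " breaths/min\n", sep = "")
  invisible(x)
}
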