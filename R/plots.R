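# Quick-look ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated measurement bundle
#'
#' Faceted traces of the measured signal, the clean and
#' drifting-parameter responses, the multiplicative distortion and the
#' baseline.
#'
#' @param object An `sdof_bundle` from [simulate_measurement()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdof_bundle <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "series")
  long$series <- factor(long$series,
                        levels = c("measured", "x_c", "x_m", "x_tvsp",
                                   "baseline"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste0("simulated ", attr(object, "sensor_kind"),
                                 " measurement"))
}

#' Plot a pulse analysis
#'
#' @param object A `pulse_analysis`.
#' @param type `"recon"` (default): pulse-band signal and
#'   reconstructions; `"tracks"`: per-harmonic instant parameters;
#'   `"hr"`: heart-rate tracks; `"resp"`: respiration tracks from both
#'   sources.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pulse_analysis <- function(object,
                                    type = c("recon", "tracks", "hr",
                                             "resp"),
                                    ...) {
  type <- match.arg(type)
  if (type == "recon") {
    long <- tidyr::pivot_longer(object$recon, -"time", names_to = "series")
    return(
      ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                         colour = .data$series)) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)",
                      colour = NULL)
    )
  }
  if (type == "tracks") {
    long <- tidyr::pivot_longer(
      dplyr::filter(object$tracks, .data$valid),
      c("amplitude", "frequency", "phi0"),
      names_to = "parameter"
    )
    return(
      ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                         colour = factor(.data$harmonic))) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::facet_wrap(~parameter, ncol = 1, scales = "free_y") +
        ggplot2::labs(x = "time (s)", y = NULL, colour = "harmonic")
    )
  }
  if (type == "hr") {
    hr <- purrr::map_dfr(object$track_list, function(tr) {
      h <- hr_track(tr)
      dplyr::mutate(h[h$valid, ], harmonic = attr(h, "harmonic"))
    })
    return(
      ggplot2::ggplot(hr, ggplot2::aes(.data$time, .data$hr,
                                       colour = factor(.data$harmonic))) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::labs(x = "time (s)", y = "heart rate (bpm)",
                      colour = "harmonic")
    )
  }
  resp <- purrr::map_dfr(c(object$resp_f, object$resp_phi), function(r) {
    dplyr::mutate(r[r$valid, c("time", "r")],
                  harmonic = attr(r, "harmonic"),
                  source = attr(r, "source"))
  })
  ggplot2::ggplot(resp, ggplot2::aes(.data$time, .data$r,
                                     colour = factor(.data$harmonic))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~source, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "respiration signal",
                  colour = "harmonic")
}
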