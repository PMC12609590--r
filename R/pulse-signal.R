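# Uniformly sampled signals are plain tibbles with a `time` column (seconds)
# and one or more value columns.  Helpers here build them and recover the
# sampling rate, enforcing uniform sampling throughout the package.

#' Build a uniformly sampled pulse signal
#'
#' Every waveform in sdoftf travels as a tibble with a `time` column in
#' seconds and a `value` column.  `pulse_signal()` builds one from a value
#' vector and either a sampling rate or an explicit time vector.
#'
#' @param value Numeric vector of samples.
#' @param fs Sampling rate in Hz. Ignored when `time` is given.
#' @param time Optional time vector in seconds; must be uniformly spaced.
#' @return A tibble with columns `time` and `value`.
#' @examples
#' pulse_signal(sin(2 * pi * 1.2 * seq(0, 10, by = 0.01)), fs = 100)
#' @export
pulse_signal <- function(value, fs = NULL, time = NULL) {
  if (!is.numeric(value) || !all(is.finite(value))) {
    stop("`value` must be a finite numeric vector", call. = FALSE)
  }
  if (is.null(time)) {
    if (is.null(fs) || !is.numeric(fs) || fs <= 0) {
      stop("supply a positive sampling rate `fs` or a `time` vector",
           call. = FALSE)
    }
    time <- (seq_along(value) - 1L) / fs
  }
  out <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  sig_fs(out)  # validates uniform spacing
  out
}

#' Sampling rate of a signal tibble
#'
#' Recovers the sampling rate from the `time` column and errors when the
#' time stamps are not uniform (tolerance: 1 % of the median step).
#'
#' @param data Tibble with a `time` column.
#' @return Sampling rate in Hz.
#' @export
sig_fs <- function(data) {
  tt <- sig_time(data)
  if (length(tt) < 2L) stop("signal needs at least two samples", call. = FALSE)
  dt <- diff(tt)
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > 0.01 * step)) {
    stop("time stamps are not uniformly sampled ",
         "(deviation exceeds 1% of the median step)", call. = FALSE)
  }
  1 / step
}

sig_time <- function(data) {
  if (!is.data.frame(data) || !"time" %in% names(data)) {
    stop("expected a data frame with a `time` column", call. = FALSE)
  }
  data$time
}

sig_values <- function(data, col = "value") {
  if (!col %in% names(data)) {
    stop("expected a `", col, "` column", call. = FALSE)
  }
  v <- data[[col]]
  if (!is.numeric(v)) stop("`", col, "` must be numeric", call. = FALSE)
  v
}

# value columns = every numeric column except time
sig_value_cols <- function(data) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))], "time")
}

#' Crop a signal to a time segment
#'
#' Keeps samples with `start <= time < end` (half-open, so an 80 s segment
#' at 100 Hz yields exactly 8000 samples).
#'
#' @param data Signal tibble.
#' @param start,end Segment bounds in seconds.
#' @return The cropped tibble.
#' @export
crop_signal <- function(data, start, end) {
  out <- dplyr::filter(data, .data$time >= start, .data$time < end)
  if (nrow(out) == 0L) {
    stop("segment [", start, ", ", end, ") contains no samples", call. = FALSE)
  }
  out
}

# numerical derivative on the signal grid (central differences)
numeric_deriv <- function(x, fs) {
  pracma::gradient(x, 1 / fs)
}
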