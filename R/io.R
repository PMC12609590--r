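# Record readers.  CSV is the package's native interchange format
# (two columns time_s,value, or one value column plus an explicit
# sampling rate).  A minimal WFDB reader covers the header plus signal
# formats 16, 212 and 80, enough for the common public pulse-waveform
# distributions (e.g. MIMIC PERform AF, BIDMC, PPG_DaLiA); channel names
# and sampling rates vary by distribution, so the channel is always
# user-specified rather than hard-coded.

#' Read a pulse record from CSV
#'
#' Accepts two-column files (`time_s`, `value`; any header) or one-column
#' files with `fs` supplied.  Non-uniform time stamps are rejected
#' (tolerance 1 % of the median step).
#'
#' @param path File path.
#' @param fs Sampling rate in Hz, required for one-column files.
#' @param segment Optional `c(start, end)` in seconds, applied at load
#'   (half-open).
#' @return A signal tibble (`time`, `value`) with attribute `label`.
#' @export
read_pulse_csv <- function(path, fs = NULL, segment = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[-+0-9.eE, \t]+$", first)
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) >= 2L) {
    out <- tibble::tibble(time = as.numeric(df[[1]]),
                          value = as.numeric(df[[2]]))
  } else {
    if (is.null(fs)) {
      stop("one-column CSV needs an explicit sampling rate `fs`",
           call. = FALSE)
    }
    out <- pulse_signal(as.numeric(df[[1]]), fs = fs)
  }
  if (any(!is.finite(out$value))) {
    stop("record contains non-finite values", call. = FALSE)
  }
  sig_fs(out)
  if (!is.null(segment)) out <- crop_signal(out, segment[1], segment[2])
  attr(out, "label") <- basename(path)
  out
}

#' Write a signal tibble as two-column CSV
#'
#' @param data Signal tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(data, path) {
  # %.17g keeps doubles exact, so write -> read round trips bitwise
  writeLines(
    c("time_s,value",
      paste(sprintf("%.17g", data$time),
            sprintf("%.17g", sig_values(data)), sep = ",")),
    path
  )
  invisible(path)
}

# parse a WFDB header file: "record nsig fs [nsamp]" + one line per signal
.parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(lines[2:(1 + nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- sub("x.*$", "", f[2])
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else NA_real_
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], format = fmt, gain = ifelse(gain == 0, 200, gain),
         baseline = ifelse(is.na(baseline), adczero, baseline),
         desc = desc)
  })
  list(record = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

# decode an interleaved WFDB .dat file into an nsig-column matrix of raw
# ADC units; supports formats 16 (int16 LE), 80 (uint8 offset), 212
# (packed pairs of 12-bit samples)
.read_wfdb_dat <- function(dat_path, fmt, nsig) {
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  adc <- switch(
    fmt,
    "16" = readBin(raw, "integer", n = length(raw) / 2, size = 2,
                   signed = TRUE, endian = "little"),
    "80" = as.integer(raw) - 128L,
    "212" = {
      n_triplets <- floor(length(raw) / 3)
      b <- matrix(as.integer(raw[seq_len(3 * n_triplets)]), nrow = 3)
      s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 15L), 8)
      s2 <- b[3, ] + bitwShiftL(bitwShiftR(b[2, ], 4L), 8)
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      as.vector(rbind(s1, s2))
    },
    stop("unsupported WFDB signal format: ", fmt, call. = FALSE)
  )
  n <- floor(length(adc) / nsig) * nsig
  matrix(adc[seq_len(n)], ncol = nsig, byrow = TRUE)
}

#' Read one channel of a WFDB record
#'
#' Minimal reader for WFDB header files plus signal formats 16, 212 and
#' 80 (single `.dat`, interleaved).  Values are returned in physical
#' units, `(adc - baseline) / gain`.
#'
#' @param record Path to the record base name or its `.hea` file.
#' @param channel Channel name (matched against the signal descriptions,
#'   case-insensitive substring) or 1-based index.  Required when the
#'   record has more than one signal.
#' @param segment Optional `c(start, end)` in seconds (half-open).
#' @return A signal tibble (`time`, `value`) with attribute `label`.
#' @export
read_pulse_wfdb <- function(record, channel = NULL, segment = NULL) {
  base <- sub("\\.hea$", "", record)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  h <- .parse_wfdb_header(hea)
  idx <- if (is.null(channel)) {
    if (h$nsig > 1) {
      stop("record has ", h$nsig, " signals (",
           paste(vapply(h$signals, `[[`, "", "desc"), collapse = ", "),
           "); name a `channel`", call. = FALSE)
    }
    1L
  } else if (is.numeric(channel)) {
    as.integer(channel)
  } else {
    hit <- which(vapply(h$signals, function(s) {
      grepl(tolower(channel), tolower(s$desc), fixed = TRUE)
    }, logical(1)))
    if (!length(hit)) {
      stop("channel '", channel, "' not found among: ",
           paste(vapply(h$signals, `[[`, "", "desc"), collapse = ", "),
           call. = FALSE)
    }
    hit[1]
  }
  if (idx < 1 || idx > h$nsig) stop("channel index out of range", call. = FALSE)
  fmts <- unique(vapply(h$signals, `[[`, "", "format"))
  if (length(fmts) != 1) {
    stop("mixed signal formats are not supported", call. = FALSE)
  }
  dat <- file.path(dirname(hea), h$signals[[idx]]$file)
  adc <- .read_wfdb_dat(dat, fmts, h$nsig)[, idx]
  sig <- h$signals[[idx]]
  out <- pulse_signal((adc - sig$baseline) / sig$gain, fs = h$fs)
  if (!is.null(segment)) out <- crop_signal(out, segment[1], segment[2])
  attr(out, "label") <- paste0(basename(base), ":", sig$desc)
  out
}

#' Read a pulse record (format dispatch)
#'
#' @param path CSV file or WFDB record base name / `.hea` path.
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @param channel WFDB channel (see [read_pulse_wfdb()]).
#' @param fs Sampling rate for one-column CSV.
#' @param segment Optional `c(start, end)` in seconds.
#' @return A signal tibble (`time`, `value`).
#' @export
read_signal <- function(path, format = c("auto", "csv", "wfdb"),
                        channel = NULL, fs = NULL, segment = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format,
         csv = read_pulse_csv(path, fs = fs, segment = segment),
         wfdb = read_pulse_wfdb(path, channel = channel, segment = segment))
}
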