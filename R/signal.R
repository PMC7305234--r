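#' Single-channel EEG signal
#'
#' Lightweight container for a regularly sampled single-channel voltage trace.
#' Time of sample `i` (1-based) is `start_time + (i - 1) / fs` seconds; sample
#' `i` covers the half-open interval `[(i-1)/fs, i/fs)` relative to
#' `start_time`.
#'
#' @param samples Numeric vector of voltages (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Offset of the first sample in seconds from recording
#'   start. Default 0.
#'
#' @return An object of class `eeg_signal`: a list with elements `samples`,
#'   `fs` and `start_time`.
#' @examples
#' s <- eeg_signal(sin(2 * pi * 13 * seq(0, 1, by = 0.01)), fs = 100)
#' s
#' @export
eeg_signal <- function(samples, fs, start_time = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  if (anyNA(samples)) stop("`samples` must not contain NA.", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs), start_time = as.numeric(start_time)),
    class = "eeg_signal"
  )
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf(
    "<eeg_signal> %d samples @ %g Hz (%.2f s), start %.3f s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs, x$start_time
  ))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param signal An [eeg_signal()].
#' @return Length of the signal in seconds.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "eeg_signal"))
  length(signal$samples) / signal$fs
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.eeg_signal <- function(x, ...) {
  tibble::tibble(
    time_s = x$start_time + (seq_along(x$samples) - 1) / x$fs,
    value_uv = x$samples
  )
}

#' Read / write a plain-text sampled signal
#'
#' The plain-text dialect is one voltage value per line preceded by a single
#' header line `fs=<Hz>` (and optionally `start=<s>`). It exists so that small
#' EEG excerpts can be exchanged without EDF tooling.
#'
#' @param path File path.
#' @return [read_signal_csv()] returns an [eeg_signal()];
#'   [write_signal_csv()] returns `path` invisibly.
#' @export
read_signal_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^fs=", lines[[1]])) {
    stop("signal file must start with a header line 'fs=<Hz>': ", path, call. = FALSE)
  }
  fs <- as.numeric(sub("^fs=", "", lines[[1]]))
  start <- 0
  body <- lines[-1]
  if (length(body) > 0 && grepl("^start=", body[[1]])) {
    start <- as.numeric(sub("^start=", "", body[[1]]))
    body <- body[-1]
  }
  vals <- as.numeric(body[nzchar(body)])
  if (anyNA(vals)) stop("non-numeric sample value in ", path, call. = FALSE)
  eeg_signal(vals, fs = fs, start_time = start)
}

#' @param signal An [eeg_signal()] to serialize.
#' @rdname read_signal_csv
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "eeg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%.10g", signal$fs), con)
  if (signal$start_time != 0) writeLines(sprintf("start=%.10g", signal$start_time), con)
  writeLines(format(signal$samples, digits = 10, scientific = FALSE, trim = TRUE), con)
  invisible(path)
}

# slice samples covering [from_s, to_s) (recording-time seconds, half-open)
signal_slice <- function(signal, from_s, to_s) {
  i0 <- round((from_s - signal$start_time) * signal$fs)
  i1 <- round((to_s - signal$start_time) * signal$fs)
  i0 <- max(i0, 0L)
  i1 <- min(i1, length(signal$samples))
  if (i1 <= i0) return(numeric(0))
  signal$samples[(i0 + 1):i1]
}
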