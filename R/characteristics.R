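#' Spindle density in spindles per minute
#'
#' @param n_events Number of spindles (or a tibble of events, in which case
#'   its row count is used).
#' @param scored_seconds Total scored signal time in seconds (115 s per
#'   block).
#' @return Density in spindles per minute (spm).
#' @examples
#' spindle_density(24, 6 * 60) # 4 spm
#' @export
spindle_density <- function(n_events, scored_seconds) {
  if (is.data.frame(n_events)) n_events <- nrow(n_events)
  if (!is.numeric(scored_seconds) || scored_seconds <= 0) {
    stop("`scored_seconds` must be positive.", call. = FALSE)
  }
  n_events / (scored_seconds / 60)
}

# consecutive local extrema of a vector (indices); endpoints included so a
# monotone segment still yields its max-min span
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(seq_len(n))
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1
  turn <- which(diff(s) != 0) + 1L
  unique(c(1L, turn, n))
}

#' Maximum peak-to-peak amplitude of one spindle
#'
#' The signal is band-pass filtered to the sigma band (default 11-16 Hz) and
#' the maximum absolute difference between consecutive local extrema
#' (trough-to-peak or peak-to-trough) within the event span is returned, the
#' conventional oscillatory peak-to-peak measure.
#'
#' @param signal An [eeg_signal()] (broad-band, typically 100 Hz).
#' @param onset_s,duration_s Event coordinates in seconds.
#' @param band Amplitude band in Hz, default `c(11, 16)`.
#' @param filtered Optional pre-filtered [eeg_signal()] to reuse across
#'   events (bypasses the internal filtering).
#' @return Peak-to-peak amplitude in the units of the signal (microvolts).
#' @export
event_amplitude <- function(signal, onset_s, duration_s, band = c(11, 16),
                            filtered = NULL) {
  stopifnot(inherits(signal, "eeg_signal"))
  if (round(duration_s * signal$fs) < 2) {
    stop("event too short for a peak-to-peak measure (< 2 samples).", call. = FALSE)
  }
  xf <- if (is.null(filtered)) bandpass_filter(signal, band[1], band[2]) else filtered
  seg <- signal_slice(xf, onset_s, onset_s + duration_s)
  if (length(seg) < 2) stop("event lies outside the signal.", call. = FALSE)
  ex <- seg[local_extrema(seg)]
  if (length(ex) < 2) return(0)
  max(abs(diff(ex)))
}

#' Dominant oscillation frequency of one spindle
#'
#' The signal is band-pass filtered (default 10-16 Hz), the event samples are
#' zero-padded by `zero_pad_s` seconds (5 s of padding gives a frequency
#' resolution of `1 / (duration + 5)` Hz), and the frequency of maximum FFT
#' energy within `search_band` is returned. The search band (default
#' 9-17 Hz) guards against energy leaking through the filter skirts.
#'
#' @inheritParams event_amplitude
#' @param band Analysis band in Hz, default `c(10, 16)`.
#' @param zero_pad_s Zero padding in seconds, default 5.
#' @param search_band Frequency range searched for the peak, default
#'   `c(9, 17)`.
#' @param energy_floor Events whose filtered in-band peak magnitude falls
#'   below this value (microvolt scale) are flagged `NA`: there is no
#'   oscillation to measure.
#' @return Dominant frequency in Hz, or `NA` below the energy floor.
#' @export
event_frequency <- function(signal, onset_s, duration_s, band = c(10, 16),
                            zero_pad_s = 5, search_band = c(9, 17),
                            energy_floor = 1e-4, filtered = NULL) {
  stopifnot(inherits(signal, "eeg_signal"))
  fs <- signal$fs
  if (round(duration_s * fs) < 2) {
    stop("event too short for a spectral estimate (< 2 samples).", call. = FALSE)
  }
  xf <- if (is.null(filtered)) bandpass_filter(signal, band[1], band[2]) else filtered
  seg <- signal_slice(xf, onset_s, onset_s + duration_s)
  if (length(seg) < 2) stop("event lies outside the signal.", call. = FALSE)
  x <- c(seg, numeric(round(zero_pad_s * fs)))
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]
  freqs <- (seq_along(mag) - 1) * fs / n
  in_band <- freqs >= search_band[1] & freqs <= search_band[2]
  if (max(mag[in_band]) < energy_floor) return(NA_real_)
  freqs[in_band][which.max(mag[in_band])]
}

#' Per-subject spindle metrics
#'
#' Aggregates an event list over one subject's recording into the four
#' standard by-subject characteristics: density (spindles per minute of
#' scored time), mean duration, mean of per-event maximum peak-to-peak
#' sigma-band amplitudes, and mean of per-event dominant frequencies. The
#' signal is filtered once per band and reused across events.
#'
#' @param events Tibble with `onset_s`, `duration_s`.
#' @param signal Broad-band [eeg_signal()] covering the events.
#' @param grid The [build_epoch_grid()] defining the scored time.
#' @param subject_id Identifier copied into the output.
#' @param amp_band Band for the amplitude measure, default `c(11, 16)`.
#' @param freq_band Band for the frequency measure, default `c(10, 16)`.
#' @return One-row tibble: `subject_id`, `n_events`, `scored_minutes`,
#'   `density_spm`, `mean_duration_s`, `mean_amplitude_uv`,
#'   `dominant_freq_hz`. Means over zero events are `NA` (flagged missing).
#' @export
subject_metrics <- function(events, signal, grid, subject_id = "s1",
                            amp_band = c(11, 16), freq_band = c(10, 16)) {
  stopifnot(inherits(signal, "eeg_signal"), inherits(grid, "epoch_grid"))
  events <- tibble::as_tibble(events)
  scored_s <- grid_scored_seconds(grid)
  n <- nrow(events)
  if (n == 0) {
    return(tibble::tibble(
      subject_id = subject_id, n_events = 0L, scored_minutes = scored_s / 60,
      density_spm = 0, mean_duration_s = NA_real_,
      mean_amplitude_uv = NA_real_, dominant_freq_hz = NA_real_
    ))
  }
  amp_f <- bandpass_filter(signal, amp_band[1], amp_band[2])
  freq_f <- bandpass_filter(signal, freq_band[1], freq_band[2])
  amps <- vapply(seq_len(n), function(k) {
    event_amplitude(signal, events$onset_s[k], events$duration_s[k], filtered = amp_f)
  }, numeric(1))
  freqs <- vapply(seq_len(n), function(k) {
    event_frequency(signal, events$onset_s[k], events$duration_s[k], filtered = freq_f)
  }, numeric(1))
  tibble::tibble(
    subject_id = subject_id,
    n_events = n,
    scored_minutes = scored_s / 60,
    density_spm = spindle_density(n, scored_s),
    mean_duration_s = mean(events$duration_s),
    mean_amplitude_uv = mean(amps),
    dominant_freq_hz = mean(freqs, na.rm = TRUE)
  )
}

#' Squared correlation of per-subject characteristics between two methods
#'
#' For each shared feature column, the squared Pearson correlation across the
#' paired subjects plus its p-value. Used to ask how well one spindle source
#' (a detector, another panel) tracks a reference across subjects even when
#' event-level agreement is imperfect.
#'
#' @param metrics_a,metrics_b Per-subject metric tibbles (one row per
#'   subject, matched via `subject_id`).
#' @param features Feature columns to correlate, default the four standard
#'   characteristics.
#' @return Tibble: `feature`, `r_squared`, `p_value`, `n`. Zero variance in
#'   either vector flags the feature as `NA` (undefined).
#' @export
characteristic_correlation <- function(metrics_a, metrics_b,
                                       features = c(
                                         "density_spm", "mean_duration_s",
                                         "mean_amplitude_uv", "dominant_freq_hz"
                                       )) {
  m <- dplyr::inner_join(
    tibble::as_tibble(metrics_a), tibble::as_tibble(metrics_b),
    by = "subject_id", suffix = c("_a", "_b")
  )
  if (nrow(m) < 3) stop("need at least 3 paired subjects.", call. = FALSE)
  purrr::map_dfr(features, function(f) {
    a <- m[[paste0(f, "_a")]]
    b <- m[[paste0(f, "_b")]]
    ok <- stats::complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(tibble::tibble(
        feature = f, r_squared = NA_real_, p_value = NA_real_, n = length(a)
      ))
    }
    ct <- stats::cor.test(a, b, method = "pearson")
    tibble::tibble(
      feature = f, r_squared = unname(ct$estimate)^2,
      p_value = ct$p.value, n = length(a)
    )
  })
}

p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare per-subject spindle characteristics between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature, with group
#' medians and the conventional significance stars (0.05 / 0.01 / 0.001).
#' Typical groupings are younger vs older and female vs male.
#'
#' @param metrics Per-subject metric tibble (one row per subject).
#' @param labels Factor-like vector of group membership, same length as
#'   `nrow(metrics)`, with exactly two levels.
#' @param features Feature columns to test.
#' @return A `group_comparison` tibble: `feature`, `median_<g1>`,
#'   `median_<g2>`, `p_value`, `stars`.
#' @export
compare_groups <- function(metrics, labels,
                           features = c(
                             "density_spm", "mean_duration_s",
                             "mean_amplitude_uv", "dominant_freq_hz"
                           )) {
  metrics <- tibble::as_tibble(metrics)
  labels <- as.character(labels)
  if (length(labels) != nrow(metrics)) {
    stop("`labels` must have one entry per metrics row.", call. = FALSE)
  }
  lv <- unique(labels)
  if (length(lv) != 2 || any(table(labels) == 0)) {
    stop("`labels` must define exactly two non-empty groups.", call. = FALSE)
  }
  out <- purrr::map_dfr(features, function(f) {
    a <- metrics[[f]][labels == lv[1]]
    b <- metrics[[f]][labels == lv[2]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    tibble::tibble(
      feature = f,
      median_1 = stats::median(a, na.rm = TRUE),
      median_2 = stats::median(b, na.rm = TRUE),
      p_value = wt$p.value,
      stars = p_stars(wt$p.value)
    )
  })
  names(out)[names(out) == "median_1"] <- paste0("median_", lv[1])
  names(out)[names(out) == "median_2"] <- paste0("median_", lv[2])
  structure(out, groups = lv, class = c("group_comparison", class(tibble::tibble())))
}

#' Cohort-level dominant-frequency histogram
#'
#' Bins the per-subject dominant frequencies (default 0.25 Hz bins over
#' 9-17 Hz). Its unimodality (or not) is what decides whether a cohort's
#' spindles warrant a slow/fast split.
#'
#' @param freqs_hz Numeric vector of per-subject dominant frequencies.
#' @param binwidth Bin width in Hz, default 0.25.
#' @param range_hz Histogram range, default `c(9, 17)`.
#' @return A `frequency_histogram` tibble: `bin_lo`, `bin_hi`, `bin_mid`,
#'   `count`.
#' @export
frequency_histogram <- function(freqs_hz, binwidth = 0.25, range_hz = c(9, 17)) {
  freqs_hz <- freqs_hz[!is.na(freqs_hz)]
  breaks <- seq(range_hz[1], range_hz[2], by = binwidth)
  if (length(freqs_hz) == 0) {
    out <- tibble::tibble(
      bin_lo = numeric(), bin_hi = numeric(), bin_mid = numeric(), count = integer()
    )
  } else {
    cnt <- table(cut(freqs_hz, breaks = breaks, right = FALSE))
    out <- tibble::tibble(
      bin_lo = breaks[-length(breaks)],
      bin_hi = breaks[-1],
      bin_mid = breaks[-length(breaks)] + binwidth / 2,
      count = as.integer(cnt)
    )
  }
  structure(out, class = c("frequency_histogram", class(tibble::tibble())))
}
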