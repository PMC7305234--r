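#' Automated sigma-band spindle detectors
#'
#' Re-implementations of five classic single-channel spindle detectors, run
#' with their published default parameters on a broad-band 100 Hz signal:
#'
#' * `"envelope"`: band-pass 11-15 Hz; the analytic-signal envelope is
#'   thresholded with an upper seed threshold of 8 x its record mean, and
#'   each seed is extended bidirectionally down to 2 x the mean.
#' * `"rms"`: band-pass 11.3-15.7 Hz; RMS in 100 ms windows stepped by
#'   50 ms; windows above 1.5 x the standard deviation of the RMS series are
#'   spindle-positive (literal reading of the published threshold; set
#'   `params$threshold_form = "mean_plus_sd"` for mean + 1.5 x SD).
#' * `"rms_percentile"`: band-pass 11-15 Hz; RMS in non-overlapping 25 ms
#'   windows; threshold at the 95th percentile of the record's RMS series.
#' * `"wavelet"`: complex Morlet transform centered at 13 Hz with half-power
#'   points near 10 and 16 Hz; squared magnitude smoothed by a 0.1 s moving
#'   average and thresholded at 4.5 x its record mean.
#' * `"a7"` (the A7 detector): four features per 0.3 s window stepped by
#'   0.1 s - log10 absolute sigma (11-16 Hz) power, relative sigma power
#'   z-scored against a 30 s centered baseline, log10 sigma/broad-band
#'   covariance z-scored the same way, and sigma/broad-band Pearson
#'   correlation - thresholded at 1.25, 1.6, 1.3 and 0.69 respectively; a
#'   window is spindle-positive when all four exceed their thresholds.
#'
#' Baseline statistics (means, SDs, percentiles) are computed over the full
#' record, which is assumed artifact-free. Runs of positive samples/windows
#' become events; all detectors then apply the same duration filter
#' (default 0.3-3 s).
#'
#' @param signal Broad-band [eeg_signal()]; resampled internally to 100 Hz if
#'   its rate differs.
#' @param method One of `"envelope"`, `"rms"`, `"rms_percentile"`,
#'   `"wavelet"`, `"a7"`.
#' @param params Named list of per-detector overrides (band edges, window
#'   lengths, thresholds, `duration_bounds`).
#' @return Tibble of detections: `onset_s`, `duration_s`.
#' @examples
#' sim <- simulate_eeg(n_blocks = 1, background_rms = 5, seed = 1)
#' det <- detect_spindles(sim$signal, "rms_percentile")
#' nrow(det)
#' @export
detect_spindles <- function(signal, method = c(
                              "envelope", "rms", "rms_percentile",
                              "wavelet", "a7"
                            ),
                            params = list()) {
  method <- match.arg(method)
  stopifnot(inherits(signal, "eeg_signal"))
  if (signal$fs != 100) signal <- resample_to(signal, 100)
  if (signal_duration(signal) < 30 && method != "a7") {
    warning("record shorter than 30 s: baseline statistics may be unstable.",
      call. = FALSE
    )
  }
  ev <- switch(method,
    envelope = det_envelope(signal, params),
    rms = det_rms(signal, params),
    rms_percentile = det_rms_percentile(signal, params),
    wavelet = det_wavelet(signal, params),
    a7 = det_a7(signal, params)
  )
  bounds <- params$duration_bounds %||% c(0.3, 3.0)
  ev <- ev[ev$duration_s >= bounds[1] - 1e-9 & ev$duration_s <= bounds[2] + 1e-9, ]
  tibble::as_tibble(ev)
}

# analytic-signal magnitude via FFT (Hilbert envelope)
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

det_envelope <- function(signal, params) {
  band <- params$band %||% c(11, 15)
  up <- params$upper_mult %||% 8
  lo <- params$lower_mult %||% 2
  xf <- bandpass_filter(signal, band[1], band[2])$samples
  env <- analytic_envelope(xf)
  m <- mean(env)
  if (m == 0) return(tibble::tibble(onset_s = numeric(), duration_s = numeric()))
  seeds <- env > up * m
  if (!any(seeds)) return(tibble::tibble(onset_s = numeric(), duration_s = numeric()))
  above_lo <- env >= lo * m
  # extend each seed run bidirectionally through the surrounding >= lo*mean run
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & vapply(
    seq_along(r$values),
    function(k) r$values[k] && any(seeds[starts[k]:ends[k]]),
    logical(1)
  )
  flag <- logical(length(env))
  for (k in which(keep)) flag[starts[k]:ends[k]] <- TRUE
  runs_to_intervals(flag, signal$fs)
}

sliding_rms <- function(x, fs, win_s, step_s) {
  win <- round(win_s * fs)
  step <- round(step_s * fs)
  starts <- seq(1, length(x) - win + 1, by = step)
  rms <- vapply(starts, function(i) sqrt(mean(x[i:(i + win - 1)]^2)), numeric(1))
  list(rms = rms, t_start = (starts - 1) / fs, win_s = win / fs, step_s = step / fs)
}

window_runs_to_events <- function(flag, t_start, win_s) {
  if (!any(flag)) return(tibble::tibble(onset_s = numeric(), duration_s = numeric()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  ev <- tibble::tibble(
    onset_s = t_start[starts[on]],
    duration_s = t_start[ends[on]] + win_s - t_start[starts[on]]
  )
  # overlapping windows (step < length) can yield runs whose spans overlap
  flatten_events(ev)
}

det_rms <- function(signal, params) {
  band <- params$band %||% c(11.3, 15.7)
  mult <- params$sd_mult %||% 1.5
  form <- params$threshold_form %||% "sd"
  xf <- bandpass_filter(signal, band[1], band[2])$samples
  sr <- sliding_rms(xf, signal$fs, params$win_s %||% 0.1, params$step_s %||% 0.05)
  thr <- switch(form,
    sd = mult * stats::sd(sr$rms),
    mean_plus_sd = mean(sr$rms) + mult * stats::sd(sr$rms),
    stop("unknown threshold_form: ", form, call. = FALSE)
  )
  window_runs_to_events(sr$rms > thr, sr$t_start, sr$win_s)
}

det_rms_percentile <- function(signal, params) {
  band <- params$band %||% c(11, 15)
  prob <- params$percentile %||% 0.95
  xf <- bandpass_filter(signal, band[1], band[2])$samples
  sr <- sliding_rms(xf, signal$fs, params$win_s %||% 0.025, params$step_s %||% 0.025)
  thr <- stats::quantile(sr$rms, prob, names = FALSE)
  window_runs_to_events(sr$rms > thr, sr$t_start, sr$win_s)
}

# complex Morlet response at center frequency f0 with given spectral sd (Hz)
morlet_power <- function(x, fs, f0, sigma_f) {
  n <- length(x)
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f0 * t) * exp(-t^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2)) # unit energy
  nf <- stats::nextn(n + length(w) - 1, 2)
  conv <- stats::fft(stats::fft(c(x, numeric(nf - n))) *
    stats::fft(c(w, numeric(nf - length(w)))), inverse = TRUE) / nf
  out <- conv[(half + 1):(half + n)]
  Mod(out)^2
}

det_wavelet <- function(signal, params) {
  f0 <- params$center_hz %||% 13
  # half-power points of the Gaussian spectrum at f0 +/- sigma_f*sqrt(ln 2):
  # sigma_f = 3.6 Hz puts them near 10 and 16 Hz
  sigma_f <- params$sigma_f %||% (3 / sqrt(log(2)))
  mult <- params$mean_mult %||% 4.5
  ma_s <- params$ma_s %||% 0.1
  pw <- morlet_power(signal$samples, signal$fs, f0, sigma_f)
  k <- round(ma_s * signal$fs)
  ma <- as.numeric(stats::filter(pw, rep(1 / k, k), sides = 2))
  ma[is.na(ma)] <- 0
  m <- mean(ma)
  if (m == 0) return(tibble::tibble(onset_s = numeric(), duration_s = numeric()))
  runs_to_intervals(ma > mult * m, signal$fs)
}

# centered rolling mean/sd over +/- half windows (truncated at the edges)
rolling_stats <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  mu <- (cs[hi + 1] - cs[lo]) / cnt
  v <- (cs2[hi + 1] - cs2[lo]) / cnt - mu^2
  list(mean = mu, sd = sqrt(pmax(v, 0)))
}

det_a7 <- function(signal, params) {
  fs <- signal$fs
  x <- signal$samples
  win_s <- params$win_s %||% 0.3
  step_s <- params$step_s %||% 0.1
  baseline_s <- params$baseline_s %||% 30
  thr_abs <- params$thr_abs_power %||% 1.25 # log10(uV^2)
  thr_rel <- params$thr_rel_power %||% 1.6 # z
  thr_cov <- params$thr_covariance %||% 1.3 # z
  thr_cor <- params$thr_correlation %||% 0.69
  band <- params$sigma_band %||% c(11, 16)
  if (signal_duration(signal) < baseline_s) {
    stop(sprintf(
      "record (%.1f s) is shorter than the %g s baseline required by the a7 detector.",
      signal_duration(signal), baseline_s
    ), call. = FALSE)
  }
  sig <- bandpass_filter(signal, band[1], band[2])$samples
  win <- round(win_s * fs)
  step <- round(step_s * fs)
  starts <- seq(1, length(x) - win + 1, by = step)
  nw <- length(starts)
  abs_pow <- rel_pow <- cov_f <- cor_f <- numeric(nw)
  # FFT band bins for the relative power (windows zero-padded to 256 samples)
  nfft <- 256
  fbins <- (0:(nfft - 1)) * fs / nfft
  sel_sigma <- fbins >= band[1] & fbins <= band[2]
  sel_broad <- fbins >= 0.5 & fbins <= 30
  for (k in seq_len(nw)) {
    idx <- starts[k]:(starts[k] + win - 1)
    s <- sig[idx]
    b <- x[idx]
    abs_pow[k] <- log10(max(mean(s^2), 1e-12))
    psd <- Mod(stats::fft(c(b - mean(b), numeric(nfft - win))))^2
    tot <- sum(psd[sel_broad])
    rel_pow[k] <- log10(max(sum(psd[sel_sigma]) / max(tot, 1e-12), 1e-12))
    cv <- mean((s - mean(s)) * (b - mean(b)))
    # floor at 0.1 uV^2 before the log so that near-zero/negative background
    # covariances do not blow up the baseline spread of the z-score
    cov_f[k] <- log10(max(cv, 0.1))
    cor_f[k] <- if (stats::sd(s) > 0 && stats::sd(b) > 0) stats::cor(s, b) else 0
  }
  half <- round(baseline_s / 2 / step_s)
  rs_rel <- rolling_stats(rel_pow, half)
  rs_cov <- rolling_stats(cov_f, half)
  z <- function(x, rs) ifelse(rs$sd > 0, (x - rs$mean) / rs$sd, 0)
  pos <- abs_pow > thr_abs &
    z(rel_pow, rs_rel) > thr_rel &
    z(cov_f, rs_cov) > thr_cov &
    cor_f > thr_cor
  window_runs_to_events(pos, (starts - 1) / fs, win / fs)
}
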