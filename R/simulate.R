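#' Simulate artifact-free N2-like EEG with injected spindle bursts
#'
#' Generates 115 s blocks of 1/f^alpha background noise at 100 Hz with
#' Hann-enveloped constant-frequency sinusoidal bursts injected at a target
#' density, the signal model the consensus pipeline assumes: an artifact-free
#' N2 background plus sigma-band (11-16 Hz) spindles of 0.5-1.5 s. Injected
#' events never overlap and keep at least `min_gap_s` between them, so the
#' ground-truth list is a valid reference for event matching. Defaults mirror
#' a healthy younger sleeper: 4.2 spindles per minute, 20-45 microvolt
#' peak-to-peak bursts on a 15 microvolt RMS background.
#'
#' @param n_blocks Number of 115 s blocks. Default 3 (the usual per-subject
#'   sampling; use 10 for the densely sampled subjects).
#' @param block_length_s Block length in seconds, default 115.
#' @param fs Sampling rate in Hz, default 100.
#' @param background_alpha Spectral slope of the 1/f^alpha background,
#'   default 1.
#' @param background_rms Background RMS in microvolts, default 15.
#' @param density_spm Target spindle density in spindles per minute,
#'   default 4.2.
#' @param duration_range Burst duration range in seconds, default
#'   `c(0.5, 1.5)`.
#' @param freq_range Burst oscillation frequency range in Hz, default
#'   `c(11, 16)`.
#' @param amplitude_range Burst peak-to-peak amplitude range in microvolts,
#'   default `c(20, 45)`.
#' @param min_gap_s Minimum gap between consecutive bursts, default 0.5.
#' @param edge_margin_s Keep-out zone at each block edge, default 1.
#' @param seed Optional integer seed for full reproducibility.
#' @return List with `signal` (an [eeg_signal()]), `truth` (tibble
#'   `onset_s`, `duration_s`, `freq_hz`, `amplitude_uv`) and `grid` (the
#'   [build_epoch_grid()] of the blocks).
#' @examples
#' sim <- simulate_eeg(n_blocks = 1, seed = 42)
#' nrow(sim$truth)
#' @export
simulate_eeg <- function(n_blocks = 3, block_length_s = 115, fs = 100,
                         background_alpha = 1, background_rms = 15,
                         density_spm = 4.2,
                         duration_range = c(0.5, 1.5),
                         freq_range = c(11, 16),
                         amplitude_range = c(20, 45),
                         min_gap_s = 0.5, edge_margin_s = 1,
                         seed = NULL) {
  stopifnot(n_blocks >= 1, density_spm >= 0, all(duration_range > 0))
  # feasibility: mean occupied span per spindle incl. dead time vs block time
  occupancy <- density_spm * (mean(duration_range) + min_gap_s) / 60
  if (occupancy > 0.8) {
    stop(sprintf(
      "density %g spm is incompatible with the %g s dead time (occupancy %.0f%%).",
      density_spm, min_gap_s, 100 * occupancy
    ), call. = FALSE)
  }
  gen <- function() {
    grid <- build_epoch_grid((seq_len(n_blocks) - 1) * block_length_s,
      fs = fs, block_length_s = block_length_s
    )
    n <- round(n_blocks * block_length_s * fs)
    x <- one_over_f_noise(n, background_alpha, background_rms)
    truth <- place_bursts(
      n_blocks, block_length_s, density_spm,
      duration_range, freq_range, amplitude_range, min_gap_s, edge_margin_s
    )
    for (k in seq_len(nrow(truth))) {
      i0 <- round(truth$onset_s[k] * fs)
      len <- round(truth$duration_s[k] * fs)
      t <- (0:(len - 1)) / fs
      env <- 0.5 * (1 - cos(2 * pi * (t + 1 / fs) / (truth$duration_s[k] + 2 / fs)))
      burst <- (truth$amplitude_uv[k] / 2) * env *
        sin(2 * pi * truth$freq_hz[k] * t + truth$phase[k])
      x[(i0 + 1):(i0 + len)] <- x[(i0 + 1):(i0 + len)] + burst
    }
    list(
      signal = eeg_signal(x, fs = fs),
      truth = truth[, c("onset_s", "duration_s", "freq_hz", "amplitude_uv")],
      grid = grid
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# gaussian 1/f^alpha noise via spectral shaping, scaled to target RMS
one_over_f_noise <- function(n, alpha, rms) {
  if (rms == 0) return(numeric(n))
  nf <- stats::nextn(n, 2)
  f <- c(1, seq_len(nf / 2), seq(nf / 2 - 1, 1)) # DC slot reuses bin 1 weight
  spec <- f^(-alpha / 2)
  spec[1] <- 0
  phase <- stats::runif(nf / 2 - 1, 0, 2 * pi)
  half <- spec[2:(nf / 2)] * exp(1i * phase)
  full <- c(0, half, spec[nf / 2 + 1], Conj(rev(half)))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x * (rms / stats::sd(x))
}

place_bursts <- function(n_blocks, block_length_s, density_spm,
                         duration_range, freq_range, amplitude_range,
                         min_gap_s, edge_margin_s) {
  out <- list()
  for (b in seq_len(n_blocks)) {
    t0 <- (b - 1) * block_length_s
    n_target <- stats::rpois(1, density_spm * block_length_s / 60)
    if (n_target == 0) next
    placed_on <- numeric(0)
    placed_off <- numeric(0)
    tries <- 0
    while (length(placed_on) < n_target && tries < 50 * n_target) {
      tries <- tries + 1
      dur <- stats::runif(1, duration_range[1], duration_range[2])
      on <- stats::runif(1, t0 + edge_margin_s, t0 + block_length_s - edge_margin_s - dur)
      if (length(placed_on) == 0 ||
        all(on >= placed_off + min_gap_s | on + dur <= placed_on - min_gap_s)) {
        placed_on <- c(placed_on, on)
        placed_off <- c(placed_off, on + dur)
      }
    }
    ord <- order(placed_on)
    out[[b]] <- tibble::tibble(
      onset_s = placed_on[ord],
      duration_s = (placed_off - placed_on)[ord]
    )
  }
  truth <- dplyr::bind_rows(out)
  if (nrow(truth) == 0) {
    return(tibble::tibble(
      onset_s = numeric(), duration_s = numeric(),
      freq_hz = numeric(), amplitude_uv = numeric(), phase = numeric()
    ))
  }
  truth$freq_hz <- stats::runif(nrow(truth), freq_range[1], freq_range[2])
  truth$amplitude_uv <- stats::runif(nrow(truth), amplitude_range[1], amplitude_range[2])
  truth$phase <- stats::runif(nrow(truth), 0, 2 * pi)
  truth
}

#' Simulate a panel of imperfect human scorers
#'
#' Each simulated scorer independently marks each ground-truth spindle with a
#' configurable sensitivity, jitters the marked boundaries, rates confidence
#' by the event's amplitude tertile (high for the loudest third, low for the
#' quietest), and adds Poisson false positives. All scorers view all epochs
#' unless `view_fraction < 1`. Each scorer draws from an independent
#' sub-stream seeded from the master seed.
#'
#' @param truth Ground-truth events from [simulate_eeg()] (needs
#'   `onset_s`, `duration_s`, `amplitude_uv`).
#' @param grid The matching [build_epoch_grid()].
#' @param n_scorers Panel size.
#' @param sensitivity Either a single detection probability applied to every
#'   event, or a list `list(midpoint_uv =, slope =)` for a logistic
#'   sensitivity in event amplitude.
#' @param jitter_sd Standard deviation (s) of independent Gaussian jitter on
#'   each marked onset and offset, default 0.05.
#' @param fp_rate_per_min False positives per scorer per viewed minute,
#'   default 0.5.
#' @param fp_duration_range Duration range of false positives, default
#'   `c(0.3, 1.0)`.
#' @param confidence_noise Probability that a confidence rating is replaced
#'   by a uniformly random one, default 0.
#' @param view_fraction Fraction of epochs each scorer views, default 1.
#' @param subtype Scorer subtype for the whole panel, default "expert".
#' @param subject_id Subject identifier, default "s1".
#' @param seed Optional master seed.
#' @return An [annotation_set()].
#' @export
simulate_panel <- function(truth, grid, n_scorers,
                           sensitivity = 0.95, jitter_sd = 0.05,
                           fp_rate_per_min = 0.5,
                           fp_duration_range = c(0.3, 1.0),
                           confidence_noise = 0, view_fraction = 1,
                           subtype = "expert", subject_id = "s1",
                           seed = NULL) {
  stopifnot(n_scorers >= 1, jitter_sd >= 0, fp_rate_per_min >= 0)
  truth <- tibble::as_tibble(truth)
  gen <- function() {
    scorer_seeds <- sample.int(.Machine$integer.max - 1, n_scorers)
    conf_levels <- amplitude_tertile_confidence(truth$amplitude_uv)
    parts <- lapply(seq_len(n_scorers), function(i) {
      withr::with_seed(
        scorer_seeds[i],
        simulate_one_scorer(
          truth, grid, sprintf("scorer%02d", i), conf_levels,
          sensitivity, jitter_sd, fp_rate_per_min, fp_duration_range,
          confidence_noise, view_fraction, subtype
        )
      )
    })
    events <- dplyr::bind_rows(lapply(parts, `[[`, "events"))
    views <- dplyr::bind_rows(lapply(parts, `[[`, "views"))
    scorers <- tibble::tibble(
      scorer_id = sprintf("scorer%02d", seq_len(n_scorers)),
      subtype = subtype
    )
    annotation_set(subject_id, grid, events, views, scorers = scorers)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

amplitude_tertile_confidence <- function(amplitude_uv) {
  if (length(amplitude_uv) == 0) return(character(0))
  q <- stats::quantile(amplitude_uv, c(1 / 3, 2 / 3), names = FALSE)
  dplyr::case_when(
    amplitude_uv > q[2] ~ "high",
    amplitude_uv > q[1] ~ "medium",
    TRUE ~ "low"
  )
}

detection_prob <- function(sensitivity, amplitude_uv) {
  if (is.list(sensitivity)) {
    stats::plogis((amplitude_uv - sensitivity$midpoint_uv) * sensitivity$slope)
  } else {
    rep(sensitivity, length(amplitude_uv))
  }
}

# epoch id containing [onset, onset+dur], NA if none
containing_epoch <- function(grid, onset, dur) {
  hit <- grid$start_s <= onset + 1e-9 & grid$end_s >= onset + dur - 1e-9
  if (!any(hit)) return(NA_character_)
  # prefer the epoch whose center is closest to the event center
  cand <- which(hit)
  centers <- (grid$start_s[cand] + grid$end_s[cand]) / 2
  grid$epoch_id[cand[which.min(abs(centers - (onset + dur / 2)))]]
}

simulate_one_scorer <- function(truth, grid, scorer_id, conf_levels,
                                sensitivity, jitter_sd, fp_rate_per_min,
                                fp_duration_range, confidence_noise,
                                view_fraction, subtype) {
  viewed <- grid$epoch_id
  if (view_fraction < 1) {
    keep <- sort(sample(length(viewed), max(1, round(view_fraction * length(viewed)))))
    viewed <- viewed[keep]
  }
  vg <- grid[grid$epoch_id %in% viewed, ]
  n_t <- nrow(truth)
  rows <- list()
  if (n_t > 0) {
    p <- detection_prob(sensitivity, truth$amplitude_uv)
    hit <- stats::runif(n_t) < p
    for (k in which(hit)) {
      on <- truth$onset_s[k] + stats::rnorm(1, 0, jitter_sd)
      off <- truth$onset_s[k] + truth$duration_s[k] + stats::rnorm(1, 0, jitter_sd)
      if (off - on < 0.1) next
      ep <- containing_epoch(vg, on, off - on)
      if (is.na(ep)) next
      conf <- conf_levels[k]
      if (confidence_noise > 0 && stats::runif(1) < confidence_noise) {
        conf <- sample(c("low", "medium", "high"), 1)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        scorer_id = scorer_id, subtype = subtype, epoch_id = ep,
        onset_s = on, duration_s = off - on, confidence = conf
      )
    }
  }
  # false positives: Poisson in viewed time, rejected if overlapping anything
  minutes <- nrow(vg) * 0 + length(unique(vg$block)) * attr(grid, "block_length_s") / 60
  n_fp <- stats::rpois(1, fp_rate_per_min * minutes)
  ev <- dplyr::bind_rows(rows)
  existing <- if (nrow(ev) > 0) ev else NULL
  placed <- 0
  tries <- 0
  while (placed < n_fp && tries < 50 * max(n_fp, 1)) {
    tries <- tries + 1
    dur <- stats::runif(1, fp_duration_range[1], fp_duration_range[2])
    row <- vg[sample(nrow(vg), 1), ]
    on <- stats::runif(1, row$start_s, row$end_s - dur)
    clash <- nrow(ev) > 0 &&
      any(on < ev$onset_s + ev$duration_s + 0.05 & on + dur > ev$onset_s - 0.05)
    if (clash) next
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      scorer_id = scorer_id, subtype = subtype, epoch_id = row$epoch_id,
      onset_s = on, duration_s = dur,
      confidence = sample(c("low", "medium", "high"), 1, prob = c(0.5, 0.35, 0.15))
    ))
    placed <- placed + 1
  }
  if (nrow(ev) == 0) {
    ev <- tibble::tibble(
      scorer_id = character(), subtype = character(), epoch_id = character(),
      onset_s = numeric(), duration_s = numeric(), confidence = character()
    )
  }
  list(
    events = ev,
    views = tibble::tibble(scorer_id = scorer_id, epoch_id = viewed)
  )
}
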