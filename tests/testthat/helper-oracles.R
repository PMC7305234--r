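# Independent brute-force event matcher used as the oracle for the greedy
# production matcher. Written deliberately as plain nested loops over an
# explicit IoU table with repeated global arg-max scans; shares no code with
# match_events().
brute_force_match <- function(gs, det, thr) {
  n_g <- nrow(gs)
  n_d <- nrow(det)
  iou_tab <- matrix(0, nrow = max(n_g, 1), ncol = max(n_d, 1))
  if (n_g > 0 && n_d > 0) {
    for (i in seq_len(n_g)) {
      for (j in seq_len(n_d)) {
        a0 <- gs$onset_s[i]; a1 <- a0 + gs$duration_s[i]
        b0 <- det$onset_s[j]; b1 <- b0 + det$duration_s[j]
        inter <- max(0, min(a1, b1) - max(a0, b0))
        iou_tab[i, j] <- if (inter > 0) inter / (max(a1, b1) - min(a0, b0)) else 0
      }
    }
  }
  used_g <- rep(FALSE, n_g)
  used_d <- rep(FALSE, n_d)
  pairs <- list()
  repeat {
    best <- NULL
    for (i in seq_len(n_g)) {
      if (used_g[i]) next
      for (j in seq_len(n_d)) {
        if (used_d[j]) next
        v <- iou_tab[i, j]
        if (v < thr || v <= 0) next
        if (is.null(best)) {
          best <- c(i, j, v)
        } else if (v > best[3] + 1e-12) {
          best <- c(i, j, v)
        } else if (abs(v - best[3]) <= 1e-12) {
          # tie: earlier event onset, then earlier detection onset
          if (gs$onset_s[i] < gs$onset_s[best[1]] - 1e-12 ||
            (abs(gs$onset_s[i] - gs$onset_s[best[1]]) <= 1e-12 &&
              det$onset_s[j] < det$onset_s[best[2]] - 1e-12)) {
            best <- c(i, j, v)
          }
        }
      }
    }
    if (is.null(best)) break
    used_g[best[1]] <- TRUE
    used_d[best[2]] <- TRUE
    pairs[[length(pairs) + 1]] <- best
  }
  tp <- length(pairs)
  list(tp = tp, fp = n_d - tp, fn = n_g - tp,
       pairs = do.call(rbind, pairs))
}

# random non-overlapping sorted event list on [0, span] seconds
random_event_list <- function(n_max, span = 20) {
  n <- sample(0:n_max, 1)
  if (n == 0) {
    return(tibble::tibble(onset_s = numeric(), duration_s = numeric()))
  }
  on <- sort(runif(n, 0, span))
  keep <- c(TRUE, diff(on) > 0.2) # enforce clean gaps
  on <- on[keep]
  gap_to_next <- c(diff(on), span - on[length(on)] + 0.5)
  dur <- pmin(runif(length(on), 0.1, 2), gap_to_next - 0.05)
  tibble::tibble(onset_s = on, duration_s = dur)
}

# annotation set where every scorer marks exactly the given events with the
# given confidence, over a shared single-block grid (all epochs viewed)
unanimous_panel <- function(events, n_scorers = 3, confidence = "high",
                            n_blocks = 1, subtype = "expert") {
  grid <- build_epoch_grid((seq_len(n_blocks) - 1) * 115)
  ep_of <- function(on, dur) {
    hit <- which(grid$start_s <= on + 1e-9 & grid$end_s >= on + dur - 1e-9)
    grid$epoch_id[hit[1]]
  }
  ev <- purrr::map_dfr(seq_len(n_scorers), function(i) {
    if (nrow(events) == 0) {
      return(tibble::tibble(
        scorer_id = character(), subtype = character(), epoch_id = character(),
        onset_s = numeric(), duration_s = numeric(), confidence = character()
      ))
    }
    tibble::tibble(
      scorer_id = sprintf("sc%02d", i), subtype = subtype,
      epoch_id = mapply(ep_of, events$onset_s, events$duration_s),
      onset_s = events$onset_s, duration_s = events$duration_s,
      confidence = confidence
    )
  })
  views <- tidyr::expand_grid(
    scorer_id = sprintf("sc%02d", seq_len(n_scorers)),
    epoch_id = grid$epoch_id
  )
  scorers <- tibble::tibble(
    scorer_id = sprintf("sc%02d", seq_len(n_scorers)), subtype = subtype
  )
  annotation_set("s1", grid, ev, views, scorers = scorers)
}

# hand-built panel: `marks` is a list of per-scorer event tibbles
# (onset_s, duration_s, confidence); all scorers view all epochs
hand_panel <- function(marks, n_blocks = 1, subtype = "expert") {
  grid <- build_epoch_grid((seq_len(n_blocks) - 1) * 115)
  ep_of <- function(on, dur) {
    hit <- which(grid$start_s <= on + 1e-9 & grid$end_s >= on + dur - 1e-9)
    grid$epoch_id[hit[1]]
  }
  ev <- purrr::imap_dfr(marks, function(m, i) {
    if (is.null(m) || nrow(m) == 0) {
      return(tibble::tibble(
        scorer_id = character(), subtype = character(), epoch_id = character(),
        onset_s = numeric(), duration_s = numeric(), confidence = character()
      ))
    }
    tibble::tibble(
      scorer_id = sprintf("sc%02d", i), subtype = subtype,
      epoch_id = mapply(ep_of, m$onset_s, m$duration_s),
      onset_s = m$onset_s, duration_s = m$duration_s, confidence = m$confidence
    )
  })
  views <- tidyr::expand_grid(
    scorer_id = sprintf("sc%02d", seq_along(marks)),
    epoch_id = grid$epoch_id
  )
  scorers <- tibble::tibble(
    scorer_id = sprintf("sc%02d", seq_along(marks)), subtype = subtype
  )
  annotation_set("s1", grid, ev, views, scorers = scorers)
}

# pure sinusoid eeg_signal helper
sine_signal <- function(freq, seconds = 10, fs = 100, amp = 1, phase = 0) {
  t <- (0:(round(seconds * fs) - 1)) / fs
  eeg_signal(amp * sin(2 * pi * freq * t + phase), fs = fs)
}

# high-SNR detector fixture: loud bursts inside the common passband of all
# five detectors, quiet 1/f background
detector_fixture <- function(seed = 11) {
  simulate_eeg(
    n_blocks = 2, background_rms = 5, amplitude_range = c(40, 60),
    freq_range = c(11.5, 14.5), seed = seed
  )
}
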