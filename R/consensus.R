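#' Consensus configuration
#'
#' Parameters of the thresholding and cleanup applied to the averaged score
#' track. `gct` is the group consensus threshold: a sample enters the
#' consensus when its mean confidence-weighted score is strictly greater than
#' `gct` ("exceeds"), which makes `gct = 0` a meaningful, maximally inclusive
#' setting. Cleanup merges too-short adjacent candidates (< 0.1 s apart with
#' at least one member < 0.3 s) and then drops events shorter than 0.3 s or
#' longer than 2.5 s.
#'
#' @param gct Group consensus threshold in `[0, 1)`.
#' @param merge_gap_s Maximum gap for the merge rule, default 0.1 s.
#' @param min_duration_s Minimum retained duration, default 0.3 s.
#' @param max_duration_s Maximum retained duration, default 2.5 s.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(gct = 0.2, merge_gap_s = 0.1,
                             min_duration_s = 0.3, max_duration_s = 2.5) {
  if (!(gct >= 0 && gct < 1)) stop("`gct` must lie in [0, 1).", call. = FALSE)
  if (!(min_duration_s > 0 && min_duration_s < max_duration_s)) {
    stop("need 0 < min_duration_s < max_duration_s.", call. = FALSE)
  }
  structure(
    list(
      gct = gct, merge_gap_s = merge_gap_s,
      min_duration_s = min_duration_s, max_duration_s = max_duration_s
    ),
    class = "consensus_config"
  )
}

#' Rasterize one scorer's markings onto the sample grid
#'
#' Converts a scorer's event list into a per-sample weight track at the grid
#' rate. Where two overlapping epochs cover the same instant (the 2.5 s epoch
#' overlap zones) a spindle may have been marked on either image, so the
#' scorer's highest weight at each sample is kept. Samples in epochs the
#' scorer never viewed are flagged not-viewed and excluded from averaging.
#'
#' @param events Tibble of this scorer's markings (`epoch_id`, `onset_s`,
#'   `duration_s`, `confidence`).
#' @param viewed_epochs Character vector of epoch ids the scorer viewed.
#' @param grid The [build_epoch_grid()].
#' @return List with `weight` (numeric, one entry per sample of the grid
#'   span) and `viewed` (logical).
#' @export
rasterize_scorer <- function(events, viewed_epochs, grid) {
  fs <- attr(grid, "fs")
  n <- grid_n_samples(grid)
  weight <- numeric(n)
  viewed <- logical(n)
  vg <- grid[grid$epoch_id %in% viewed_epochs, ]
  for (k in seq_len(nrow(vg))) {
    r <- sample_range(vg$start_s[k], vg$end_s[k], fs)
    viewed[r[1]:r[2]] <- TRUE
  }
  if (nrow(events) > 0) {
    w <- confidence_weight(events$confidence)
    for (k in seq_len(nrow(events))) {
      r <- sample_range(events$onset_s[k], events$onset_s[k] + events$duration_s[k], fs)
      if (r[2] < r[1]) next
      idx <- max(r[1], 1L):min(r[2], n)
      weight[idx] <- pmax(weight[idx], w[k])
    }
  }
  weight[!viewed] <- 0
  list(weight = weight, viewed = viewed)
}

#' Average per-scorer weight tracks into a score track
#'
#' Sample by sample, the mean of the confidence weights over the scorers who
#' viewed that sample. Samples nobody viewed get score 0 with viewer count 0.
#'
#' @param tracks List of [rasterize_scorer()] results.
#' @param fs Sampling rate of the tracks, default 100.
#' @return A `score_track`: list with `score` in `[0, 1]`, integer
#'   `viewers`, and `fs`.
#' @export
average_scores <- function(tracks, fs = 100) {
  if (length(tracks) == 0) stop("need at least one scorer track.", call. = FALSE)
  n <- length(tracks[[1]]$weight)
  wsum <- numeric(n)
  vcount <- integer(n)
  for (tr in tracks) {
    wsum <- wsum + tr$weight
    vcount <- vcount + tr$viewed
  }
  score <- ifelse(vcount > 0, wsum / pmax(vcount, 1L), 0)
  structure(list(score = score, viewers = vcount, fs = fs), class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf(
    "<score_track> %d samples @ %g Hz, score range [%.3f, %.3f], max viewers %d\n",
    length(x$score), x$fs, min(x$score), max(x$score), max(x$viewers)
  ))
  invisible(x)
}

#' @export
as_tibble.score_track <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$score) - 1) / x$fs,
    score = x$score,
    viewers = x$viewers
  )
}

#' Threshold a score track and clean up the candidate events
#'
#' Maximal runs of samples whose score strictly exceeds `gct` become candidate
#' spindles. Cleanup then (1) merges adjacent candidates separated by less
#' than `merge_gap_s` when at least one of the pair is shorter than
#' `min_duration_s`, repeating to a fixed point, and (2) removes events
#' shorter than `min_duration_s` or longer than `max_duration_s`.
#'
#' @param track A [average_scores()] result.
#' @param config A [consensus_config()].
#' @return A `consensus_events` tibble: `onset_s`, `duration_s`, `peak_score`.
#' @export
threshold_and_clean <- function(track, config = consensus_config()) {
  stopifnot(inherits(track, "score_track"), inherits(config, "consensus_config"))
  fs <- track$fs
  iv <- runs_to_intervals(track$score > config$gct, fs)
  iv <- merge_short_adjacent(iv, config$merge_gap_s, config$min_duration_s)
  keep <- iv$duration_s >= config$min_duration_s - 1e-9 &
    iv$duration_s <= config$max_duration_s + 1e-9
  iv <- iv[keep, , drop = FALSE]
  peak <- vapply(seq_len(nrow(iv)), function(k) {
    r <- sample_range(iv$onset_s[k], iv$onset_s[k] + iv$duration_s[k], fs)
    max(track$score[r[1]:r[2]])
  }, numeric(1))
  new_consensus_events(
    tibble::tibble(onset_s = iv$onset_s, duration_s = iv$duration_s, peak_score = peak),
    gct = config$gct
  )
}

new_consensus_events <- function(events, gct = NA_real_, subtype = NA_character_,
                                 n_scorers = NA_integer_, gold_standard = FALSE) {
  structure(
    events,
    gct = gct, subtype = subtype, n_scorers = n_scorers,
    gold_standard = gold_standard,
    class = c("consensus_events", class(tibble::tibble()))
  )
}

# logical vector -> tibble(onset_s, duration_s), half-open sample convention
runs_to_intervals <- function(flag, fs) {
  if (!any(flag)) return(tibble::tibble(onset_s = numeric(), duration_s = numeric()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values
  tibble::tibble(
    onset_s = (starts[on] - 1L) / fs,
    duration_s = r$lengths[on] / fs
  )
}

# merge adjacent intervals (gap < merge_gap) where at least one member is
# shorter than min_dur; repeat until no pair qualifies
merge_short_adjacent <- function(iv, merge_gap, min_dur) {
  if (nrow(iv) < 2) return(iv)
  on <- iv$onset_s
  off <- iv$onset_s + iv$duration_s
  repeat {
    if (length(on) < 2) break
    gap <- on[-1] - off[-length(off)]
    dur <- off - on
    short <- dur < min_dur - 1e-9
    mergeable <- gap < merge_gap - 1e-9 & (short[-length(short)] | short[-1])
    i <- which(mergeable)[1]
    if (is.na(i)) break
    off[i] <- max(off[i], off[i + 1])
    on <- on[-(i + 1)]
    off <- off[-(i + 1)]
  }
  tibble::tibble(onset_s = on, duration_s = off - on)
}

#' Build the group consensus event list for a scorer panel
#'
#' The full consensus pipeline: rasterize each scorer of the requested
#' subtype, average the weight tracks sample by sample over viewers, threshold
#' at the group consensus threshold and clean up. The consensus of the expert
#' panel is the gold standard (GS).
#'
#' @param annotations An [annotation_set()].
#' @param subtype One of "expert", "researcher", "nonexpert", or `NULL` for
#'   all scorers.
#' @param config A [consensus_config()].
#' @return A `consensus_events` tibble (`onset_s`, `duration_s`,
#'   `peak_score`) with the panel subtype, size and `gct` as attributes;
#'   `attr(-, "gold_standard")` is `TRUE` for an expert panel.
#' @examples
#' sim <- simulate_eeg(n_blocks = 1, seed = 1)
#' anns <- simulate_panel(sim$truth, sim$grid, n_scorers = 4, seed = 2)
#' gs <- build_group_consensus(anns, subtype = "expert", config = consensus_config(gct = 0.2))
#' nrow(gs)
#' @export
build_group_consensus <- function(annotations, subtype = "expert",
                                  config = consensus_config()) {
  stopifnot(inherits(annotations, "annotation_set"))
  ids <- panel_scorers(annotations, subtype)
  if (length(ids) == 0) {
    stop(
      "no scorers of subtype ",
      if (is.null(subtype)) "<any>" else paste(subtype, collapse = "/"),
      " in the annotation set.",
      call. = FALSE
    )
  }
  tracks <- scorer_tracks(annotations, ids)
  track <- average_scores(tracks, fs = attr(annotations$grid, "fs"))
  ev <- threshold_and_clean(track, config)
  new_consensus_events(
    tibble::as_tibble(ev),
    gct = config$gct,
    subtype = if (is.null(subtype)) "all" else paste(subtype, collapse = "+"),
    n_scorers = length(ids),
    gold_standard = identical(subtype, "expert")
  )
}

scorer_tracks <- function(annotations, ids) {
  grid <- annotations$grid
  lapply(ids, function(id) {
    rasterize_scorer(
      annotations$events[annotations$events$scorer_id == id, ],
      annotations$views$epoch_id[annotations$views$scorer_id == id],
      grid
    )
  })
}

#' Leave-one-out group consensus
#'
#' The consensus rebuilt with one scorer's tracks removed from both the
#' numerator and the viewer denominator, used as the reference when that
#' scorer is being evaluated (avoids the positive bias of self-agreement).
#'
#' @inheritParams build_group_consensus
#' @param excluded_scorer Scorer id to leave out.
#' @return A `consensus_events` tibble.
#' @export
leave_one_out_consensus <- function(annotations, excluded_scorer,
                                    subtype = "expert",
                                    config = consensus_config()) {
  stopifnot(inherits(annotations, "annotation_set"))
  ids <- panel_scorers(annotations, subtype)
  if (!excluded_scorer %in% ids) {
    stop("scorer ", excluded_scorer, " is not a member of the ",
      if (is.null(subtype)) "full" else paste(subtype, collapse = "/"),
      " panel.",
      call. = FALSE
    )
  }
  rest <- setdiff(ids, excluded_scorer)
  if (length(rest) == 0) {
    stop("leave-one-out consensus is undefined for a single-scorer panel.", call. = FALSE)
  }
  tracks <- scorer_tracks(annotations, rest)
  track <- average_scores(tracks, fs = attr(annotations$grid, "fs"))
  ev <- threshold_and_clean(track, config)
  new_consensus_events(
    tibble::as_tibble(ev),
    gct = config$gct,
    subtype = if (is.null(subtype)) "all" else paste(subtype, collapse = "+"),
    n_scorers = length(rest),
    gold_standard = FALSE
  )
}

#' @export
print.consensus_events <- function(x, ...) {
  cat(sprintf(
    "<consensus_events>%s %d events | panel %s (n=%s) | gct=%s\n",
    if (isTRUE(attr(x, "gold_standard"))) " [gold standard]" else "",
    nrow(x), attr(x, "subtype"), attr(x, "n_scorers"), attr(x, "gct")
  ))
  NextMethod()
}
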