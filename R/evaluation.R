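#' Intersection-over-union of two time intervals
#'
#' The overlap measure used for event matching: length of the intersection of
#' the two intervals divided by the length of their union. 1 for identical
#' intervals, 0 for disjoint ones. Vectorized over events.
#'
#' @param onset_a,duration_a,onset_b,duration_b Interval coordinates in
#'   seconds (half-open `[onset, onset + duration)`).
#' @return IoU fraction(s) in `[0, 1]`.
#' @examples
#' iou_overlap(0, 1, 0.5, 1) # 1/3
#' @export
iou_overlap <- function(onset_a, duration_a, onset_b, duration_b) {
  if (any(duration_a <= 0) || any(duration_b <= 0)) {
    stop("durations must be positive.", call. = FALSE)
  }
  end_a <- onset_a + duration_a
  end_b <- onset_b + duration_b
  inter <- pmax(pmin(end_a, end_b) - pmax(onset_a, onset_b), 0)
  # for overlapping intervals the union is one spanning interval; computing
  # it from the endpoints keeps IoU exactly 1 for identical intervals
  union <- pmax(end_a, end_b) - pmin(onset_a, onset_b)
  ifelse(inter > 0, inter / union, 0)
}

check_event_list <- function(x, what) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(onset_s = numeric(), duration_s = numeric()))
  }
  if (!all(c("onset_s", "duration_s") %in% names(x))) {
    stop(what, " must have columns onset_s, duration_s.", call. = FALSE)
  }
  x <- x[order(x$onset_s), ]
  if (any(x$duration_s <= 0)) stop(what, ": durations must be positive.", call. = FALSE)
  ends <- x$onset_s + x$duration_s
  if (nrow(x) > 1 && any(x$onset_s[-1] < ends[-nrow(x)] - 1e-9)) {
    i <- which(x$onset_s[-1] < ends[-nrow(x)] - 1e-9)[1]
    stop(sprintf(
      "%s contains overlapping events (rows %d and %d, around %.3f s).",
      what, i, i + 1L, x$onset_s[i + 1L]
    ), call. = FALSE)
  }
  x
}

#' Event-level matching of detections against reference spindles
#'
#' Greedy one-to-one matching by overlap: among all unmatched
#' (event, detection) pairs with IoU at or above `overlap_threshold`, the pair
#' with the globally greatest IoU is matched and removed, repeatedly, until no
#' pair qualifies. A reference event can absorb at most one detection; extra
#' detections overlapping an already-matched event count as false positives.
#' IoU ties are broken by earlier event onset, then earlier detection onset.
#'
#' @param gs_events Reference (e.g. gold standard) events: tibble with
#'   `onset_s`, `duration_s`, sorted and non-overlapping.
#' @param detections Candidate events in the same format.
#' @param overlap_threshold Minimum IoU for a match, default 0.2.
#' @return A `match_result` with counts (`tp`, `fp`, `fn`), the matched pairs
#'   and derived `precision`, `recall`, `f1`. Use [tidy()] for the pair table
#'   and [glance()] for the one-row metric summary.
#' @examples
#' gs <- tibble::tibble(onset_s = c(1, 5), duration_s = c(1, 0.8))
#' det <- tibble::tibble(onset_s = c(1.1, 8), duration_s = c(1, 0.5))
#' glance(match_events(gs, det))
#' @export
match_events <- function(gs_events, detections, overlap_threshold = 0.2) {
  if (!(overlap_threshold >= 0 && overlap_threshold <= 1)) {
    stop("`overlap_threshold` must lie in [0, 1].", call. = FALSE)
  }
  gs <- check_event_list(gs_events, "gs_events")
  det <- check_event_list(detections, "detections")
  n_gs <- nrow(gs)
  n_det <- nrow(det)
  pairs <- NULL
  if (n_gs > 0 && n_det > 0) {
    # candidate pairs: restrict to overlapping combinations
    cand <- tidyr::expand_grid(ev = seq_len(n_gs), dt = seq_len(n_det))
    cand$iou <- iou_overlap(
      gs$onset_s[cand$ev], gs$duration_s[cand$ev],
      det$onset_s[cand$dt], det$duration_s[cand$dt]
    )
    cand <- cand[cand$iou >= overlap_threshold & cand$iou > 0, ]
    matched_ev <- integer(0)
    matched_dt <- integer(0)
    ious <- numeric(0)
    while (nrow(cand) > 0) {
      best <- order(-cand$iou, gs$onset_s[cand$ev], det$onset_s[cand$dt])[1]
      matched_ev <- c(matched_ev, cand$ev[best])
      matched_dt <- c(matched_dt, cand$dt[best])
      ious <- c(ious, cand$iou[best])
      cand <- cand[cand$ev != cand$ev[best] & cand$dt != cand$dt[best], ]
    }
    pairs <- tibble::tibble(
      gs_onset_s = gs$onset_s[matched_ev],
      gs_duration_s = gs$duration_s[matched_ev],
      det_onset_s = det$onset_s[matched_dt],
      det_duration_s = det$duration_s[matched_dt],
      iou = ious
    )
    pairs <- pairs[order(pairs$gs_onset_s), ]
    fp <- det[-matched_dt, c("onset_s", "duration_s"), drop = FALSE]
    fn <- gs[-matched_ev, c("onset_s", "duration_s"), drop = FALSE]
    if (length(matched_dt) == 0) fp <- det[, c("onset_s", "duration_s")]
    if (length(matched_ev) == 0) fn <- gs[, c("onset_s", "duration_s")]
  } else {
    pairs <- tibble::tibble(
      gs_onset_s = numeric(), gs_duration_s = numeric(),
      det_onset_s = numeric(), det_duration_s = numeric(), iou = numeric()
    )
    fp <- det[, c("onset_s", "duration_s")]
    fn <- gs[, c("onset_s", "duration_s")]
  }
  tp <- nrow(pairs)
  res <- list(
    matches = pairs,
    fp_detections = fp,
    fn_events = fn,
    tp = tp, fp = nrow(fp), fn = nrow(fn),
    overlap_threshold = overlap_threshold
  )
  res <- c(res, precision_recall_f1(tp = tp, fp = nrow(fp), fn = nrow(fn)))
  structure(res, class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d | FP %d | FN %d @ IoU >= %g\n  precision %.3f, recall %s, f1 %s\n",
    x$tp, x$fp, x$fn, x$overlap_threshold,
    x$precision,
    ifelse(is.na(x$recall), "undefined", sprintf("%.3f", x$recall)),
    ifelse(is.na(x$f1), "undefined", sprintf("%.3f", x$f1))
  ))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `f1 = 2 * precision * recall / (precision + recall)`. Degenerate cases
#' follow plotting-friendly conventions: precision is 0 when there are no
#' detections at all, recall is `NA` (undefined, flagged) when there are no
#' reference events, and f1 is 0 when `precision + recall == 0`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname match_events
#' @param x A `match_result`.
#' @param ... Unused.
#' @export
tidy.match_result <- function(x, ...) x$matches

#' @rdname match_events
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn,
    precision = x$precision, recall = x$recall, f1 = x$f1,
    overlap_threshold = x$overlap_threshold
  )
}

#' F1 as a function of the overlap threshold
#'
#' Re-matches the same detection list against the same reference at each
#' requested IoU threshold. Because raising the threshold can only invalidate
#' matches, the resulting f1 curve is non-increasing.
#'
#' @inheritParams match_events
#' @param thresholds Ascending IoU thresholds, default `seq(0, 1, 0.05)`.
#' @return An `overlap_sweep` tibble: `overlap_threshold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
sweep_overlap_threshold <- function(gs_events, detections,
                                    thresholds = seq(0, 1, by = 0.05)) {
  if (is.unsorted(thresholds)) stop("`thresholds` must be ascending.", call. = FALSE)
  out <- purrr::map_dfr(
    thresholds,
    function(th) glance(match_events(gs_events, detections, overlap_threshold = th))
  )
  structure(
    dplyr::relocate(out, "overlap_threshold"),
    class = c("overlap_sweep", class(tibble::tibble()))
  )
}

# flatten possibly-overlapping markings of one scorer into disjoint events
# (a marking drawn on both images of an epoch-overlap zone is one event)
flatten_events <- function(events) {
  ev <- tibble::as_tibble(events)[, c("onset_s", "duration_s")]
  if (nrow(ev) < 2) return(ev)
  ev <- ev[order(ev$onset_s), ]
  on <- ev$onset_s
  off <- ev$onset_s + ev$duration_s
  keep_on <- on[1]
  keep_off <- off[1]
  for (k in 2:length(on)) {
    m <- length(keep_on)
    if (on[k] <= keep_off[m] + 1e-9) {
      keep_off[m] <- max(keep_off[m], off[k])
    } else {
      keep_on <- c(keep_on, on[k])
      keep_off <- c(keep_off, off[k])
    }
  }
  tibble::tibble(onset_s = keep_on, duration_s = keep_off - keep_on)
}

#' Evaluate one scorer against the leave-one-out consensus
#'
#' The scorer's own markings (confidence ignored; overlapping markings of the
#' same stretch are flattened into single events) are matched against the
#' consensus of the rest of their panel.
#'
#' @inheritParams leave_one_out_consensus
#' @param scorer_id Scorer to evaluate.
#' @param eval_overlap Minimum IoU for a match, default 0.2.
#' @return One-row tibble: `scorer_id`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_individual <- function(annotations, scorer_id, subtype = "expert",
                                config = consensus_config(), eval_overlap = 0.2) {
  loo <- leave_one_out_consensus(annotations, scorer_id,
    subtype = subtype, config = config
  )
  own <- flatten_events(
    annotations$events[annotations$events$scorer_id == scorer_id, ]
  )
  res <- match_events(loo, own, overlap_threshold = eval_overlap)
  dplyr::mutate(glance(res), scorer_id = scorer_id, .before = 1)
}

#' Choose the group consensus threshold that maximizes expert agreement
#'
#' For each candidate threshold, every scorer of the panel is evaluated
#' against the leave-one-out consensus built at that threshold, and the mean
#' individual f1 across scorers is recorded. The returned `best_gct` is the
#' arg-max (smallest threshold on ties). Per-scorer rasterized tracks are
#' computed once and reused across the grid.
#'
#' @inheritParams build_group_consensus
#' @param gct_grid Candidate thresholds in `[0, 1)`, default
#'   `seq(0.05, 0.95, 0.05)`.
#' @param eval_overlap Minimum IoU for a match, default 0.2.
#' @param config Cleanup parameters ([consensus_config()]); its `gct` field is
#'   ignored in favour of `gct_grid`.
#' @return A list of class `gct_optimization`: `best_gct`, `curve` (tibble
#'   `gct`, `mean_f1`, `n_scorers`), `per_scorer` (tibble of individual f1 by
#'   `gct` and `scorer_id`).
#' @export
optimize_gct <- function(annotations, subtype = "expert",
                         gct_grid = seq(0.05, 0.95, by = 0.05),
                         eval_overlap = 0.2, config = consensus_config()) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (length(gct_grid) == 0) stop("`gct_grid` must not be empty.", call. = FALSE)
  if (any(gct_grid < 0 | gct_grid >= 1)) stop("`gct_grid` must lie in [0, 1).", call. = FALSE)
  ids <- panel_scorers(annotations, subtype)
  if (length(ids) < 2) {
    stop("threshold optimization needs at least 2 scorers in the panel.", call. = FALSE)
  }
  fs <- attr(annotations$grid, "fs")
  tracks <- scorer_tracks(annotations, ids)
  wsum <- Reduce(`+`, lapply(tracks, `[[`, "weight"))
  vsum <- Reduce(`+`, lapply(tracks, function(t) as.integer(t$viewed)))
  own_events <- lapply(ids, function(id) {
    flatten_events(annotations$events[annotations$events$scorer_id == id, ])
  })
  per <- purrr::map_dfr(sort(gct_grid), function(g) {
    cfg <- consensus_config(
      gct = g, merge_gap_s = config$merge_gap_s,
      min_duration_s = config$min_duration_s, max_duration_s = config$max_duration_s
    )
    purrr::map_dfr(seq_along(ids), function(i) {
      w <- wsum - tracks[[i]]$weight
      v <- vsum - as.integer(tracks[[i]]$viewed)
      track <- structure(
        list(score = ifelse(v > 0, w / pmax(v, 1L), 0), viewers = v, fs = fs),
        class = "score_track"
      )
      loo <- threshold_and_clean(track, cfg)
      res <- match_events(loo, own_events[[i]], overlap_threshold = eval_overlap)
      tibble::tibble(gct = g, scorer_id = ids[i], f1 = res$f1)
    })
  })
  curve <- per |>
    dplyr::group_by(.data$gct) |>
    dplyr::summarise(
      mean_f1 = mean(.data$f1, na.rm = TRUE),
      n_scorers = dplyr::n(), .groups = "drop"
    )
  best <- curve$gct[which.max(curve$mean_f1)] # which.max takes first (smallest) on ties
  structure(
    list(best_gct = best, curve = curve, per_scorer = per),
    class = "gct_optimization"
  )
}

#' @export
print.gct_optimization <- function(x, ...) {
  cat(sprintf(
    "<gct_optimization> best gct = %g (mean individual f1 = %.3f over %d grid points)\n",
    x$best_gct, max(x$curve$mean_f1), nrow(x$curve)
  ))
  invisible(x)
}

#' @rdname optimize_gct
#' @param x A `gct_optimization`.
#' @param ... Unused.
#' @export
tidy.gct_optimization <- function(x, ...) x$curve

#' @rdname optimize_gct
#' @export
glance.gct_optimization <- function(x, ...) {
  tibble::tibble(
    best_gct = x$best_gct,
    best_mean_f1 = max(x$curve$mean_f1),
    n_grid = nrow(x$curve)
  )
}
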