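#' Confidence labels and their score weights
#'
#' Each spindle marking carries the scorer's confidence that the marked
#' stretch really is a spindle. Confidence maps to the per-sample score weight
#' used when scorers are averaged into a group consensus: 1 for high, 0.75 for
#' medium, 0.5 for low; an unmarked sample contributes 0.
#'
#' @param label Character vector of confidence labels (case-insensitive).
#' @return Numeric weights in `[0.5, 1]`.
#' @examples
#' confidence_weight(c("high", "MEDIUM", "low"))
#' @export
confidence_weight <- function(label) {
  w <- c(high = 1, medium = 0.75, low = 0.5)
  key <- tolower(as.character(label))
  bad <- !key %in% names(w)
  if (any(bad)) {
    stop("unknown confidence label(s): ", paste(unique(label[bad]), collapse = ", "),
      " (expected high/medium/low).",
      call. = FALSE
    )
  }
  unname(w[key])
}

normalize_confidence <- function(label) {
  key <- tolower(as.character(label))
  confidence_weight(key) # validates
  key
}

#' Multi-scorer annotation set
#'
#' Bundles everything the consensus stage needs for one subject: the epoch
#' grid, a table of markings (one row per scored event) and a table of viewed
#' epochs. The views table is load-bearing: a scorer who viewed an epoch and
#' marked nothing contributes weight 0 there, while a scorer who never viewed
#' it is excluded from that epoch's averaging denominator.
#'
#' @param subject_id Subject identifier.
#' @param grid An [build_epoch_grid()] result.
#' @param events Tibble with columns `scorer_id`, `subtype` (one of
#'   "expert", "researcher", "nonexpert"), `epoch_id`, `onset_s`,
#'   `duration_s`, `confidence`.
#' @param views Tibble with columns `scorer_id`, `epoch_id` listing every
#'   epoch each scorer viewed (including epochs with no markings), and
#'   optionally a `subtype` column.
#' @param scorers Optional tibble `scorer_id`, `subtype` declaring the subtype
#'   of every scorer. Needed only for scorers who viewed epochs but marked no
#'   events (their subtype cannot be inferred from `events`); such scorers
#'   still count in the averaging denominator of their panel.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(subject_id, grid, events, views, scorers = NULL) {
  stopifnot(inherits(grid, "epoch_grid"))
  events <- tibble::as_tibble(events)
  views <- tibble::as_tibble(views)
  need_ev <- c("scorer_id", "subtype", "epoch_id", "onset_s", "duration_s", "confidence")
  if (!all(need_ev %in% names(events))) {
    stop("events must have columns: ", paste(need_ev, collapse = ", "), call. = FALSE)
  }
  if (!all(c("scorer_id", "epoch_id") %in% names(views))) {
    stop("views must have columns scorer_id, epoch_id.", call. = FALSE)
  }
  ok_sub <- c("expert", "researcher", "nonexpert")
  if (!all(events$subtype %in% ok_sub)) {
    stop("unknown scorer subtype(s): ",
      paste(setdiff(unique(events$subtype), ok_sub), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(events$duration_s <= 0)) stop("event durations must be > 0.", call. = FALSE)
  events$confidence <- normalize_confidence(events$confidence)
  bad_ep <- setdiff(unique(c(events$epoch_id, views$epoch_id)), grid$epoch_id)
  if (length(bad_ep) > 0) {
    stop("epoch id(s) not in grid: ", paste(bad_ep, collapse = ", "), call. = FALSE)
  }
  # every event must fall inside an epoch its scorer viewed
  ev_ep <- dplyr::left_join(events, as.data.frame(grid), by = "epoch_id")
  out_of_epoch <- ev_ep$onset_s < ev_ep$start_s - 1e-9 |
    ev_ep$onset_s + ev_ep$duration_s > ev_ep$end_s + 1e-9
  if (any(out_of_epoch)) {
    i <- which(out_of_epoch)[1]
    stop(sprintf(
      "event row %d (scorer %s, onset %.3f s) lies outside its epoch %s [%g, %g) s.",
      i, ev_ep$scorer_id[i], ev_ep$onset_s[i], ev_ep$epoch_id[i],
      ev_ep$start_s[i], ev_ep$end_s[i]
    ), call. = FALSE)
  }
  seen <- paste(events$scorer_id, events$epoch_id) %in%
    paste(views$scorer_id, views$epoch_id)
  if (!all(seen)) {
    i <- which(!seen)[1]
    stop(sprintf(
      "event row %d: scorer %s marked epoch %s but it is not in the views table.",
      i, events$scorer_id[i], events$epoch_id[i]
    ), call. = FALSE)
  }
  from_events <- dplyr::distinct(events, .data$scorer_id, .data$subtype)
  if (any(duplicated(from_events$scorer_id))) {
    dup <- from_events$scorer_id[duplicated(from_events$scorer_id)][1]
    stop("scorer ", dup, " appears with more than one subtype.", call. = FALSE)
  }
  if ("subtype" %in% names(views) && is.null(scorers)) {
    scorers <- dplyr::distinct(views, .data$scorer_id, .data$subtype)
  }
  if (is.null(scorers)) {
    scorers <- from_events
  } else {
    scorers <- tibble::as_tibble(scorers)
    mism <- dplyr::inner_join(from_events, scorers,
      by = "scorer_id", suffix = c("", ".decl")
    )
    if (any(mism$subtype != mism$subtype.decl)) {
      stop("declared scorer subtypes disagree with the events table.", call. = FALSE)
    }
  }
  silent <- setdiff(unique(views$scorer_id), scorers$scorer_id)
  if (length(silent) > 0) {
    scorers <- dplyr::bind_rows(
      scorers, tibble::tibble(scorer_id = silent, subtype = NA_character_)
    )
  }
  structure(
    list(
      subject_id = subject_id, grid = grid,
      events = events,
      views = dplyr::distinct(views[, c("scorer_id", "epoch_id")]),
      scorers = scorers
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> subject %s: %d scorers, %d events, %d epochs (%d blocks)\n",
    x$subject_id, length(unique(x$views$scorer_id)), nrow(x$events),
    nrow(x$grid), length(unique(x$grid$block))
  ))
  invisible(x)
}

# scorer ids belonging to a subtype panel (NULL filter = all scorers)
panel_scorers <- function(annotations, subtype_filter = NULL) {
  sc <- annotations$scorers
  if (is.null(subtype_filter)) return(sc$scorer_id)
  sc$scorer_id[!is.na(sc$subtype) & sc$subtype %in% subtype_filter]
}

#' Read annotations and views from tab-separated files
#'
#' The annotation dialect is a TSV with header
#' `subject_id scorer_id subtype epoch_id onset_s duration_s confidence`
#' plus a companion views TSV (`scorer_id epoch_id`) listing every epoch each
#' scorer viewed, including epochs where they marked nothing.
#'
#' @param path Annotation TSV path.
#' @param views_path Views TSV path.
#' @param grid The [build_epoch_grid()] the epoch ids refer to.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, views_path, grid) {
  if (!file.exists(views_path)) {
    stop("views file not found: ", views_path,
      " (a views table is mandatory; epochs viewed without markings count as weight 0).",
      call. = FALSE
    )
  }
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  vw <- readr::read_tsv(views_path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "scorer_id", "subtype", "epoch_id", "onset_s", "duration_s", "confidence")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0) {
    stop("annotation file ", path, " is missing column(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  key <- tolower(ev$confidence)
  bad <- !key %in% c("high", "medium", "low")
  if (any(bad)) {
    stop(sprintf(
      "%s line %d: unknown confidence label '%s'.",
      path, which(bad)[1] + 1L, ev$confidence[which(bad)[1]]
    ), call. = FALSE)
  }
  subj <- unique(ev$subject_id)
  if (length(subj) > 1) {
    stop("annotation file contains multiple subjects: ", paste(subj, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(subj) == 0) subj <- "unknown"
  set <- tryCatch(
    annotation_set(subj, grid,
      events = dplyr::select(ev, -"subject_id"),
      views = vw
    ),
    error = function(e) {
      stop("while validating ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  set
}

#' Write a spindle event list to TSV (and optionally BED)
#'
#' Events are serialized as a TSV (`subject_id onset_s duration_s score`) with
#' seconds printed to 3 decimals (millisecond precision, round-half-even), so
#' a write/read cycle is lossless at 1 ms. The optional BED export uses
#' 0-based half-open sample coordinates at `fs`.
#'
#' @param events Tibble with `onset_s`, `duration_s` and optionally `score`.
#' @param path Output TSV path.
#' @param subject_id Subject identifier column value.
#' @param bed_path Optional BED output path.
#' @param fs Sampling rate for BED sample coordinates, default 100.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, subject_id = "s1", bed_path = NULL, fs = 100) {
  events <- tibble::as_tibble(events)
  score <- if ("score" %in% names(events)) {
    events$score
  } else if ("peak_score" %in% names(events)) {
    events$peak_score
  } else {
    rep(NA_real_, nrow(events))
  }
  out <- tibble::tibble(
    subject_id = rep(subject_id, nrow(events)),
    onset_s = sprintf("%.3f", round(events$onset_s, 3)),
    duration_s = sprintf("%.3f", round(events$duration_s, 3)),
    score = ifelse(is.na(score), "NA", sprintf("%.4f", score))
  )
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(bed_path)) {
    bed <- tibble::tibble(
      chrom = rep(subject_id, nrow(events)),
      start = round(events$onset_s * fs),
      end = round((events$onset_s + events$duration_s) * fs),
      name = sprintf("spindle_%d", seq_len(max(nrow(events), 0)))
    )
    readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Read a spindle event list written by [write_events()]
#'
#' @param path TSV path.
#' @return Tibble with `subject_id`, `onset_s`, `duration_s`, `score`.
#' @export
read_events <- function(path) {
  readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      onset_s = readr::col_double(),
      duration_s = readr::col_double(),
      score = readr::col_double()
    )
  )
}
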