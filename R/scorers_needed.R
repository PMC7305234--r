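#' Panel-size threshold schedule
#'
#' When a partial consensus is built from only `n` scorers per epoch, the
#' group consensus threshold has to adapt: with a single scorer even a
#' low-confidence marking (weight 0.5) should survive, so the schedule starts
#' at 0.4 for one scorer per epoch and moves linearly to the panel's optimum
#' threshold at `n_opt` scorers, staying constant beyond.
#'
#' @param optimum Optimum threshold for the full panel, default 0.2.
#' @param n_opt Panel size at which the optimum applies, default 5.
#' @param start Threshold for a single scorer per epoch, default 0.4.
#' @return A function of the panel size `n` returning a threshold.
#' @examples
#' s <- gct_schedule_linear()
#' s(1) # 0.4
#' s(5) # 0.2
#' @export
gct_schedule_linear <- function(optimum = 0.2, n_opt = 5, start = 0.4) {
  force(optimum); force(n_opt); force(start)
  function(n) {
    if (n >= n_opt) return(optimum)
    if (n <= 1) return(start)
    start + (optimum - start) * (n - 1) / (n_opt - 1)
  }
}

#' How many scorers are needed: partial-consensus experiment
#'
#' For each panel size `n`, scorers are subsampled uniformly without
#' replacement per epoch among that epoch's viewers, a partial group
#' consensus is built with the threshold given by `gct_schedule(n)`, and its
#' event-level f1 against `reference_events` is recorded. The subsampling is
#' repeated `n_repeats` times so the spread across random scorer selections
#' is visible.
#'
#' If `n` exceeds the number of viewers on more than 5% of the epochs a
#' warning is issued and those epochs fall back to all their viewers.
#'
#' @inheritParams build_group_consensus
#' @param reference_events Reference event list to score against (e.g. a
#'   consensus from another panel).
#' @param n_list Panel sizes to test.
#' @param n_repeats Independent scorer draws per size, default 3.
#' @param gct_schedule Function mapping panel size to consensus threshold,
#'   default [gct_schedule_linear()].
#' @param eval_overlap Minimum IoU for a match, default 0.2.
#' @param seed Optional integer seed; fixes the scorer draws.
#' @return A `scorers_needed` tibble with one row per (n, repeat):
#'   `n_scorers`, `draw`, `gct`, `f1`, plus `precision` and `recall`.
#'   `summary(x)`-style aggregation is available via [tidy()] (mean and sd of
#'   f1 per panel size).
#' @export
scorers_needed_experiment <- function(annotations, reference_events, n_list,
                                      subtype = "expert", n_repeats = 3,
                                      gct_schedule = gct_schedule_linear(),
                                      eval_overlap = 0.2,
                                      config = consensus_config(),
                                      seed = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  ids <- panel_scorers(annotations, subtype)
  if (length(ids) == 0) stop("empty scorer panel.", call. = FALSE)
  grid <- annotations$grid
  fs <- attr(grid, "fs")
  views <- annotations$views[annotations$views$scorer_id %in% ids, ]
  viewers_by_epoch <- split(views$scorer_id, views$epoch_id)
  tracks <- scorer_tracks(annotations, ids)
  names(tracks) <- ids
  # per-epoch sample masks, reused across draws
  ep_mask <- lapply(seq_len(nrow(grid)), function(k) {
    r <- sample_range(grid$start_s[k], grid$end_s[k], fs)
    r[1]:r[2]
  })
  names(ep_mask) <- grid$epoch_id
  run <- function() {
    purrr::map_dfr(n_list, function(n) {
      short <- mean(vapply(viewers_by_epoch, length, integer(1)) < n)
      if (short > 0.05) {
        warning(sprintf(
          "panel size %d exceeds the viewer count on %.0f%% of epochs; those epochs fall back to all viewers.",
          n, 100 * short
        ), call. = FALSE)
      }
      g <- gct_schedule(n)
      cfg <- consensus_config(
        gct = g, merge_gap_s = config$merge_gap_s,
        min_duration_s = config$min_duration_s,
        max_duration_s = config$max_duration_s
      )
      purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
        # selection[[epoch]] = scorer ids contributing there this draw
        sel <- lapply(viewers_by_epoch, function(v) {
          if (length(v) <= n) v else sample(v, n)
        })
        nsamp <- grid_n_samples(grid)
        wsum <- numeric(nsamp)
        vcount <- integer(nsamp)
        for (ep in names(sel)) {
          idx <- ep_mask[[ep]]
          for (id in sel[[ep]]) {
            tr <- tracks[[id]]
            # a scorer counts once per sample even where epochs overlap
            fresh <- idx[!seen_mask[[id]][idx]]
            if (length(fresh) > 0) {
              wsum[fresh] <- wsum[fresh] + tr$weight[fresh]
              vcount[fresh] <- vcount[fresh] + 1L
              seen_mask[[id]][fresh] <<- TRUE
            }
          }
        }
        for (id in ids) seen_mask[[id]][] <<- FALSE
        track <- structure(
          list(
            score = ifelse(vcount > 0, wsum / pmax(vcount, 1L), 0),
            viewers = vcount, fs = fs
          ),
          class = "score_track"
        )
        pgc <- threshold_and_clean(track, cfg)
        res <- match_events(reference_events, pgc, overlap_threshold = eval_overlap)
        tibble::tibble(
          n_scorers = n, draw = rep_i, gct = g,
          precision = res$precision, recall = res$recall, f1 = res$f1
        )
      })
    })
  }
  seen_mask <- lapply(ids, function(i) logical(grid_n_samples(grid)))
  names(seen_mask) <- ids
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out, class = c("scorers_needed", class(tibble::tibble())))
}

#' @rdname scorers_needed_experiment
#' @param x A `scorers_needed` result.
#' @param ... Unused.
#' @export
tidy.scorers_needed <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$n_scorers) |>
    dplyr::summarise(
      mean_f1 = mean(.data$f1),
      sd_f1 = stats::sd(.data$f1),
      n_draws = dplyr::n(),
      .groups = "drop"
    )
}
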