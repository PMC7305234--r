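#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an overlap-threshold sweep
#'
#' F1 (with precision and recall) as a function of the IoU threshold used for
#' event matching.
#'
#' @param object An `overlap_sweep` from [sweep_overlap_threshold()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$overlap_threshold, y = .data$value,
    colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "overlap threshold (IoU)", y = NULL,
      title = "Event-matching performance vs overlap threshold"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a group-consensus threshold optimization curve
#'
#' @param object A `gct_optimization` from [optimize_gct()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gct_optimization <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$gct, y = .data$mean_f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_gct, linetype = 2) +
    ggplot2::labs(
      x = "group consensus threshold",
      y = "mean individual f1 (leave-one-out)",
      title = sprintf("Consensus threshold optimization (best = %g)", object$best_gct)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the scorers-needed experiment
#'
#' Mean f1 of the partial consensus against the reference, by panel size,
#' with a ribbon of +/- 1 sd across random scorer draws.
#'
#' @param object A `scorers_needed` tibble from [scorers_needed_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scorers_needed <- function(object, ...) {
  s <- tidy(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n_scorers, y = .data$mean_f1)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_f1 - .data$sd_f1,
        ymax = .data$mean_f1 + .data$sd_f1
      ),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "scorers per epoch", y = "f1 vs reference",
      title = "Partial group consensus performance vs panel size"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cohort dominant-frequency histogram
#'
#' @param object A `frequency_histogram` from [frequency_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frequency_histogram <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$bin_mid, y = .data$count)
  ) +
    ggplot2::geom_col(width = if (nrow(object) > 1) diff(object$bin_mid[1:2]) else 0.25) +
    ggplot2::labs(
      x = "dominant oscillation frequency (Hz)", y = "subjects",
      title = "Cohort dominant spindle frequency"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a consensus score track with its events
#'
#' @param track A `score_track` from [average_scores()].
#' @param events Optional `consensus_events` to overlay.
#' @param gct Optional threshold line.
#' @param window_s Optional `c(from, to)` time window in seconds.
#' @return A ggplot.
#' @export
plot_score_track <- function(track, events = NULL, gct = NULL, window_s = NULL) {
  d <- as_tibble(track)
  if (!is.null(window_s)) {
    d <- d[d$time_s >= window_s[1] & d$time_s < window_s[2], ]
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "mean weighted score",
      title = "Group consensus score track"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(gct)) p <- p + ggplot2::geom_hline(yintercept = gct, linetype = 2)
  if (!is.null(events) && nrow(events) > 0) {
    ev <- tibble::as_tibble(events)
    if (!is.null(window_s)) {
      ev <- ev[ev$onset_s < window_s[2] & ev$onset_s + ev$duration_s > window_s[1], ]
    }
    p <- p + ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(
        xmin = .data$onset_s, xmax = .data$onset_s + .data$duration_s,
        ymin = 0, ymax = 1
      ),
      alpha = 0.15, fill = "orange"
    )
  }
  p
}
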