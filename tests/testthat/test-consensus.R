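test_that("rasterization follows the half-open sample convention", {
  grid <- build_epoch_grid(0)
  ev <- tibble::tibble(
    epoch_id = "b0e0", onset_s = 1.00, duration_s = 0.50, confidence = "high"
  )
  tr <- rasterize_scorer(ev, grid$epoch_id, grid)
  # [1.00, 1.50) at 100 Hz -> samples 101..150 (1-based)
  expect_true(all(tr$weight[101:150] == 1))
  expect_true(all(tr$weight[-(101:150)] == 0))
  expect_true(all(tr$viewed))
})

test_that("a scorer's highest score wins where overlapping epochs cover the same instant", {
  grid <- build_epoch_grid(0)
  # same stretch in the b0e0/b0e1 overlap zone marked on both images
  ev <- tibble::tibble(
    epoch_id = c("b0e0", "b0e1"),
    onset_s = c(23.0, 23.0), duration_s = c(1, 1),
    confidence = c("high", "low")
  )
  tr <- rasterize_scorer(ev, grid$epoch_id, grid)
  expect_true(all(tr$weight[2301:2400] == 1.0))
})

test_that("unviewed epochs are excluded and eventless scorers give zero tracks", {
  grid <- build_epoch_grid(0)
  tr <- rasterize_scorer(
    tibble::tibble(
      epoch_id = character(), onset_s = numeric(),
      duration_s = numeric(), confidence = character()
    ),
    viewed_epochs = c("b0e0", "b0e1"), grid
  )
  expect_true(all(tr$weight == 0))
  expect_true(all(tr$viewed[1:4750]))
  expect_false(any(tr$viewed[4751:11500]))
})

test_that("averaging divides by the number of viewers at each sample", {
  grid <- build_epoch_grid(0)
  mark <- tibble::tibble(
    epoch_id = "b0e0", onset_s = 2, duration_s = 1, confidence = "high"
  )
  none <- tibble::tibble(
    epoch_id = character(), onset_s = numeric(),
    duration_s = numeric(), confidence = character()
  )
  tracks4 <- c(
    list(rasterize_scorer(mark, grid$epoch_id, grid)),
    replicate(3, rasterize_scorer(none, grid$epoch_id, grid), simplify = FALSE)
  )
  s4 <- average_scores(tracks4)
  expect_equal(max(s4$score), 0.25) # 1 of 4 viewers marks high
  mark_low <- dplyr::mutate(mark, confidence = "low")
  tracks5 <- c(
    list(rasterize_scorer(mark_low, grid$epoch_id, grid)),
    replicate(4, rasterize_scorer(none, grid$epoch_id, grid), simplify = FALSE)
  )
  s5 <- average_scores(tracks5)
  expect_equal(max(s5$score), 0.1) # 0.5 of 5 viewers
  expect_true(all(s5$viewers == 5))
  # unanimity saturates at 1
  tracks_u <- replicate(6, rasterize_scorer(mark, grid$epoch_id, grid), simplify = FALSE)
  expect_equal(max(average_scores(tracks_u)$score), 1)
})

test_that("samples nobody viewed have score 0 and count 0, not an error", {
  grid <- build_epoch_grid(0)
  tr <- rasterize_scorer(
    tibble::tibble(
      epoch_id = "b0e0", onset_s = 2, duration_s = 1, confidence = "high"
    ),
    viewed_epochs = "b0e0", grid
  )
  s <- average_scores(list(tr))
  expect_true(all(s$score[s$viewers == 0] == 0))
  expect_gt(sum(s$viewers == 0), 0)
})

test_that("thresholding merges short adjacent candidates then filters durations", {
  fs <- 100
  score <- numeric(300)
  score[101:120] <- 1 # [1.0, 1.2): 0.2 s, too short
  score[126:150] <- 1 # [1.25, 1.5): gap 0.05 s
  track <- structure(
    list(score = score, viewers = rep(1L, 300), fs = fs),
    class = "score_track"
  )
  ev <- threshold_and_clean(track, consensus_config(gct = 0.5))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$onset_s, 1.0)
  expect_equal(ev$duration_s, 0.5)

  # isolated too-short candidate is removed
  score2 <- numeric(300)
  score2[101:125] <- 1 # 0.25 s
  track2 <- structure(
    list(score = score2, viewers = rep(1L, 300), fs = fs),
    class = "score_track"
  )
  expect_identical(nrow(threshold_and_clean(track2, consensus_config(gct = 0.5))), 0L)

  # over-long candidate is removed
  score3 <- numeric(400)
  score3[101:360] <- 1 # 2.6 s
  track3 <- structure(
    list(score = score3, viewers = rep(1L, 400), fs = fs),
    class = "score_track"
  )
  expect_identical(nrow(threshold_and_clean(track3, consensus_config(gct = 0.5))), 0L)
})

test_that("a unanimous panel reproduces its input at any threshold below 1", {
  events <- tibble::tibble(onset_s = c(3, 30, 60.25), duration_s = c(0.8, 1.2, 0.5))
  anns <- unanimous_panel(events, n_scorers = 3)
  for (gct in c(0, 0.2, 0.5, 0.9, 0.99)) {
    gc <- build_group_consensus(anns, "expert", consensus_config(gct = gct))
    expect_equal(gc$onset_s, events$onset_s, tolerance = 1e-6)
    expect_equal(gc$duration_s, events$duration_s, tolerance = 1e-6)
    expect_true(all(gc$peak_score == 1))
  }
})

test_that("a single high-confidence scorer clears gct 0.4 but a high gct empties the consensus", {
  events <- tibble::tibble(onset_s = 5, duration_s = 1)
  solo <- unanimous_panel(events, n_scorers = 1)
  expect_identical(nrow(build_group_consensus(solo, "expert", consensus_config(gct = 0.4))), 1L)
  # 1 marker among 4 viewers -> score 0.25 < 0.99
  quad <- hand_panel(list(
    tibble::tibble(onset_s = 5, duration_s = 1, confidence = "high"),
    NULL, NULL, NULL
  ))
  expect_identical(nrow(build_group_consensus(quad, "expert", consensus_config(gct = 0.99))), 0L)
})

test_that("an empty panel is an explicit error", {
  anns <- unanimous_panel(tibble::tibble(onset_s = 5, duration_s = 1), n_scorers = 2)
  expect_error(build_group_consensus(anns, "researcher"), "no scorers of subtype")
})

test_that("leave-one-out removes the scorer from numerator and denominator", {
  events <- tibble::tibble(onset_s = c(5, 40), duration_s = c(0.8, 1))
  two <- unanimous_panel(events, n_scorers = 2)
  loo <- leave_one_out_consensus(two, "sc01", config = consensus_config(gct = 0.4))
  solo_gc <- build_group_consensus(
    unanimous_panel(events, n_scorers = 1), "expert",
    consensus_config(gct = 0.4)
  )
  expect_equal(loo$onset_s, solo_gc$onset_s)
  expect_equal(loo$duration_s, solo_gc$duration_s)

  # sole marker excluded -> the event vanishes even at gct 0
  panel <- hand_panel(list(
    tibble::tibble(onset_s = 5, duration_s = 1, confidence = "high"),
    NULL, NULL, NULL, NULL
  ))
  loo2 <- leave_one_out_consensus(panel, "sc01", config = consensus_config(gct = 0))
  expect_identical(nrow(loo2), 0L)

  expect_error(leave_one_out_consensus(two, "nobody"), "not a member")
  solo <- unanimous_panel(events, n_scorers = 1)
  expect_error(leave_one_out_consensus(solo, "sc01"), "single-scorer")
})

test_that("raising the threshold only shrinks the candidate sample set", {
  sim <- simulate_eeg(n_blocks = 1, seed = 3)
  anns <- simulate_panel(sim$truth, sim$grid,
    n_scorers = 5, sensitivity = 0.8,
    fp_rate_per_min = 1, confidence_noise = 0.3, seed = 4
  )
  ids <- spindler:::panel_scorers(anns, "expert")
  tracks <- spindler:::scorer_tracks(anns, ids)
  track <- average_scores(tracks)
  prev <- track$score > 0
  for (gct in c(0.1, 0.2, 0.4, 0.6, 0.8)) {
    cur <- track$score > gct
    expect_true(all(!cur | prev)) # cur subset of prev
    prev <- cur
  }
})

test_that("upgrading a marking's confidence never removes consensus samples", {
  base_marks <- list(
    tibble::tibble(onset_s = c(5, 40), duration_s = c(0.8, 1), confidence = c("low", "medium")),
    tibble::tibble(onset_s = 5.1, duration_s = 0.7, confidence = "medium"),
    tibble::tibble(onset_s = 40.2, duration_s = 0.9, confidence = "low")
  )
  up_marks <- base_marks
  up_marks[[1]]$confidence <- c("high", "high") # upgrade scorer 1
  gct <- 0.3
  score_of <- function(marks) {
    anns <- hand_panel(marks)
    tracks <- spindler:::scorer_tracks(anns, spindler:::panel_scorers(anns))
    average_scores(tracks)$score
  }
  s_base <- score_of(base_marks)
  s_up <- score_of(up_marks)
  expect_true(all(s_up >= s_base - 1e-12))
  expect_true(all((s_base > gct) <= (s_up > gct)))
})

test_that("consensus output durations always respect the duration bounds", {
  sim <- simulate_eeg(n_blocks = 2, seed = 5)
  anns <- simulate_panel(sim$truth, sim$grid,
    n_scorers = 6, sensitivity = 0.7,
    jitter_sd = 0.15, fp_rate_per_min = 2, seed = 6
  )
  for (gct in c(0, 0.1, 0.3)) {
    gc <- build_group_consensus(anns, "expert", consensus_config(gct = gct))
    if (nrow(gc) > 0) {
      expect_true(all(gc$duration_s >= 0.3 - 1e-9))
      expect_true(all(gc$duration_s <= 2.5 + 1e-9))
      # non-overlapping and sorted
      expect_true(all(diff(gc$onset_s) > 0))
      expect_true(all(gc$onset_s[-1] >= (gc$onset_s + gc$duration_s)[-nrow(gc)] - 1e-9))
    }
  }
})
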