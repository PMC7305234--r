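test_that("interval IoU follows intersection over union", {
  expect_equal(iou_overlap(0, 1, 0, 1), 1)
  expect_equal(iou_overlap(0, 1, 2, 1), 0)
  expect_equal(iou_overlap(0, 1, 0.5, 1), 1 / 3)
  expect_error(iou_overlap(0, 0, 0, 1), "positive")
})

test_that("matching handles the canonical fixtures", {
  gs <- tibble::tibble(onset_s = 0, duration_s = 1)
  det <- tibble::tibble(onset_s = 0.1, duration_s = 1)
  r <- match_events(gs, det, 0.2)
  expect_identical(c(r$tp, r$fp, r$fn), c(1L, 0L, 0L))

  # two detections halving one event: tie at IoU 0.5 resolved to the earlier
  # detection; the other is a false positive
  det2 <- tibble::tibble(onset_s = c(0, 0.5), duration_s = c(0.5, 0.5))
  r2 <- match_events(gs, det2, 0.2)
  expect_identical(c(r2$tp, r2$fp, r2$fn), c(1L, 1L, 0L))
  expect_equal(r2$matches$det_onset_s, 0)
  expect_equal(r2$fp_detections$onset_s, 0.5)

  # no detections: everything is a miss, f1 collapses to 0
  r3 <- match_events(gs, tibble::tibble(onset_s = numeric(), duration_s = numeric()), 0.2)
  expect_identical(c(r3$tp, r3$fp, r3$fn), c(0L, 0L, 1L))
  expect_equal(r3$precision, 0)
  expect_equal(r3$recall, 0)
  expect_equal(r3$f1, 0)
})

test_that("overlapping events within one list violate the matcher's contract", {
  bad <- tibble::tibble(onset_s = c(0, 0.5), duration_s = c(1, 1))
  good <- tibble::tibble(onset_s = 3, duration_s = 1)
  expect_error(match_events(bad, good), "overlapping")
  expect_error(match_events(good, bad), "overlapping")
})

test_that("precision/recall/f1 identities hold", {
  m <- precision_recall_f1(tp = 2, fp = 1, fn = 2)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1 / 2)
  expect_equal(m$f1, 4 / 7)
  # harmonic-mean identity: p = r = x gives f1 = x
  for (x in c(0.2, 0.5, 0.9)) {
    tp <- round(100 * x)
    m2 <- precision_recall_f1(tp, 100 - tp, 100 - tp)
    expect_equal(m2$f1, x)
  }
  expect_equal(precision_recall_f1(0, 5, 3)$f1, 0)
  expect_true(is.na(precision_recall_f1(0, 5, 0)$recall))
})

test_that("the production matcher agrees with the brute-force oracle", {
  set.seed(20)
  for (i in 1:300) {
    gs <- random_event_list(8)
    det <- random_event_list(8)
    thr <- sample(c(0.01, 0.2, 0.5, 0.9), 1)
    r <- match_events(gs, det, thr)
    o <- brute_force_match(gs, det, thr)
    expect_identical(c(r$tp, r$fp, r$fn), c(o$tp, o$fp, o$fn))
  }
})

test_that("matching invariants hold on random instances", {
  set.seed(21)
  for (i in 1:100) {
    gs <- random_event_list(6)
    det <- random_event_list(6)
    r <- match_events(gs, det, 0.2)
    expect_lte(r$tp, min(nrow(gs), nrow(det)))
    if (!is.na(r$f1)) expect_true(r$f1 >= 0 && r$f1 <= 1)
    # one-to-one: no event or detection appears twice
    expect_false(any(duplicated(r$matches$gs_onset_s)))
    expect_false(any(duplicated(r$matches$det_onset_s)))
  }
})

test_that("self-matching is perfect at any threshold", {
  set.seed(22)
  x <- random_event_list(8)
  x <- x[x$duration_s > 0, ]
  for (thr in c(0, 0.5, 1)) {
    r <- match_events(x, x, thr)
    expect_identical(r$fp + r$fn, 0L)
    if (nrow(x) > 0) expect_equal(r$f1, 1)
  }
})

test_that("the f1 curve is non-increasing in the overlap threshold", {
  set.seed(23)
  gs <- random_event_list(10, span = 40)
  det <- random_event_list(10, span = 40)
  sw <- sweep_overlap_threshold(gs, det, seq(0, 1, 0.1))
  f1s <- ifelse(is.na(sw$f1), 0, sw$f1)
  expect_true(all(diff(f1s) <= 1e-12))
  # each sweep point equals an independent re-match at that threshold
  for (k in seq_len(nrow(sw))) {
    fresh <- match_events(gs, det, sw$overlap_threshold[k])
    expect_equal(sw$f1[k], fresh$f1)
  }
  # perfect detections: flat at 1
  sw2 <- sweep_overlap_threshold(gs, gs, c(0, 0.5, 1))
  if (nrow(gs) > 0) expect_true(all(sw2$f1 == 1))
})

test_that("individual evaluation composes leave-one-out consensus with matching", {
  events <- tibble::tibble(onset_s = c(3, 30, 60), duration_s = c(0.8, 1.2, 0.6))
  anns <- unanimous_panel(events, n_scorers = 4)
  ei <- evaluate_individual(anns, "sc01", config = consensus_config(gct = 0.2))
  expect_equal(ei$f1, 1) # clone of a unanimous panel

  # compositional oracle on an imperfect panel
  sim <- simulate_eeg(n_blocks = 1, seed = 31)
  anns2 <- simulate_panel(sim$truth, sim$grid,
    n_scorers = 5, sensitivity = 0.8,
    fp_rate_per_min = 1, seed = 32
  )
  ei2 <- evaluate_individual(anns2, "scorer03", config = consensus_config(gct = 0.2))
  loo <- leave_one_out_consensus(anns2, "scorer03", config = consensus_config(gct = 0.2))
  own <- spindler:::flatten_events(
    anns2$events[anns2$events$scorer_id == "scorer03", ]
  )
  direct <- match_events(loo, own, 0.2)
  expect_equal(ei2$f1, direct$f1)
  expect_identical(c(ei2$tp, ei2$fp, ei2$fn), c(direct$tp, direct$fp, direct$fn))
})

test_that("a scorer who marked nothing scores recall 0 against a non-empty reference", {
  marks <- list(
    tibble::tibble(onset_s = c(5, 40), duration_s = c(0.8, 1), confidence = c("high", "high")),
    tibble::tibble(onset_s = c(5, 40), duration_s = c(0.8, 1), confidence = c("high", "high")),
    NULL
  )
  anns <- hand_panel(marks)
  ei <- evaluate_individual(anns, "sc03", config = consensus_config(gct = 0.2))
  expect_equal(ei$recall, 0)
  expect_equal(ei$f1, 0)
})

test_that("gct optimization returns the grid arg-max with the smallest-tie rule", {
  events <- tibble::tibble(onset_s = c(3, 30), duration_s = c(0.8, 1.2))
  anns <- unanimous_panel(events, n_scorers = 3)
  og <- optimize_gct(anns, gct_grid = seq(0.1, 0.9, 0.2))
  expect_equal(og$best_gct, 0.1) # flat curve -> smallest grid value
  expect_true(all(og$curve$mean_f1 == 1))

  sim <- simulate_eeg(n_blocks = 1, seed = 33)
  anns2 <- simulate_panel(sim$truth, sim$grid,
    n_scorers = 5, sensitivity = 0.85,
    fp_rate_per_min = 1, confidence_noise = 0.2, seed = 34
  )
  og2 <- optimize_gct(anns2, gct_grid = seq(0.05, 0.95, 0.1))
  best_val <- og2$curve$mean_f1[og2$curve$gct == og2$best_gct]
  expect_true(all(best_val >= og2$curve$mean_f1 - 1e-12))
  # full-scan oracle: each curve point equals the direct mean of
  # evaluate_individual across scorers at that threshold
  g_probe <- og2$curve$gct[3]
  direct <- mean(purrr::map_dbl(
    sprintf("scorer%02d", 1:5),
    function(id) {
      evaluate_individual(anns2, id, config = consensus_config(gct = g_probe))$f1
    }
  ))
  expect_equal(og2$curve$mean_f1[og2$curve$gct == g_probe], direct)

  expect_error(optimize_gct(anns2, gct_grid = numeric(0)), "empty")
  solo <- unanimous_panel(events, n_scorers = 1)
  expect_error(optimize_gct(solo), "at least 2")
})

test_that("the scorers-needed experiment is deterministic and exact at full panel size", {
  sim <- simulate_eeg(n_blocks = 1, seed = 35)
  anns <- simulate_panel(sim$truth, sim$grid,
    n_scorers = 5, sensitivity = 0.9,
    fp_rate_per_min = 0.5, seed = 36
  )
  sched <- gct_schedule_linear(optimum = 0.2, n_opt = 5, start = 0.4)
  expect_equal(sched(1), 0.4)
  expect_equal(sched(5), 0.2)
  expect_equal(sched(3), 0.3)
  expect_equal(sched(10), 0.2)
  sn1 <- scorers_needed_experiment(anns, sim$truth,
    n_list = c(1, 3, 5),
    gct_schedule = sched, seed = 99
  )
  sn2 <- scorers_needed_experiment(anns, sim$truth,
    n_list = c(1, 3, 5),
    gct_schedule = sched, seed = 99
  )
  expect_identical(as.data.frame(sn1), as.data.frame(sn2))
  # at n = panel size every draw is the full panel: zero spread, equals full GC
  full <- match_events(
    sim$truth,
    build_group_consensus(anns, "expert", consensus_config(gct = 0.2)),
    0.2
  )
  s5 <- tidy(sn1)
  expect_equal(s5$sd_f1[s5$n_scorers == 5], 0)
  expect_equal(s5$mean_f1[s5$n_scorers == 5], full$f1)
})

test_that("panel sizes beyond the viewer count trigger the documented fallback warning", {
  sim <- simulate_eeg(n_blocks = 1, seed = 37)
  anns <- simulate_panel(sim$truth, sim$grid, n_scorers = 3, seed = 38)
  expect_warning(
    scorers_needed_experiment(anns, sim$truth, n_list = 5, seed = 39),
    "fall back to all viewers"
  )
})
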