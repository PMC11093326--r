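test_that("the EMA motion vector folds displacements as specified", {
  expect_equal(ema_velocity(matrix(numeric(), ncol = 2), 0.5), c(0, 0))
  # constant displacement is a fixed point for any alpha
  for (a in c(0.1, 0.5, 0.9))
    expect_equal(ema_velocity(rbind(c(2, 0), c(2, 0), c(2, 0)), a), c(2, 0))
  # one update step from a previous EMA of (0,0)
  expect_equal(ema_velocity(rbind(c(0, 0), c(4, 0)), 0.5), c(2, 0))
})

test_that("predict_motion reads a track's history", {
  tr <- list(hist_frames = 3L, hist_centers = matrix(c(1, 1), 1))
  expect_equal(predict_motion(tr, 0.5), c(0, 0))   # single observation
  tr2 <- list(hist_frames = c(1L, 2L, 3L),
              hist_centers = rbind(c(0, 0), c(2, 0), c(4, 0)))
  expect_equal(predict_motion(tr2, 0.7), c(2, 0))
  expect_error(predict_motion(list(hist_frames = integer()), 0.5), "empty")
})

test_that("greedy matching is gated, score-ordered and deterministic", {
  # in gate
  m <- greedy_match(data.frame(cx = 10, cy = 10, score = 1),
                    data.frame(px = 11, py = 10, gate = 5, id = 1))
  expect_equal(nrow(m$matches), 1L)
  # out of gate
  m <- greedy_match(data.frame(cx = 100, cy = 100, score = 1),
                    data.frame(px = 0, py = 0, gate = 5, id = 1))
  expect_equal(nrow(m$matches), 0L)
  expect_equal(m$unmatched_dets, 1L)
  expect_equal(m$unmatched_cands, 1L)
  # two detections, two candidates: higher score picks first and takes the
  # nearest candidate, the second detection gets the remaining one
  dets <- data.frame(cx = c(0, 1), cy = c(0, 0), score = c(0.9, 0.8))
  cand <- data.frame(px = c(0.4, 3), py = c(0, 0), gate = c(5, 5),
                     id = c(1, 2))
  m <- greedy_match(dets, cand)
  expect_equal(m$matches[order(m$matches[, 1]), , drop = FALSE],
               cbind(det = 1:2, cand = 1:2), ignore_attr = TRUE)
  # exact distance ties resolve to the lower track id
  m <- greedy_match(data.frame(cx = 0, cy = 0, score = 1),
                    data.frame(px = c(1, -1), py = c(0, 0), gate = c(5, 5),
                               id = c(7, 3)))
  expect_equal(unname(m$matches[1, 2]), 2L)   # candidate row 2 has id 3
  expect_error(greedy_match(dets, data.frame(px = 0, py = 0, gate = 0,
                                             id = 1)),
               "gate")
})

test_that("the stranding area drifts, ages and expires", {
  adv <- advance_stranding(list())
  expect_length(adv$stranded, 0)
  tr <- list(id = 1L, center = c(10, 10), velocity = c(2, 0), health = 3L)
  adv <- advance_stranding(list(tr))
  expect_equal(adv$stranded[[1]]$center, c(12, 10))
  expect_equal(adv$stranded[[1]]$health, 2L)
  tr$health <- 1L
  adv <- advance_stranding(list(tr))
  expect_length(adv$stranded, 0)
  expect_equal(adv$terminated, 1L)
  # backward drift negates the motion vector
  tr$health <- 3L
  adv <- advance_stranding(list(tr), direction = "backward")
  expect_equal(adv$stranded[[1]]$center, c(8, 10))
})

test_that("a first frame founds one track per detection, ids 1..n", {
  dets <- frame_table(frame = 1, id = NA, cx = c(10, 50, 90),
                      cy = 10, w = 5, h = 5, score = 0.9)
  st <- two_stage_update(new_tracker_state(), dets, 1L)
  expect_equal(sort(st$out$id), 1:3)
  expect_length(st$state$active, 3)
  expect_error(two_stage_update(new_tracker_state(),
                                frame_table(frame = c(1, 2), id = NA,
                                            cx = c(1, 2), cy = 1, w = 1,
                                            h = 1, score = 1), 1L),
               "mixed frames")
})

make_gap_dets <- function(gap, n_frames = 60, drop_at = 20) {
  # one target moving at 4 px/frame; detections missing for `gap` frames
  frames <- seq_len(n_frames)
  keep <- !(frames %in% seq(drop_at, drop_at + gap - 1L))
  frame_table(frame = frames[keep], id = NA, cx = 100 + 4 * frames[keep],
              cy = 50, w = 20, h = 20, score = 0.9)
}

test_that("a short occlusion is bridged with the same identity", {
  dets <- make_gap_dets(gap = 5)
  res <- track_detections(dets, default_config())$result
  expect_equal(length(unique(res$id)), 1L)         # no new identity
  expect_equal(nrow(res), nrow(dets))
})

test_that("an occlusion longer than the lifespan founds a new identity", {
  dets <- make_gap_dets(gap = 25)
  res <- track_detections(dets, default_config())$result
  expect_equal(length(unique(res$id)), 2L)
  # the new identity begins exactly at re-detection
  expect_equal(min(res$frame[res$id == 2L]), 45L)
})

test_that("per-frame output ids are unique and ids never revive", {
  cfg <- default_config()
  scn <- simulate_scenario(cfg, seed = 42)
  tr <- track_detections(scn$det, cfg)
  res <- tr$result
  for (f in unique(res$frame))
    expect_false(anyDuplicated(res$id[res$frame == f]) > 0)
  # terminated ids never appear after their termination is recorded
  expect_true(all(tr$state$terminated <= tr$state$next_id - 1L))
  # conservation: every above-threshold detection is either matched or
  # founds a track, so output size equals the retained detection count
  kept <- sum(scn$det$score >= cfg$tracker$score_threshold)
  expect_equal(nrow(res), kept)
})

test_that("disabling stage 2 reduces to the pure greedy baseline", {
  cfg <- default_config()
  cfg$tracker$stage2 <- FALSE
  dets <- make_gap_dets(gap = 5)
  res <- track_detections(dets, cfg)$result
  expect_gt(length(unique(res$id)), 1L)            # identity lost at the gap
})
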