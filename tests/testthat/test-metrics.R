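box <- function(l, t, w, h) c(l + w / 2, t + h / 2, w, h)

test_that("IoU handles the canonical cases", {
  expect_equal(iou(box(0, 0, 2, 2), box(0, 0, 2, 2)), 1)
  expect_equal(iou(box(0, 0, 2, 2), box(10, 10, 2, 2)), 0)
  expect_equal(iou(box(0, 0, 2, 2), box(1, 0, 2, 2)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 2), box(0, 0, 2, 2)), "positive")
})

test_that("the assignment solver matches exhaustive enumeration", {
  set.seed(10)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n, 0, 10), n)
    a <- solve_assignment(C)
    expect_equal(sum(C[cbind(seq_len(n), a)]), oracle_assignment_cost(C))
    expect_equal(sort(a), seq_len(n))
  }
  # rectangular: every row assigned to a distinct column
  C <- matrix(runif(12), 3, 4)
  a <- solve_assignment(C)
  expect_equal(anyDuplicated(a), 0L)
})

test_that("perfect hypotheses score perfectly", {
  set.seed(11)
  inst <- random_instance()
  ev <- evaluate_tracking(inst$gt, inst$gt, 0.5)
  expect_equal(ev$mota, 1)
  expect_equal(ev$motp, 1)
  expect_equal(ev$idf1, 1)
  expect_equal(ev$idsw + ev$fp + ev$fn, 0L)
})

test_that("CLEAR and identity arithmetic match the printed formulas", {
  # 10 frames x 10 objects on a well-separated grid: GT = 100
  gt <- as_frame_table(do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, id = 1:10, cx = 100 * (1:10), cy = 50 + 2 * f,
               w = 10, h = 10, score = 1))))
  hyp <- as.data.frame(gt)
  # 5 missed boxes -> FN = 5
  hyp <- hyp[!(hyp$frame == 4 & hyp$id %in% 1:5), ]
  # 3 spurious boxes far from everything -> FP = 3
  hyp <- rbind(hyp, data.frame(frame = c(2, 5, 9), id = 90:92, cx = 5000,
                               cy = 50, w = 10, h = 10, score = 1))
  # two identity switches at frame 7 (new labels persist afterwards)
  sw <- hyp$frame >= 7 & hyp$id %in% c(1, 2)
  hyp$id[sw] <- hyp$id[sw] + 50L
  cm <- clear_mot(as_frame_table(gt), as_frame_table(hyp), 0.5)
  expect_equal(cm$gt, 100L)
  expect_equal(cm$fn, 5L)
  expect_equal(cm$fp, 3L)
  expect_equal(cm$idsw, 2L)
  expect_equal(cm$mota, 1 - (5 + 3 + 2) / 100)   # = 0.90
  # IDF1 from IDTP 8, IDFP 2, IDFN 2 -> 0.8
  gt1 <- frame_table(frame = 1:10, id = 1, cx = 10 + 3 * (1:10), cy = 20,
                     w = 8, h = 8)
  h1 <- as.data.frame(gt1)[1:8, ]; h1$id <- 4L
  h2 <- data.frame(frame = 9:10, id = 5L, cx = 900, cy = 900, w = 8, h = 8,
                   score = 1)
  im <- idf1(gt1, as_frame_table(rbind(h1, h2)), 0.5)
  expect_equal(im$idtp, 8L)
  expect_equal(im$idfp, 2L)
  expect_equal(im$idfn, 2L)
  expect_equal(im$idf1, 16 / 20)
})

test_that("evaluation errors on empty ground truth", {
  hyp <- frame_table(frame = 1, id = 1, cx = 1, cy = 1, w = 1, h = 1)
  expect_error(clear_mot(frame_table(), hyp), "undefined")
  expect_error(idf1(frame_table(), hyp), "undefined")
})

test_that("trajectory statistics classify tracked fractions and count
           interruptions", {
  gt <- frame_table(frame = 1:10, id = 1, cx = 10, cy = 10, w = 4, h = 4)
  # matched 9 of 10 -> MT; one interruption inside the lifespan
  hyp <- as.data.frame(gt); hyp <- hyp[-5, ]
  ts <- trajectory_stats(gt, as_frame_table(hyp), 0.5)
  expect_equal(ts$mt, 1L)
  expect_equal(ts$ml, 0L)
  expect_equal(ts$fm, 1L)                # T,U,T pattern
  # matched 1 of 10 -> ML
  hyp2 <- as.data.frame(gt)[1, , drop = FALSE]
  ts2 <- trajectory_stats(gt, as_frame_table(hyp2), 0.5)
  expect_equal(ts2$ml, 1L)
  expect_equal(ts2$mt, 0L)
})

test_that("all counts equal the brute-force oracle on random instances", {
  set.seed(12)
  n_bad <- 0L
  for (i in 1:60) {
    inst <- random_instance()
    if (nrow(inst$gt) == 0L) next
    cm <- clear_mot(inst$gt, inst$hyp, 0.5)
    oc <- oracle_clear_mot(as.data.frame(inst$gt), as.data.frame(inst$hyp),
                           0.5)
    expect_equal(cm$fn, oc$fn)
    expect_equal(cm$fp, oc$fp)
    expect_equal(cm$idsw, oc$idsw)
    expect_equal(cm$matches, oc$matches)
    expect_equal(cm$sum_iou, oc$sum_iou, tolerance = 1e-9)
    ts <- trajectory_stats(inst$gt, inst$hyp, 0.5, cm = cm)
    expect_equal(ts$mt, oc$mt)
    expect_equal(ts$ml, oc$ml)
    expect_equal(ts$fm, oc$fm)
    im <- idf1(inst$gt, inst$hyp, 0.5)
    oi <- oracle_idf1(as.data.frame(inst$gt), as.data.frame(inst$hyp), 0.5)
    expect_equal(im$idtp, oi$idtp)
    expect_equal(im$idf1, oi$idf1)
  }
})

test_that("metrics are invariant under hypothesis relabeling", {
  set.seed(13)
  inst <- random_instance()
  ev <- evaluate_tracking(inst$gt, inst$hyp, 0.5)
  hyp2 <- as.data.frame(inst$hyp)
  ids <- unique(hyp2$id)
  newids <- sample(1000:2000, length(ids))
  hyp2$id <- newids[match(hyp2$id, ids)]
  ev2 <- evaluate_tracking(inst$gt, as_frame_table(hyp2), 0.5)
  for (k in c("mota", "motp", "idf1", "idsw", "fp", "fn", "mt", "ml", "fm"))
    expect_equal(ev2[[k]], ev[[k]], tolerance = 1e-12)
})

test_that("deleting a matched hypothesis record never raises MOTA", {
  set.seed(14)
  for (i in 1:10) {
    inst <- random_instance()
    if (nrow(inst$gt) == 0L || nrow(inst$hyp) == 0L) next
    cm <- clear_mot(inst$gt, inst$hyp, 0.5)
    if (nrow(cm$match_log) == 0L) next
    pick <- cm$match_log[sample.int(nrow(cm$match_log), 1), ]
    hyp2 <- as.data.frame(inst$hyp)
    drop <- which(hyp2$frame == pick$frame & hyp2$id == pick$hyp_id)[1]
    hyp2 <- hyp2[-drop, , drop = FALSE]
    if (nrow(hyp2) == 0L) next
    cm2 <- clear_mot(inst$gt, as_frame_table(hyp2), 0.5)
    expect_lte(cm2$mota, cm$mota + 1e-12)
  }
})

test_that("MOTP lies between the gate and one whenever matches exist", {
  set.seed(15)
  for (i in 1:15) {
    inst <- random_instance()
    if (nrow(inst$gt) == 0L) next
    cm <- clear_mot(inst$gt, inst$hyp, 0.5)
    if (cm$matches == 0L) next
    expect_gte(cm$motp, 0.5)
    expect_lte(cm$motp, 1)
  }
})
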