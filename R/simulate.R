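#' Synthetic aerial-herd scenario simulation
#'
#' The generator emulates the statistical structure the tracker and filter
#' assume: herd animals moving on a flat pasture under a hovering UAV with
#' a nadir-pointing gimballed camera. Targets follow a first-order Markov
#' chain over three motion modes (straight, coordinated turn left/right);
#' the UAV pose jitters with Gaussian GPS (position) and INS (attitude)
#' errors; ground-truth boxes come from pinhole projection of each target's
#' footprint; detections are the ground truth after mutual-occlusion
#' dropouts, missed detections, centre/size noise, Beta-distributed
#' confidence scores and Poisson false positives. One master seed fixes
#' everything.
#'
#' @name simulate
NULL

#' Simulate ground-plane target trajectories
#'
#' Dispatches on `config$scenario$type`: `"markov"` (random mode-switching
#' herd), `"separated"` (parallel straight movers, deterministic),
#' `"crossing"` (two-target scripted overtake with an exact occlusion gap),
#' `"maneuvering"` (single target alternating straight legs and turns).
#'
#' @param config a `herd_config`.
#' @param seed integer seed; `NULL` leaves the RNG stream alone.
#' @return A long data frame of class `trajectory_set`: `target`, `frame`,
#'   `X`, `Y` (metres), `Vx`, `Vy`, `heading`, `mode`.
#' @export
simulate_targets <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sc <- config$scenario
  out <- switch(sc$type,
    markov = sim_targets_markov(sc),
    separated = sim_targets_separated(sc),
    crossing = sim_targets_crossing(sc),
    maneuvering = sim_targets_maneuvering(sc),
    stop("unknown scenario type: ", sc$type))
  class(out) <- c("trajectory_set", "data.frame")
  out
}

sim_targets_markov <- function(sc) {
  dt <- 1 / sc$frame_rate
  lo <- c(sc$margin, sc$margin); hi <- sc$arena - sc$margin
  modes <- c("straight", "turn_left", "turn_right")
  omega <- c(straight = 0, turn_left = sc$turn_rate,
             turn_right = -sc$turn_rate)
  rows <- vector("list", sc$n_targets)
  for (i in seq_len(sc$n_targets)) {
    x <- stats::runif(1, lo[1], hi[1]); y <- stats::runif(1, lo[2], hi[2])
    th <- stats::runif(1, -pi, pi)
    sp <- stats::runif(1, sc$speed_range[1], sc$speed_range[2])
    mode <- sample(modes, 1)
    X <- Y <- H <- numeric(sc$n_frames); MO <- character(sc$n_frames)
    for (k in seq_len(sc$n_frames)) {
      X[k] <- x; Y[k] <- y; H[k] <- th; MO[k] <- mode
      if (stats::runif(1) < sc$switch_prob)
        mode <- sample(setdiff(modes, mode), 1)
      th <- th + omega[[mode]] * dt
      hx <- cos(th); hy <- sin(th)
      nx <- x + sp * dt * hx; ny <- y + sp * dt * hy
      if (nx < lo[1] || nx > hi[1]) hx <- -hx
      if (ny < lo[2] || ny > hi[2]) hy <- -hy
      th <- atan2(hy, hx)
      x <- x + sp * dt * hx; y <- y + sp * dt * hy
    }
    rows[[i]] <- data.frame(target = i, frame = seq_len(sc$n_frames),
                            X = X, Y = Y,
                            Vx = sp * cos(H), Vy = sp * sin(H),
                            heading = H, mode = MO)
  }
  do.call(rbind, rows)
}

sim_targets_separated <- function(sc) {
  # parallel eastbound lanes, spaced in north, distinct speeds
  dt <- 1 / sc$frame_rate
  n <- sc$n_targets
  lanes <- sc$margin + (seq_len(n) - 0.5) / n * (sc$arena[1] - 2 * sc$margin)
  speeds <- seq(sc$speed_range[1], sc$speed_range[2], length.out = max(n, 2))[seq_len(n)]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    y0 <- sc$margin + 1
    Y <- y0 + speeds[i] * dt * (seq_len(sc$n_frames) - 1)
    rows[[i]] <- data.frame(target = i, frame = seq_len(sc$n_frames),
                            X = lanes[i], Y = Y, Vx = 0, Vy = speeds[i],
                            heading = pi / 2, mode = "straight")
  }
  do.call(rbind, rows)
}

sim_targets_crossing <- function(sc) {
  # Target 1 rests mid-arena; target 2 drives east along the same lane and
  # overtakes it. Both footprints point east, so the boxes overlap in the
  # along-track (east) axis only; two equal boxes offset by s have
  # IoU = (len - |s|) / (len + |s|), which exceeds occ_iou exactly while
  # |s| < c = len (1 - occ_iou) / (1 + occ_iou). The step per frame d is
  # solved so that exactly `gap` frames fall inside (-c, c): the offsets
  # form the grid s_k = (k - k0) d for odd gaps (a frame of exact overlap)
  # or s_k = (k - k0 - 1/2) d for even gaps, with d = 2 c / gap.
  dt <- 1 / sc$frame_rate
  g <- sc$gap
  len <- sc$footprint[1]
  c_ov <- len * (1 - sc$occ_iou) / (1 + sc$occ_iou)
  d <- 2 * c_ov / g
  v2 <- d / dt
  T <- sc$n_frames
  k0 <- ceiling(T / 2)
  off <- if (g %% 2 == 1) 0 else 0.5
  x1 <- sc$arena[1] / 2
  y1 <- sc$arena[2] / 2
  y2 <- y1 + (seq_len(T) - k0 - off) * d
  rbind(
    data.frame(target = 1, frame = seq_len(T), X = x1, Y = y1,
               Vx = 0, Vy = 0, heading = pi / 2, mode = "straight"),
    data.frame(target = 2, frame = seq_len(T), X = x1, Y = y2,
               Vx = 0, Vy = v2, heading = pi / 2, mode = "straight"))
}

sim_targets_maneuvering <- function(sc) {
  # straight / turn-left / straight / turn-right / straight, equal legs
  dt <- 1 / sc$frame_rate
  T <- sc$n_frames
  leg <- ceiling(T / 5)
  modes <- rep(c("straight", "turn_left", "straight", "turn_right",
                 "straight"), each = leg)[seq_len(T)]
  omega <- c(straight = 0, turn_left = sc$turn_rate,
             turn_right = -sc$turn_rate)
  sp <- mean(sc$speed_range)
  x <- sc$arena[1] / 2 - 2; y <- sc$margin + 2
  th <- pi / 2
  X <- Y <- H <- numeric(T)
  for (k in seq_len(T)) {
    X[k] <- x; Y[k] <- y; H[k] <- th
    th <- th + omega[[modes[k]]] * dt
    x <- x + sp * dt * cos(th); y <- y + sp * dt * sin(th)
  }
  data.frame(target = 1, frame = seq_len(T), X = X, Y = Y,
             Vx = sp * cos(H), Vy = sp * sin(H), heading = H, mode = modes)
}

#' Simulate the UAV pose stream
#'
#' The UAV hovers over the arena centre at `Z = 0` with a nadir-pointing
#' gimbal (pan 0, tilt -90 degrees) and zero nominal attitude; the ground
#' plane sits at down-coordinate `altitude`. The returned sequence is the
#' *measured* pose — the true pose corrupted by Gaussian GPS error on
#' position (`pos_jitter` metres) and INS error on roll/pitch/yaw
#' (`att_jitter` radians) each frame. The true pose sequence (used by
#' [render_boxes()], since the camera physically projects through it) is
#' attached as `attr(, "true_poses")`; pose measurement error is what makes
#' raw per-frame geolocation noisy.
#'
#' @inheritParams simulate_targets
#' @return A `uav_poses` data frame (measured poses) with attribute
#'   `true_poses`.
#' @export
simulate_uav <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sc <- config$scenario
  T <- sc$n_frames
  true <- data.frame(frame = seq_len(T),
                     X = sc$arena[1] / 2, Y = sc$arena[2] / 2, Z = 0,
                     roll = 0, pitch = 0, yaw = 0,
                     pan = 0, tilt = -pi / 2)
  jp <- function() stats::rnorm(T, 0, sc$pos_jitter)
  ja <- function() stats::rnorm(T, 0, sc$att_jitter)
  meas <- true
  meas$X <- meas$X + jp(); meas$Y <- meas$Y + jp(); meas$Z <- meas$Z + jp()
  meas$roll <- meas$roll + ja(); meas$pitch <- meas$pitch + ja()
  meas$yaw <- meas$yaw + ja()
  out <- as_uav_poses(meas)
  attr(out, "true_poses") <- as_uav_poses(true)
  out
}

#' Render ground-truth boxes by pinhole projection
#'
#' Each target's footprint (an oriented rectangle on the ground, long axis
#' along the heading) has its four corners projected through the frame's
#' pose; the ground-truth box is the axis-aligned enclosure of the
#' projected corners. Targets whose projection falls outside the image (or
#' behind the camera plane) are omitted for that frame.
#'
#' @param traj a `trajectory_set`.
#' @param poses a `uav_poses` table.
#' @param intrinsics camera intrinsics.
#' @param footprint `(length, width)` of the target footprint in metres.
#' @param ground_z down-coordinate of the ground plane.
#' @return An id-bearing `frame_table` (score 1).
#' @export
render_boxes <- function(traj, poses, intrinsics, footprint, ground_z) {
  rows <- vector("list", nrow(traj))
  pose_idx <- match(traj$frame, poses$frame)
  if (anyNA(pose_idx)) stop("missing pose for a trajectory frame")
  hl <- footprint[1] / 2; hw <- footprint[2] / 2
  n_out <- 0L
  for (i in seq_len(nrow(traj))) {
    pose <- poses[pose_idx[i], ]
    th <- traj$heading[i]
    dir <- c(cos(th), sin(th)); perp <- c(-sin(th), cos(th))
    ctr <- c(traj$X[i], traj$Y[i])
    corners <- rbind(ctr + hl * dir + hw * perp, ctr + hl * dir - hw * perp,
                     ctr - hl * dir + hw * perp, ctr - hl * dir - hw * perp)
    px <- matrix(NA_real_, 4, 2)
    ok <- TRUE
    for (cn in 1:4) {
      p <- project_ground_point(corners[cn, ], pose, intrinsics, ground_z)
      if (!p$visible) { ok <- FALSE; break }
      px[cn, ] <- c(p$x, p$y)
    }
    if (!ok) next
    cx <- mean(range(px[, 1])); cy <- mean(range(px[, 2]))
    if (cx < 0 || cx > intrinsics$width || cy < 0 || cy > intrinsics$height)
      next
    n_out <- n_out + 1L
    rows[[n_out]] <- data.frame(frame = traj$frame[i], id = traj$target[i],
                                cx = cx, cy = cy,
                                w = diff(range(px[, 1])),
                                h = diff(range(px[, 2])), score = 1)
  }
  if (n_out == 0L) return(frame_table())
  as_frame_table(do.call(rbind, rows[seq_len(n_out)]))
}

#' Corrupt ground truth into raw detections
#'
#' Per ground-truth box, in order: mutual-occlusion dropout (when two boxes
#' of one frame overlap with IoU above `occ_iou`, the higher-id box is
#' dropped — a nadir camera gives no depth ordering, so the deterministic
#' id rule stands in for one); missed detection with probability `p_miss`;
#' Gaussian centre noise (`center_noise` pixels) and multiplicative
#' log-normal size noise (`size_noise` log-sd); confidence scores from
#' `Beta(score_true)` (all 1 when `score_true` is `NULL`). Poisson
#' (`fp_rate`) false positives per frame are added as uniform boxes scored
#' from `Beta(score_false)`. Identities are stripped.
#'
#' @param gt an id-bearing `frame_table`.
#' @param config a `herd_config`.
#' @param seed integer seed; `NULL` leaves the RNG stream alone.
#' @return An id-free `frame_table` of detections.
#' @export
degrade <- function(gt, config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sc <- config$scenario
  cam <- config$camera
  keep <- rep(TRUE, nrow(gt))
  for (f in unique(gt$frame)) {
    idx <- which(gt$frame == f)
    if (length(idx) < 2L) next
    M <- iou_matrix(gt[idx, ], gt[idx, ])
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      if (M[a, b] > sc$occ_iou) {
        drop <- if (gt$id[idx[a]] > gt$id[idx[b]]) idx[a] else idx[b]
        keep[drop] <- FALSE
      }
    }
  }
  det <- gt[keep, , drop = FALSE]
  if (nrow(det) && sc$p_miss > 0)
    det <- det[stats::runif(nrow(det)) >= sc$p_miss, , drop = FALSE]
  n <- nrow(det)
  if (n) {
    det$cx <- det$cx + stats::rnorm(n, 0, sc$center_noise)
    det$cy <- det$cy + stats::rnorm(n, 0, sc$center_noise)
    det$w <- det$w * exp(stats::rnorm(n, 0, sc$size_noise))
    det$h <- det$h * exp(stats::rnorm(n, 0, sc$size_noise))
    det$score <- if (is.null(sc$score_true)) 1
                 else stats::rbeta(n, sc$score_true[1], sc$score_true[2])
    det$id <- NA_integer_
  }
  fps <- list()
  if (sc$fp_rate > 0) {
    mean_w <- if (n) mean(det$w) else 30
    mean_h <- if (n) mean(det$h) else 30
    for (f in sort(unique(gt$frame))) {
      nf <- stats::rpois(1, sc$fp_rate)
      if (nf == 0L) next
      fps[[length(fps) + 1L]] <- data.frame(
        frame = f, id = NA_integer_,
        cx = stats::runif(nf, 0, cam$width),
        cy = stats::runif(nf, 0, cam$height),
        w = mean_w * stats::runif(nf, 0.5, 1.5),
        h = mean_h * stats::runif(nf, 0.5, 1.5),
        score = if (is.null(sc$score_false)) 0.5
                else stats::rbeta(nf, sc$score_false[1], sc$score_false[2]))
    }
  }
  all <- rbind(as.data.frame(det), do.call(rbind, fps))
  if (is.null(all) || nrow(all) == 0L) return(frame_table())
  as_frame_table(all)
}

#' Generate a complete synthetic scenario
#'
#' Derives independent sub-seeds for targets, poses and corruption from the
#' master seed, then chains [simulate_targets()], [simulate_uav()],
#' [render_boxes()] and [degrade()].
#'
#' @param config a `herd_config`.
#' @param seed master seed; defaults to `config$scenario$seed`.
#' @return A list of class `herd_scenario`: `truth` (trajectories), `poses`,
#'   `gt` (rendered boxes), `det` (corrupted detections), `config`, `seed`.
#' @examples
#' sc <- simulate_scenario(preset_config("separated"), seed = 1)
#' sc$gt
#' @export
simulate_scenario <- function(config, seed = config$scenario$seed) {
  seed <- as.integer(seed)
  set.seed(seed)
  sub <- sample.int(2147483646L, 3)
  truth <- simulate_targets(config, seed = sub[1])
  poses <- simulate_uav(config, seed = sub[2])
  intr <- do.call(camera_intrinsics, config$camera)
  # the camera physically projects through the true pose; the measured
  # (GPS/INS-corrupted) pose stream is what downstream geolocation sees
  gt <- render_boxes(truth, attr(poses, "true_poses"), intr,
                     config$scenario$footprint,
                     ground_z = config$scenario$altitude)
  det <- degrade(gt, config, seed = sub[3])
  structure(list(truth = truth, poses = poses, gt = gt, det = det,
                 config = config, seed = seed, intrinsics = intr),
            class = "herd_scenario")
}

#' @export
print.herd_scenario <- function(x, ...) {
  cat(sprintf("<herd_scenario> type %s, %d targets, %d frames; %d gt boxes, %d detections\n",
              x$config$scenario$type, x$config$scenario$n_targets,
              x$config$scenario$n_frames, nrow(x$gt), nrow(x$det)))
  invisible(x)
}
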