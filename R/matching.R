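#' Two-stage greedy data association with a stranding area
#'
#' The tracker associates per-frame detections to tracks with two
#' distance-based greedy passes. Stage 1 matches detections (highest score
#' first) to *active* tracks at their predicted centres (last centre plus
#' motion vector). Active tracks that find no detection are moved to the
#' *stranding area*: a holding buffer whose members keep drifting by their
#' frozen motion vector and carry a health countdown, initialised to the
#' configured lifespan (default 20 frames). Stage 2 matches the detections
#' left over from stage 1 against the drifted stranded tracks with a wider
#' gate; a hit restores the track to active status with its original
#' identity, which is what suppresses identity switches across short
#' occlusions. Detections unmatched after both stages found new tracks with
#' fresh, never-reused ids. Stranded tracks whose health reaches zero are
#' terminated.
#'
#' The motion vector is an exponential moving average of observed per-frame
#' centre displacements (see [ema_velocity()]); the backward vector is its
#' negation and can be selected for stage-2 drift via
#' `tracker$stage2_direction = "backward"`.
#'
#' @name matching
NULL

#' Exponential-moving-average motion vector
#'
#' Folds per-frame centre displacements into a motion vector:
#' the first displacement initialises the average, after which
#' `v <- alpha * d + (1 - alpha) * v`. With no displacement history the
#' motion vector is zero.
#'
#' @param disps numeric matrix with one displacement `(dx, dy)` per row
#'   (pixels/frame), oldest first; may have zero rows.
#' @param alpha EMA weight in (0, 1].
#' @return Numeric `(vx, vy)`.
#' @examples
#' ema_velocity(rbind(c(2, 0), c(2, 0), c(2, 0)), 0.3)  # (2, 0) for any alpha
#' @export
ema_velocity <- function(disps, alpha) {
  disps <- matrix(as.numeric(disps), ncol = 2)
  if (nrow(disps) == 0L) return(c(0, 0))
  v <- disps[1, ]
  for (i in seq_len(nrow(disps))[-1]) v <- alpha * disps[i, ] + (1 - alpha) * v
  v
}

#' Motion vector of a track
#'
#' Recomputes the forward motion vector from a track's observation history
#' (per-frame displacements between consecutive observations, divided by the
#' frame gap) as an EMA; equals the incrementally maintained
#' `track$velocity`. Errors on an empty history; returns `(0, 0)` for a
#' single observation.
#'
#' @param track a track record as found in `tracker_state$active`.
#' @param alpha EMA weight.
#' @return Numeric `(vx, vy)` in pixels/frame.
#' @export
predict_motion <- function(track, alpha) {
  if (is.null(track$hist_frames) || length(track$hist_frames) == 0L)
    stop("track has an empty history")
  n <- length(track$hist_frames)
  if (n == 1L) return(c(0, 0))
  d <- diff(track$hist_centers) / diff(track$hist_frames)
  ema_velocity(d, alpha)
}

#' Greedy gated nearest-neighbour matching
#'
#' Detections are processed in descending score order (ties keep input
#' order); each takes the nearest still-unmatched candidate whose Euclidean
#' centre distance does not exceed that candidate's gate radius. Exact
#' distance ties go to the candidate with the lower track id. Deterministic
#' given its inputs.
#'
#' @param dets data frame with columns `cx`, `cy`, `score` (one detection
#'   per row).
#' @param cand data frame with columns `px`, `py` (predicted centre),
#'   `gate` (> 0) and `id` (track id, used only for tie-breaking).
#' @return List with `matches` (two-column matrix of det row / candidate
#'   row), `unmatched_dets`, `unmatched_cands` (row indices).
#' @export
greedy_match <- function(dets, cand) {
  nd <- nrow(dets); nc <- nrow(cand)
  matches <- matrix(integer(), ncol = 2,
                    dimnames = list(NULL, c("det", "cand")))
  if (nd == 0L || nc == 0L)
    return(list(matches = matches, unmatched_dets = seq_len(nd),
                unmatched_cands = seq_len(nc)))
  if (any(cand$gate <= 0)) stop("gate radius must be positive")
  free <- rep(TRUE, nc)
  order_d <- order(-dets$score)  # stable: ties keep input order
  for (di in order_d) {
    idx <- which(free)
    if (length(idx) == 0L) break
    dist <- sqrt((dets$cx[di] - cand$px[idx])^2 +
                 (dets$cy[di] - cand$py[idx])^2)
    ok <- dist <= cand$gate[idx]
    if (!any(ok)) next
    idx <- idx[ok]; dist <- dist[ok]
    best <- idx[dist == min(dist)]
    ci <- best[which.min(cand$id[best])]
    matches <- rbind(matches, c(di, ci))
    free[ci] <- FALSE
  }
  list(matches = matches,
       unmatched_dets = setdiff(seq_len(nd), matches[, 1]),
       unmatched_cands = which(free))
}

#' Fresh tracker state
#'
#' @param config a `herd_config` (only the `tracker` section is used).
#' @return A list of class `tracker_state` with empty `active` and
#'   `stranded` track lists, the next id to allocate, and a record of
#'   terminated ids.
#' @export
new_tracker_state <- function(config = default_config()) {
  structure(list(active = list(), stranded = list(), next_id = 1L,
                 terminated = integer(), config = config),
            class = "tracker_state")
}

new_track <- function(id, det, frame) {
  list(id = id, center = c(det$cx, det$cy), size = c(det$w, det$h),
       velocity = c(0, 0), n_disp = 0L, health = NA_integer_,
       last_frame = frame,
       hist_frames = frame, hist_centers = matrix(c(det$cx, det$cy), 1))
}

observe_track <- function(track, det, frame, alpha) {
  gap <- frame - track$last_frame
  d <- (c(det$cx, det$cy) - track$center) / gap
  track$velocity <- if (track$n_disp == 0L) d
                    else alpha * d + (1 - alpha) * track$velocity
  track$n_disp <- track$n_disp + 1L
  track$center <- c(det$cx, det$cy)
  track$size <- c(det$w, det$h)
  track$last_frame <- frame
  track$health <- NA_integer_
  track$hist_frames <- c(track$hist_frames, frame)
  track$hist_centers <- rbind(track$hist_centers, track$center)
  track
}

#' Advance the stranding area by one frame
#'
#' Every stranded track's centre is shifted by its frozen motion vector
#' (drift simulating the occluded target's continued movement), its health
#' decremented by one; tracks reaching zero health are terminated and
#' removed.
#'
#' @param stranded list of stranded track records.
#' @param direction `"forward"` (drift by the motion vector) or
#'   `"backward"` (its negation).
#' @return List with the surviving `stranded` list and the `terminated` ids.
#' @export
advance_stranding <- function(stranded, direction = "forward") {
  sgn <- if (identical(direction, "backward")) -1 else 1
  terminated <- integer()
  keep <- list()
  for (tr in stranded) {
    tr$center <- tr$center + sgn * tr$velocity
    tr$health <- tr$health - 1L
    if (tr$health <= 0L) terminated <- c(terminated, tr$id)
    else keep[[length(keep) + 1L]] <- tr
  }
  list(stranded = keep, terminated = terminated)
}

#' One frame of the two-stage tracker
#'
#' Runs the full per-frame update described in [matching]: score filtering,
#' stage-1 greedy match against active tracks, stranding of unmatched
#' tracks, stage-2 greedy match against the (drift-predicted) stranding
#' area, creation of new tracks, and the stranding-area drift/health
#' advance.
#'
#' @param state a `tracker_state`.
#' @param dets `frame_table` rows, all from the same frame (may be empty).
#' @param frame the frame index being processed.
#' @return List with the updated `state` and `out`, a data frame of the
#'   frame's id-bearing output boxes.
#' @export
two_stage_update <- function(state, dets, frame) {
  cfg <- state$config$tracker
  dets <- as.data.frame(dets)
  if (nrow(dets) && length(unique(dets$frame)) > 1L)
    stop("detections from mixed frames passed to two_stage_update")
  dets <- dets[order(seq_len(nrow(dets))), , drop = FALSE]  # file order
  keep <- if (nrow(dets)) dets$score >= cfg$score_threshold else logical()
  dets <- dets[keep, , drop = FALSE]
  sgn2 <- if (identical(cfg$stage2_direction, "backward")) -1 else 1

  out_id <- integer(); out_det <- integer()

  # stage 1: active tracks at predicted centres
  active <- state$active
  cand1 <- track_candidates(active, cfg$kappa, drift_sign = 1)
  m1 <- greedy_match(dets, cand1)
  for (r in seq_len(nrow(m1$matches))) {
    di <- m1$matches[r, 1]; ci <- m1$matches[r, 2]
    active[[ci]] <- observe_track(active[[ci]], dets[di, ], frame, cfg$alpha)
    out_id <- c(out_id, active[[ci]]$id); out_det <- c(out_det, di)
  }

  stranded <- state$stranded
  terminated <- integer()
  if (cfg$stage2) {
    for (ci in m1$unmatched_cands) {
      tr <- active[[ci]]
      tr$health <- cfg$lifespan
      stranded[[length(stranded) + 1L]] <- tr
    }
  } else {
    terminated <- c(terminated,
                    vapply(active[m1$unmatched_cands], `[[`, integer(1), "id"))
  }
  active <- active[setdiff(seq_along(active), m1$unmatched_cands)]

  # stage 2: leftover detections against drifted stranded tracks
  rem <- m1$unmatched_dets
  if (cfg$stage2 && length(rem) && length(stranded)) {
    dets2 <- dets[rem, , drop = FALSE]
    cand2 <- track_candidates(stranded, cfg$kappa2, drift_sign = sgn2)
    m2 <- greedy_match(dets2, cand2)
    restored <- integer()
    for (r in seq_len(nrow(m2$matches))) {
      di2 <- m2$matches[r, 1]; ci <- m2$matches[r, 2]
      tr <- observe_track(stranded[[ci]], dets2[di2, ], frame, cfg$alpha)
      active[[length(active) + 1L]] <- tr
      restored <- c(restored, ci)
      out_id <- c(out_id, tr$id); out_det <- c(out_det, rem[di2])
    }
    stranded <- stranded[setdiff(seq_along(stranded), restored)]
    rem <- rem[m2$unmatched_dets]
  }

  # new tracks for detections unmatched after both stages (file order)
  for (di in sort(rem)) {
    tr <- new_track(state$next_id, dets[di, ], frame)
    state$next_id <- state$next_id + 1L
    active[[length(active) + 1L]] <- tr
    out_id <- c(out_id, tr$id); out_det <- c(out_det, di)
  }

  adv <- advance_stranding(stranded, cfg$stage2_direction)
  state$active <- active
  state$stranded <- adv$stranded
  state$terminated <- c(state$terminated, terminated, adv$terminated)

  out <- if (length(out_det)) {
    data.frame(frame = frame, id = out_id,
               cx = dets$cx[out_det], cy = dets$cy[out_det],
               w = dets$w[out_det], h = dets$h[out_det],
               score = dets$score[out_det])
  } else {
    data.frame(frame = integer(), id = integer(), cx = numeric(),
               cy = numeric(), w = numeric(), h = numeric(),
               score = numeric())
  }
  list(state = state, out = out)
}

track_candidates <- function(tracks, kappa, drift_sign = 1) {
  n <- length(tracks)
  if (n == 0L)
    return(data.frame(px = numeric(), py = numeric(), gate = numeric(),
                      id = integer()))
  px <- py <- gate <- numeric(n); id <- integer(n)
  for (i in seq_len(n)) {
    tr <- tracks[[i]]
    p <- tr$center + drift_sign * tr$velocity
    px[i] <- p[1]; py[i] <- p[2]
    gate[i] <- kappa * sqrt(tr$size[1] * tr$size[2])
    id[i] <- tr$id
  }
  data.frame(px = px, py = py, gate = gate, id = id)
}

#' Track a whole detection table
#'
#' Iterates [two_stage_update()] over the table's full frame range (frames
#' with no detections still advance the stranding area) and collects the
#' id-bearing output.
#'
#' @param dets a `frame_table` of raw detections (ids ignored).
#' @param config a `herd_config`.
#' @return List of class `herd_tracks` with `result` (an id-bearing
#'   `frame_table`) and the final `state`.
#' @examples
#' sc <- simulate_scenario(preset_config("separated"))
#' tr <- track_detections(sc$det, preset_config("separated"))
#' print(tr$result)
#' @export
track_detections <- function(dets, config = default_config()) {
  state <- new_tracker_state(config)
  pieces <- list()
  fr <- frame_range(dets)
  if (!is.na(fr[1])) {
    for (f in seq(fr[1], fr[2])) {
      step <- two_stage_update(state, dets[dets$frame == f, , drop = FALSE], f)
      state <- step$state
      if (nrow(step$out)) pieces[[length(pieces) + 1L]] <- step$out
    }
  }
  result <- if (length(pieces)) as_frame_table(do.call(rbind, pieces))
            else frame_table()
  structure(list(result = result, state = state), class = "herd_tracks")
}

#' @export
print.herd_tracks <- function(x, ...) {
  cat(sprintf("<herd_tracks> %d output boxes, %d identities created, %d terminated\n",
              nrow(x$result), x$state$next_id - 1L,
              length(x$state$terminated)))
  invisible(x)
}
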