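#' Bounding-box intersection over union
#'
#' Boxes are centre + size with half-open pixel semantics
#' `[left, left+w) x [top, top+h)`; IoU = intersection area / union area.
#'
#' @param a,b boxes as numeric `(cx, cy, w, h)`.
#' @return Overlap ratio in \[0, 1\].
#' @examples
#' box <- function(l, t, w, h) c(l + w/2, t + h/2, w, h)
#' iou(box(0, 0, 2, 2), box(1, 0, 2, 2))  # 1/3
#' @export
iou <- function(a, b) {
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0)
    stop("box sizes must be positive")
  iw <- max(0, min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
               max(a[1] - a[3] / 2, b[1] - b[3] / 2))
  ih <- max(0, min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
               max(a[2] - a[4] / 2, b[2] - b[4] / 2))
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# pairwise IoU matrix between two box data frames (cx, cy, w, h columns)
iou_matrix <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  M <- matrix(0, nA, nB)
  if (nA == 0L || nB == 0L) return(M)
  al <- A$cx - A$w / 2; ar <- A$cx + A$w / 2
  at <- A$cy - A$h / 2; ab <- A$cy + A$h / 2
  bl <- B$cx - B$w / 2; br <- B$cx + B$w / 2
  bt <- B$cy - B$h / 2; bb <- B$cy + B$h / 2
  for (i in seq_len(nA)) {
    iw <- pmax(0, pmin(ar[i], br) - pmax(al[i], bl))
    ih <- pmax(0, pmin(ab[i], bb) - pmax(at[i], bt))
    inter <- iw * ih
    M[i, ] <- inter / (A$w[i] * A$h[i] + B$w * B$h - inter)
  }
  M
}

# lexicographic optimal matching: maximise #pairs with IoU >= thr, then
# total IoU, via an assignment with benefit costs and zero-cost dummies
optimal_iou_match <- function(IoU, thr) {
  nA <- nrow(IoU); nB <- ncol(IoU)
  if (nA == 0L || nB == 0L)
    return(matrix(integer(), ncol = 2))
  K <- nA + nB
  C <- matrix(0, K, K)
  valid <- IoU >= thr
  C[seq_len(nA), seq_len(nB)][valid] <- -(1 + IoU[valid])
  a <- solve_assignment(C)
  pairs <- cbind(seq_len(nA), a[seq_len(nA)])
  pairs <- pairs[pairs[, 2] <= nB, , drop = FALSE]
  pairs[valid[pairs], , drop = FALSE]
}

#' CLEAR-MOT evaluation
#'
#' Frame-by-frame protocol: correspondences persisting from the previous
#' frame are kept while their IoU stays at or above the threshold; the
#' remaining boxes are paired by optimal bipartite matching (maximum number
#' of pairs, then maximum total IoU) among pairs with IoU at or above the
#' threshold. Unmatched ground truth counts as FN, unmatched hypotheses as
#' FP; a ground-truth object matched to a hypothesis id different from its
#' last matched id (memory persists across gaps) counts as an identity
#' switch.
#'
#' `MOTA = 1 - (FN + FP + IDSW) / GT` and `MOTP = sum(IoU of matches) /
#' #matches` (on the IoU scale in \[0, 1\]).
#'
#' @param gt,hyp id-bearing `frame_table`s.
#' @param iou_threshold match gate, default 0.5.
#' @return List with totals (`gt`, `fn`, `fp`, `idsw`, `matches`,
#'   `sum_iou`), derived `mota` and `motp`, a per-frame count data frame
#'   `frames`, and `match_log` (frame, gt id, hyp id, IoU of every match) —
#'   the input to [trajectory_stats()].
#' @export
clear_mot <- function(gt, hyp, iou_threshold = 0.5) {
  gt <- as_frame_table(gt); hyp <- as_frame_table(hyp)
  if (anyNA(gt$id) || anyNA(hyp$id))
    stop("clear_mot needs id-bearing tables")
  if (nrow(gt) == 0L)
    stop("MOTA undefined: ground truth is empty")
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  prev_map <- integer()                      # names: gt ids -> hyp ids
  last_match <- integer()                    # IDSW memory, persists gaps
  pf <- data.frame(frame = frames, gt = 0L, fn = 0L, fp = 0L, idsw = 0L,
                   matches = 0L, sum_iou = 0)
  log_frame <- integer(); log_gt <- integer(); log_hyp <- integer()
  log_iou <- numeric()
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    G <- gt[gt$frame == f, , drop = FALSE]
    H <- hyp[hyp$frame == f, , drop = FALSE]
    IoU <- iou_matrix(G, H)
    pairs <- matrix(integer(), ncol = 2)
    # keep persisting correspondences first
    if (length(prev_map)) {
      gi <- match(as.integer(names(prev_map)), G$id)
      hi <- match(prev_map, H$id)
      ok <- !is.na(gi) & !is.na(hi)
      ok[ok] <- IoU[cbind(gi[ok], hi[ok])] >= iou_threshold
      pairs <- cbind(gi[ok], hi[ok])
    }
    restG <- setdiff(seq_len(nrow(G)), pairs[, 1])
    restH <- setdiff(seq_len(nrow(H)), pairs[, 2])
    if (length(restG) && length(restH)) {
      sub <- optimal_iou_match(IoU[restG, restH, drop = FALSE], iou_threshold)
      if (nrow(sub))
        pairs <- rbind(pairs, cbind(restG[sub[, 1]], restH[sub[, 2]]))
    }
    nm <- nrow(pairs)
    idsw <- 0L
    if (nm) {
      gids <- G$id[pairs[, 1]]; hids <- H$id[pairs[, 2]]
      prev <- last_match[as.character(gids)]
      idsw <- sum(!is.na(prev) & prev != hids)
      last_match[as.character(gids)] <- hids
      ious <- IoU[pairs]
      log_frame <- c(log_frame, rep(f, nm))
      log_gt <- c(log_gt, gids); log_hyp <- c(log_hyp, hids)
      log_iou <- c(log_iou, ious)
      prev_map <- stats::setNames(hids, gids)
      pf$sum_iou[fi] <- sum(ious)
    } else {
      prev_map <- integer()
    }
    pf$gt[fi] <- nrow(G)
    pf$fn[fi] <- nrow(G) - nm
    pf$fp[fi] <- nrow(H) - nm
    pf$idsw[fi] <- idsw
    pf$matches[fi] <- nm
  }
  tot_gt <- sum(pf$gt); fn <- sum(pf$fn); fp <- sum(pf$fp)
  idsw <- sum(pf$idsw); C <- sum(pf$matches); sum_iou <- sum(pf$sum_iou)
  list(gt = tot_gt, fn = fn, fp = fp, idsw = idsw, matches = C,
       sum_iou = sum_iou,
       mota = 1 - (fn + fp + idsw) / tot_gt,
       motp = if (C > 0) sum_iou / C else NA_real_,
       frames = pf,
       match_log = data.frame(frame = log_frame, gt_id = log_gt,
                              hyp_id = log_hyp, iou = log_iou))
}

#' Identity F1 (IDF1)
#'
#' Global trajectory-level assignment between ground-truth and hypothesis
#' identities minimising total identity-level mismatches; for a candidate
#' pair the per-frame agreement is IoU at or above the threshold. With
#' `IDTP` the identity true positives under the optimal assignment,
#' `IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#'
#' @inheritParams clear_mot
#' @return List `idtp`, `idfp`, `idfn`, `idf1`.
#' @export
idf1 <- function(gt, hyp, iou_threshold = 0.5) {
  gt <- as_frame_table(gt); hyp <- as_frame_table(hyp)
  if (anyNA(gt$id) || anyNA(hyp$id))
    stop("idf1 needs id-bearing tables")
  if (nrow(gt) == 0L)
    stop("IDF1 undefined: ground truth is empty")
  gids <- sort(unique(gt$id)); hids <- sort(unique(hyp$id))
  nG <- length(gids); nH <- length(hids)
  lenG <- as.vector(table(factor(gt$id, levels = gids)))
  lenH <- as.vector(table(factor(hyp$id, levels = hids)))
  # per-pair agreeing-frame counts
  agree <- matrix(0L, nG, nH)
  for (f in sort(unique(intersect(gt$frame, hyp$frame)))) {
    G <- gt[gt$frame == f, , drop = FALSE]
    H <- hyp[hyp$frame == f, , drop = FALSE]
    M <- iou_matrix(G, H) >= iou_threshold
    gi <- match(G$id, gids); hi <- match(H$id, hids)
    agree[gi, hi] <- agree[gi, hi] + M
  }
  # padded square cost: real-real pairings cost their identity mismatches
  # (FN + FP of the pair); leaving a trajectory unpaired costs its length;
  # each real id gets exactly one private dummy partner
  K <- nG + nH
  C <- matrix(1e9, K, K)
  C[seq_len(nG), seq_len(nH)] <- outer(lenG, lenH, `+`) - 2 * agree
  C[cbind(seq_len(nG), nH + seq_len(nG))] <- lenG
  C[cbind(nG + seq_len(nH), seq_len(nH))] <- lenH
  C[nG + seq_len(nH), nH + seq_len(nG)] <- 0
  a <- solve_assignment(C)
  idtp <- 0L
  for (i in seq_len(nG)) {
    j <- a[i]
    if (j <= nH) idtp <- idtp + agree[i, j]
  }
  idfn <- sum(lenG) - idtp
  idfp <- sum(lenH) - idtp
  list(idtp = as.integer(idtp), idfp = as.integer(idfp),
       idfn = as.integer(idfn),
       idf1 = 2 * idtp / (2 * idtp + idfp + idfn))
}

#' Trajectory-level statistics: MT, ML, FM
#'
#' Per ground-truth trajectory the tracked fraction is the number of
#' CLEAR-matched frames over the trajectory's length (frames where the
#' object is annotated). Mostly tracked (MT) counts fractions of at least
#' 0.8, mostly lost (ML) fractions below 0.2. FM counts interruptions —
#' tracked-to-untracked transitions along the trajectory's own frame
#' sequence — not fragments.
#'
#' @inheritParams clear_mot
#' @param cm optionally a precomputed [clear_mot()] result.
#' @return List `mt`, `ml`, `fm`, `n_traj`, and the per-trajectory data
#'   frame `per_traj`.
#' @export
trajectory_stats <- function(gt, hyp, iou_threshold = 0.5, cm = NULL) {
  gt <- as_frame_table(gt)
  if (is.null(cm)) cm <- clear_mot(gt, hyp, iou_threshold)
  ml <- cm$match_log
  gids <- sort(unique(gt$id))
  frac <- numeric(length(gids)); fm <- integer(length(gids))
  for (i in seq_along(gids)) {
    g <- gids[i]
    frames <- sort(gt$frame[gt$id == g])
    matched <- frames %in% ml$frame[ml$gt_id == g]
    frac[i] <- mean(matched)
    n <- length(matched)
    fm[i] <- if (n > 1) sum(matched[-n] & !matched[-1]) else 0L
  }
  list(mt = sum(frac >= 0.8), ml = sum(frac < 0.2), fm = sum(fm),
       n_traj = length(gids),
       per_traj = data.frame(id = gids, tracked_fraction = frac,
                             interruptions = fm))
}

#' Full tracking evaluation report
#'
#' Combines [clear_mot()], [idf1()] and [trajectory_stats()] into one
#' report with all counts and derived metrics.
#'
#' @inheritParams clear_mot
#' @return A list of class `eval_report`.
#' @examples
#' gt <- frame_table(frame = rep(1:3, each = 1), id = 1,
#'                   cx = c(10, 12, 14), cy = 10, w = 4, h = 4)
#' ev <- evaluate_tracking(gt, gt)
#' ev$mota; ev$idf1
#' @export
evaluate_tracking <- function(gt, hyp, iou_threshold = 0.5) {
  cm <- clear_mot(gt, hyp, iou_threshold)
  idm <- idf1(gt, hyp, iou_threshold)
  ts <- trajectory_stats(gt, hyp, iou_threshold, cm = cm)
  structure(list(mota = cm$mota, motp = cm$motp, idf1 = idm$idf1,
                 gt = cm$gt, fn = cm$fn, fp = cm$fp, idsw = cm$idsw,
                 matches = cm$matches,
                 idtp = idm$idtp, idfp = idm$idfp, idfn = idm$idfn,
                 mt = ts$mt, ml = ts$ml, fm = ts$fm, n_traj = ts$n_traj,
                 iou_threshold = iou_threshold,
                 clear = cm, trajectories = ts$per_traj),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Tracking evaluation (IoU gate ", x$iou_threshold, ")\n", sep = "")
  cat(sprintf("  MOTA %6.1f%%   MOTP %6.1f%%   IDF1 %6.1f%%\n",
              100 * x$mota, 100 * x$motp, 100 * x$idf1))
  cat(sprintf("  GT %d  FP %d  FN %d  IDsw %d  matches %d\n",
              x$gt, x$fp, x$fn, x$idsw, x$matches))
  cat(sprintf("  MT %d/%d  ML %d/%d  FM %d\n",
              x$mt, x$n_traj, x$ml, x$n_traj, x$fm))
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  keep <- c("mota", "motp", "idf1", "gt", "fn", "fp", "idsw", "matches",
            "idtp", "idfp", "idfn", "mt", "ml", "fm", "n_traj",
            "iou_threshold")
  jsonlite::write_json(report[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
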