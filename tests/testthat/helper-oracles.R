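# Independent oracles and fixture builders. Everything here is written
# against the definitions, not against the package implementation: IoU from
# corner coordinates, exhaustive-enumeration assignment, a standalone
# Kalman filter.

# --- independent IoU (corner arithmetic, no shared code) ---------------------
oracle_iou <- function(a, b) {
  l1 <- a[1] - a[3] / 2; r1 <- a[1] + a[3] / 2
  t1 <- a[2] - a[4] / 2; b1 <- a[2] + a[4] / 2
  l2 <- b[1] - b[3] / 2; r2 <- b[1] + b[3] / 2
  t2 <- b[2] - b[4] / 2; b2 <- b[2] + b[4] / 2
  iw <- min(r1, r2) - max(l1, l2); ih <- min(b1, b2) - max(t1, t2)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((r1 - l1) * (b1 - t1) + (r2 - l2) * (b2 - t2) - inter)
}

# exhaustive best injective matching of gt rows to hyp rows: maximise number
# of pairs with IoU >= thr, then total IoU, by recursion over gt rows
oracle_best_match <- function(IoU, thr) {
  nG <- nrow(IoU); nH <- ncol(IoU)
  best <- list(count = -1, sum = -Inf, pairs = matrix(integer(), ncol = 2))
  recurse <- function(g, used, pairs, s) {
    if (g > nG) {
      cnt <- nrow(pairs)
      if (cnt > best$count || (cnt == best$count && s > best$sum + 1e-12))
        best <<- list(count = cnt, sum = s, pairs = pairs)
      return(invisible())
    }
    recurse(g + 1L, used, pairs, s)                 # leave g unmatched
    for (h in seq_len(nH)) {
      if (!used[h] && IoU[g, h] >= thr) {
        used[h] <- TRUE
        recurse(g + 1L, used, rbind(pairs, c(g, h)), s + IoU[g, h])
        used[h] <- FALSE
      }
    }
  }
  recurse(1L, logical(nH), matrix(integer(), ncol = 2), 0)
  best$pairs
}

# full CLEAR-MOT protocol by brute force: persistence of the previous
# frame's correspondences, exhaustive assignment for the rest, IDSW memory
# across gaps; also returns per-gt matched flags for MT/ML/FM
oracle_clear_mot <- function(gt, hyp, thr) {
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  prev <- list(); last <- list()
  fn <- fp <- idsw <- C <- ngt <- 0L; sum_iou <- 0
  gids <- sort(unique(gt$id))
  matched_frames <- stats::setNames(vector("list", length(gids)),
                                    as.character(gids))
  for (f in frames) {
    G <- gt[gt$frame == f, , drop = FALSE]
    H <- hyp[hyp$frame == f, , drop = FALSE]
    IoU <- matrix(0, nrow(G), nrow(H))
    for (i in seq_len(nrow(G))) for (j in seq_len(nrow(H)))
      IoU[i, j] <- oracle_iou(c(G$cx[i], G$cy[i], G$w[i], G$h[i]),
                              c(H$cx[j], H$cy[j], H$w[j], H$h[j]))
    pairs <- matrix(integer(), ncol = 2)
    for (g_id in names(prev)) {
      gi <- match(as.integer(g_id), G$id); hi <- match(prev[[g_id]], H$id)
      if (!is.na(gi) && !is.na(hi) && IoU[gi, hi] >= thr)
        pairs <- rbind(pairs, c(gi, hi))
    }
    restG <- setdiff(seq_len(nrow(G)), pairs[, 1])
    restH <- setdiff(seq_len(nrow(H)), pairs[, 2])
    if (length(restG) && length(restH)) {
      sub <- oracle_best_match(IoU[restG, restH, drop = FALSE], thr)
      if (nrow(sub)) pairs <- rbind(pairs, cbind(restG[sub[, 1]],
                                                 restH[sub[, 2]]))
    }
    prev <- list()
    for (r in seq_len(nrow(pairs))) {
      g_id <- as.character(G$id[pairs[r, 1]]); h_id <- H$id[pairs[r, 2]]
      if (!is.null(last[[g_id]]) && last[[g_id]] != h_id)
        idsw <- idsw + 1L
      last[[g_id]] <- h_id
      prev[[g_id]] <- h_id
      sum_iou <- sum_iou + IoU[pairs[r, 1], pairs[r, 2]]
      matched_frames[[g_id]] <- c(matched_frames[[g_id]], f)
    }
    ngt <- ngt + nrow(G)
    fn <- fn + nrow(G) - nrow(pairs)
    fp <- fp + nrow(H) - nrow(pairs)
    C <- C + nrow(pairs)
  }
  mt <- ml <- fm <- 0L
  for (g in gids) {
    fr <- sort(gt$frame[gt$id == g])
    mf <- fr %in% matched_frames[[as.character(g)]]
    frac <- mean(mf)
    if (frac >= 0.8) mt <- mt + 1L
    if (frac < 0.2) ml <- ml + 1L
    if (length(mf) > 1)
      fm <- fm + sum(mf[-length(mf)] & !mf[-1])
  }
  list(gt = ngt, fn = fn, fp = fp, idsw = idsw, matches = C,
       sum_iou = sum_iou, mota = 1 - (fn + fp + idsw) / ngt,
       motp = if (C > 0) sum_iou / C else NA_real_,
       mt = mt, ml = ml, fm = fm)
}

# brute-force IDF1: enumerate injective maps of gt ids to hyp ids
oracle_idf1 <- function(gt, hyp, thr) {
  gids <- sort(unique(gt$id)); hids <- sort(unique(hyp$id))
  agree <- matrix(0L, length(gids), length(hids))
  for (f in sort(unique(intersect(gt$frame, hyp$frame)))) {
    G <- gt[gt$frame == f, , drop = FALSE]
    H <- hyp[hyp$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(G))) for (j in seq_len(nrow(H))) {
      v <- oracle_iou(c(G$cx[i], G$cy[i], G$w[i], G$h[i]),
                      c(H$cx[j], H$cy[j], H$w[j], H$h[j])) >= thr
      gi <- match(G$id[i], gids); hj <- match(H$id[j], hids)
      agree[gi, hj] <- agree[gi, hj] + v
    }
  }
  best <- 0L
  recurse <- function(g, used, s) {
    if (g > length(gids)) { best <<- max(best, s); return(invisible()) }
    recurse(g + 1L, used, s)
    for (h in seq_along(hids)) if (!used[h]) {
      used[h] <- TRUE
      recurse(g + 1L, used, s + agree[g, h])
      used[h] <- FALSE
    }
  }
  recurse(1L, logical(length(hids)), 0L)
  idtp <- best
  idfn <- nrow(gt) - idtp
  idfp <- nrow(hyp) - idtp
  list(idtp = idtp, idfp = idfp, idfn = idfn,
       idf1 = 2 * idtp / (2 * idtp + idfp + idfn))
}

# brute-force assignment by permutation enumeration (square matrices)
oracle_assignment_cost <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(C[cbind(seq_len(n), p)]), numeric(1)))
}

# random small tracking instance: continuous boxes so assignment ties have
# measure zero
random_instance <- function(n_frames = 5, max_obj = 4) {
  mk <- function() {
    rows <- list()
    for (f in seq_len(n_frames)) {
      n <- sample.int(max_obj + 1, 1) - 1L
      if (n == 0L) next
      ids <- sample.int(max_obj, n)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, id = ids,
        cx = stats::runif(n, 0, 30), cy = stats::runif(n, 0, 30),
        w = stats::runif(n, 2, 8), h = stats::runif(n, 2, 8), score = 1)
    }
    if (!length(rows)) return(frame_table())
    as_frame_table(do.call(rbind, rows))
  }
  gt <- mk()
  # hypothesis: perturbed copy of gt with some noise, drops and relabels
  if (nrow(gt)) {
    hyp <- as.data.frame(gt)
    hyp <- hyp[stats::runif(nrow(hyp)) > 0.2, , drop = FALSE]
    if (nrow(hyp)) {
      hyp$cx <- hyp$cx + stats::rnorm(nrow(hyp), 0, 1.5)
      hyp$cy <- hyp$cy + stats::rnorm(nrow(hyp), 0, 1.5)
      relabel <- sample.int(9, max_obj)          # random id mapping
      hyp$id <- relabel[hyp$id]
      # occasional mid-track identity corruption
      flip <- stats::runif(nrow(hyp)) < 0.1
      hyp$id[flip] <- hyp$id[flip] + 10L
    }
    hyp <- tryCatch(as_frame_table(hyp), error = function(e) frame_table())
  } else hyp <- frame_table()
  list(gt = gt, hyp = hyp)
}

# exact Kalman filter for the linear-Gaussian CV case
oracle_kalman <- function(z, F, G, H, q_sd, r_sd, x0, P0) {
  Q <- G %*% t(G) * q_sd^2
  R <- diag(r_sd^2, 2)
  x <- x0; P <- P0
  out <- matrix(NA_real_, nrow(z), length(x0))
  out[1, ] <- x
  for (k in seq_len(nrow(z))[-1]) {
    x <- F %*% x
    P <- F %*% P %*% t(F) + Q
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (z[k, ] - H %*% x)
    P <- (diag(length(x0)) - K %*% H) %*% P
    out[k, ] <- x
  }
  out
}

# linear-Gaussian CV simulation sharing nothing with the package integrator
simulate_cv_truth <- function(T, dt, q_sd, r_sd, x0 = c(0, 0, 1, 0.5)) {
  F <- rbind(c(1, 0, dt, 0), c(0, 1, 0, dt), c(0, 0, 1, 0), c(0, 0, 0, 1))
  G <- rbind(c(dt^2 / 2, 0), c(0, dt^2 / 2), c(dt, 0), c(0, dt))
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  x <- x0
  X <- matrix(NA_real_, T, 4); Z <- matrix(NA_real_, T, 2)
  for (k in seq_len(T)) {
    X[k, ] <- x
    Z[k, ] <- x[1:2] + stats::rnorm(2, 0, r_sd)
    x <- as.vector(F %*% x + G %*% stats::rnorm(2, 0, q_sd))
  }
  list(X = X, Z = Z, F = F, G = G, H = H)
}

# piecewise straight/turn ground truth for mode-identification checks
switching_truth <- function(T, dt, omega, leg, speed) {
  x <- c(0, 0); th <- 0
  modes <- rep(rep(c("straight", "turn"), length.out = ceiling(T / leg)),
               each = leg)[seq_len(T)]
  X <- matrix(NA_real_, T, 2)
  for (k in seq_len(T)) {
    X[k, ] <- x
    th <- th + (if (modes[k] == "turn") omega else 0) * dt
    x <- x + speed * dt * c(cos(th), sin(th))
  }
  list(X = X, modes = modes)
}
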