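#' Interacting-multiple-model particle filter
#'
#' The IMM-PF maintains one particle set per motion model plus model
#' probabilities mixed through a Markov transition matrix. One recursion
#' from time k-1 to k is:
#'
#' 1. **Interaction** ([imm_interact()]): mixing probabilities
#'    `mu(i|j) = P[i,j] mu(i) / b(j)` with normaliser
#'    `b(j) = sum_i P[i,j] mu(i)`; each particle's state is mixed across
#'    models, `x^l(j) <- sum_i x^l(i) mu(i|j)`.
#' 2. **Propagation and weighting** ([imm_propagate()]): per particle
#'    `x <- F x + G u` with sampled process noise, predicted observation
#'    `H x`, raw weight = observation-noise density of the residual
#'    `z - H x`, then per-model weight normalisation.
#' 3. **Resampling** ([imm_resample()]): systematic resampling per model;
#'    all weights return to `1/N`; the per-model estimate is the mean of the
#'    resampled set.
#' 4. **Model-probability update** ([imm_update_model_probs()]): pooled
#'    residual covariance `S` about the mean predicted observation,
#'    per-model likelihood `Lambda = mean_l N(r^l; 0, S)`, and
#'    `mu(j) <- Lambda(j) b(j) / B` with `B = sum_j Lambda(j) b(j)`.
#' 5. **Fusion**: `x_hat = sum_j x_hat(j) mu(j)`.
#'
#' [imm_step()] composes the five stages; [imm_filter()] runs a whole
#' observation sequence (NA rows coast: particles propagate, weights and
#' model probabilities are left untouched).
#'
#' @name imm_pf
NULL

#' Initialise an IMM-PF state
#'
#' Particles are drawn Gaussian around the first observation with the
#' configured position spread; initial velocities Gaussian around zero;
#' model probabilities uniform. Draws come from the ambient RNG stream (the
#' caller seeds it; [imm_filter()] does so from `filter_cfg$seed`).
#'
#' @param z0 first observation `(X, Y)` in metres.
#' @param filter_cfg the `filter` section of a `herd_config`.
#' @param dt time step in seconds.
#' @return A list of class `imm_state`: `models`, transition matrix `P`,
#'   particle matrices `X` (one `N x 4` matrix per model), weights `W`,
#'   model probabilities `mu`, step counter `k`.
#' @export
imm_init <- function(z0, filter_cfg, dt) {
  models <- build_models(filter_cfg, dt)
  M <- length(models)
  N <- filter_cfg$n_particles
  X <- lapply(seq_len(M), function(m)
    cbind(stats::rnorm(N, z0[1], filter_cfg$init_pos_spread),
          stats::rnorm(N, z0[2], filter_cfg$init_pos_spread),
          stats::rnorm(N, 0, filter_cfg$init_vel_spread),
          stats::rnorm(N, 0, filter_cfg$init_vel_spread)))
  structure(list(models = models, P = transition_matrix(filter_cfg),
                 X = X, W = rep(list(rep(1 / N, N)), M),
                 mu = rep(1 / M, M), k = 0L, flags = character()),
            class = "imm_state")
}

#' Interaction (mixing) stage
#'
#' Computes the mixing probabilities `mu(i|j) = P[i,j] mu(i) / b(j)` with
#' normaliser `b(j) = sum_i P[i,j] mu(i)`, then rebuilds each model's
#' particle set by a systematic draw from the *mixture* of all model clouds
#' weighted by `mu(.|j)` — the particle-filter form of IMM state mixing.
#' (Collapsing each particle to the convex combination of its cross-model
#' states instead would shrink the cloud's spread by a factor of
#' `sum_i mu(i|j)^2` every step and makes the filter overconfident; the
#' mixture draw preserves the mixed distribution.) With an identity
#' transition matrix each model reproduces its own particle multiset
#' exactly; with a single model the stage is a no-op.
#'
#' @param state an `imm_state`.
#' @return List with the mixed `state`, normalisation factors `b` (one per
#'   model) and the `M x M` mixing-probability matrix `mix` (`mix[i, j]` =
#'   probability of model i given a transition into model j).
#' @export
imm_interact <- function(state) {
  M <- length(state$models)
  if (M == 1L)
    return(list(state = state, b = 1, mix = matrix(1, 1, 1)))
  b <- as.vector(crossprod(state$P, state$mu))     # b[j] = sum_i P[i,j] mu[i]
  reach <- colSums(state$P) > 0
  if (any(b[reach] == 0))
    stop("degenerate model probabilities: b(m) = 0 for a reachable model")
  mix <- state$P * state$mu                         # rows i, cols j
  mix <- sweep(mix, 2, ifelse(b > 0, b, 1), "/")
  Xall <- do.call(rbind, state$X)
  Wall <- unlist(state$W)
  N <- nrow(state$X[[1]])
  Xmixed <- vector("list", M)
  for (j in seq_len(M)) {
    wj <- Wall * rep(mix[, j], each = N)
    wj <- wj / sum(wj)
    u <- (stats::runif(1) + seq_len(N) - 1) / N
    idx <- findInterval(u, cumsum(wj)) + 1L
    idx[idx > length(wj)] <- length(wj)
    Xmixed[[j]] <- Xall[idx, , drop = FALSE]
  }
  state$X <- Xmixed
  state$W <- rep(list(rep(1 / N, N)), M)
  list(state = state, b = b, mix = mix)
}

#' Propagation and weighting stage
#'
#' @param state an `imm_state` (normally the mixed state).
#' @param z observation `(X, Y)` in metres.
#' @return List with the propagated-and-weighted `state` and `collapsed`, a
#'   logical per model flagging weight collapse (all raw weights zero or
#'   non-finite, reset to uniform).
#' @export
imm_propagate <- function(state, z) {
  M <- length(state$models)
  collapsed <- logical(M)
  for (m in seq_len(M)) {
    mod <- state$models[[m]]
    N <- nrow(state$X[[m]])
    U <- mod$sample_u(N)
    Xn <- state$X[[m]] %*% t(mod$F) + U %*% t(mod$G)
    resid <- -sweep(Xn %*% t(mod$H), 2, z)          # z - H x
    w <- mod$dv(resid)
    s <- sum(w)
    if (!is.finite(s) || s <= 0) {
      w <- rep(1 / N, N)
      collapsed[m] <- TRUE
    } else {
      w <- w / s
    }
    state$X[[m]] <- Xn
    state$W[[m]] <- w
  }
  if (any(collapsed))
    state$flags <- c(state$flags,
                     sprintf("weight collapse in model %s at step %d",
                             paste(which(collapsed), collapse = ","),
                             state$k + 1L))
  list(state = state, collapsed = collapsed)
}

#' Systematic resampling stage
#'
#' @param state an `imm_state` with normalised weights.
#' @return List with the resampled `state` (all weights `1/N`) and `xhat`,
#'   an `M x 4` matrix of per-model particle means.
#' @export
imm_resample <- function(state) {
  M <- length(state$models)
  xhat <- matrix(NA_real_, M, 4)
  for (m in seq_len(M)) {
    w <- state$W[[m]]
    N <- length(w)
    u <- (stats::runif(1) + seq_len(N) - 1) / N
    idx <- findInterval(u, cumsum(w)) + 1L
    idx[idx > N] <- N                               # guard cumsum rounding
    state$X[[m]] <- state$X[[m]][idx, , drop = FALSE]
    state$W[[m]] <- rep(1 / N, N)
    xhat[m, ] <- colMeans(state$X[[m]])
  }
  list(state = state, xhat = xhat)
}

#' Model-probability update stage
#'
#' Residuals are taken on the resampled particles; the pooled residual
#' covariance `S` (about the mean predicted observation) is regularised by
#' `1e-9 * trace(S)/dim * I` (with an absolute floor) when near-singular so
#' the Gaussian likelihood stays defined.
#'
#' @param state a resampled `imm_state`.
#' @param z the observation.
#' @param b interaction normalisation factors from [imm_interact()].
#' @return List with the updated `state` and a `report` carrying `b`,
#'   per-model `lambda`, covariances `S`, mean predicted observations
#'   `zbar`, and the overall normaliser `B`. When `B` is zero the model
#'   probabilities are left unchanged and a flag is recorded.
#' @export
imm_update_model_probs <- function(state, z, b) {
  M <- length(state$models)
  lambda <- numeric(M)
  S_list <- vector("list", M)
  zbar_m <- matrix(NA_real_, M, 2)
  for (m in seq_len(M)) {
    mod <- state$models[[m]]
    Zp <- state$X[[m]] %*% t(mod$H)
    N <- nrow(Zp)
    zbar <- colMeans(Zp)
    D <- sweep(Zp, 2, zbar)
    # pooled predicted-observation spread plus the measurement-noise
    # covariance: the sample analogue of the classical IMM residual
    # covariance H P H' + R (without R the likelihood degenerates as the
    # process noise shrinks)
    S <- crossprod(D) / N + diag(mod$obs_noise^2, 2)
    S <- regularize_cov(S)
    resid <- -sweep(Zp, 2, z)                       # r^l = z - H x^l
    lambda[m] <- mean(dmvnorm0(resid, S))
    S_list[[m]] <- S
    zbar_m[m, ] <- zbar
  }
  B <- sum(lambda * b)
  if (is.finite(B) && B > 0) {
    state$mu <- lambda * b / B
  } else {
    state$flags <- c(state$flags,
                     sprintf("likelihood collapse at step %d", state$k + 1L))
  }
  list(state = state,
       report = list(b = b, lambda = lambda, S = S_list, zbar = zbar_m,
                     B = B))
}

regularize_cov <- function(S) {
  d <- nrow(S)
  eps <- 1e-9 * sum(diag(S)) / d
  if (eps <= 0 || !is.finite(eps)) eps <- 1e-12
  ok <- FALSE
  for (i in 0:8) {
    test <- S + diag(eps * 10^i, d)
    ch <- tryCatch(chol(test), error = function(e) NULL)
    if (!is.null(ch) && all(diag(ch) > 1e-154)) { S <- test; ok <- TRUE; break }
  }
  if (!ok) S <- diag(1e-6, d)
  S
}

# zero-mean multivariate normal density for residual rows
dmvnorm0 <- function(resid, S) {
  ch <- chol(S)
  q <- colSums(backsolve(ch, t(resid), transpose = TRUE)^2)
  exp(-q / 2) / ((2 * pi)^(ncol(resid) / 2) * prod(diag(ch)))
}

#' One full IMM-PF recursion
#'
#' Composes interaction, propagation/weighting, resampling,
#' model-probability update and fusion. Deterministic given the seeded RNG
#' stream. A missing observation (`z` all `NA`) coasts: particles propagate
#' under their models, weights and model probabilities are unchanged.
#'
#' @param state an `imm_state`.
#' @param z observation `(X, Y)` or a length-2 `NA` vector.
#' @return List with the new `state` and `estimate`: fused state `x`
#'   (`sum_m x_hat(m) mu(m)`), per-model estimates `per_model`, model
#'   probabilities `mu`, and the update `report` (NULL when coasting).
#' @export
imm_step <- function(state, z) {
  M <- length(state$models)
  if (all(is.na(z))) {
    xhat <- matrix(NA_real_, M, 4)
    for (m in seq_len(M)) {
      mod <- state$models[[m]]
      N <- nrow(state$X[[m]])
      state$X[[m]] <- state$X[[m]] %*% t(mod$F) + mod$sample_u(N) %*% t(mod$G)
      xhat[m, ] <- colMeans(state$X[[m]])
    }
    state$k <- state$k + 1L
    est <- list(x = as.vector(state$mu %*% xhat), per_model = xhat,
                mu = state$mu, report = NULL)
    return(list(state = state, estimate = est))
  }
  s1 <- imm_interact(state)
  s2 <- imm_propagate(s1$state, z)
  s3 <- imm_resample(s2$state)
  s4 <- imm_update_model_probs(s3$state, z, s1$b)
  state <- s4$state
  state$k <- state$k + 1L
  est <- list(x = as.vector(state$mu %*% s3$xhat), per_model = s3$xhat,
              mu = state$mu, report = s4$report)
  list(state = state, estimate = est)
}

#' Filter a whole observation sequence
#'
#' Seeds the RNG from `filter_cfg$seed` (unless `NULL`), initialises on the
#' first non-missing observation, then applies [imm_step()] to each later
#' row. Rows before the first observation yield no estimate; `NA` rows after
#' it coast.
#'
#' @param z numeric matrix, one `(X, Y)` observation per row; `NA` rows
#'   denote missing observations.
#' @param filter_cfg the `filter` section of a `herd_config`.
#' @param dt time step in seconds.
#' @param seed overrides `filter_cfg$seed` when not `NULL`.
#' @return List of class `imm_fit`: `estimates`, a data frame with one row
#'   per input row (`step`, fused `X, Y, Vx, Vy`, one `mu_*` column per
#'   model, `observed`), and the final `state`.
#' @examples
#' cfg <- default_config()$filter
#' cfg$models <- "cv"; cfg$n_particles <- 200L; cfg$seed <- 7L
#' z <- cbind(seq(0, 5, by = 0.5), 0)
#' fit <- imm_filter(z, cfg, dt = 0.5)
#' tail(fit$estimates, 3)
#' @export
imm_filter <- function(z, filter_cfg, dt, seed = NULL) {
  z <- matrix(as.numeric(z), ncol = 2)
  seed <- if (!is.null(seed)) seed else filter_cfg$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  T <- nrow(z)
  obs_ok <- stats::complete.cases(z)
  mods <- filter_cfg$models
  est <- data.frame(step = seq_len(T), X = NA_real_, Y = NA_real_,
                    Vx = NA_real_, Vy = NA_real_)
  for (nm in mods) est[[paste0("mu_", nm)]] <- NA_real_
  est$observed <- obs_ok
  first <- which(obs_ok)[1]
  if (is.na(first)) return(structure(list(estimates = est, state = NULL),
                                     class = "imm_fit"))
  state <- imm_init(z[first, ], filter_cfg, dt)
  xhat0 <- t(vapply(state$X, colMeans, numeric(4)))
  est[first, c("X", "Y", "Vx", "Vy")] <- as.vector(state$mu %*% xhat0)
  est[first, paste0("mu_", mods)] <- state$mu
  if (first < T) {
    for (t in seq(first + 1L, T)) {
      zt <- if (obs_ok[t]) z[t, ] else c(NA_real_, NA_real_)
      stp <- imm_step(state, zt)
      state <- stp$state
      est[t, c("X", "Y", "Vx", "Vy")] <- stp$estimate$x
      est[t, paste0("mu_", mods)] <- stp$estimate$mu
    }
  }
  structure(list(estimates = est, state = state), class = "imm_fit")
}

#' @export
print.imm_fit <- function(x, ...) {
  n <- sum(x$estimates$observed)
  cat(sprintf("<imm_fit> %d steps (%d observed), models: %s\n",
              nrow(x$estimates), n,
              paste(vapply(x$state$models, `[[`, character(1), "name"),
                    collapse = ", ")))
  if (length(x$state$flags)) cat("  flags:", length(x$state$flags), "\n")
  invisible(x)
}
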