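make_state <- function(X, mu, P, obs_noise = 0.5, accel_noise = 0.4,
                       dt = 0.1) {
  M <- length(X)
  models <- lapply(seq_len(M), function(i) mm_cv(dt, accel_noise, obs_noise))
  structure(list(models = models, P = P, X = X,
                 W = lapply(X, function(x) rep(1 / nrow(x), nrow(x))),
                 mu = mu, k = 0L, flags = character()),
            class = "imm_state")
}

test_that("interaction computes Markov mixing factors correctly", {
  X <- list(matrix(rnorm(40), 10), matrix(rnorm(40), 10))
  st <- make_state(X, mu = c(0.5, 0.5),
                   P = rbind(c(0.9, 0.1), c(0.1, 0.9)))
  out <- imm_interact(st)
  expect_equal(out$b, c(0.5, 0.5))
  expect_equal(out$mix, rbind(c(0.9, 0.1), c(0.1, 0.9)))
})

test_that("identity transitions leave each model's particle multiset alone", {
  set.seed(1)
  X <- list(matrix(rnorm(40), 10), matrix(rnorm(40), 10))
  st <- make_state(X, mu = c(0.3, 0.7), P = diag(2))
  out <- imm_interact(st)
  for (m in 1:2) {
    a <- out$state$X[[m]][order(out$state$X[[m]][, 1]), ]
    b <- X[[m]][order(X[[m]][, 1]), ]
    expect_equal(a, b)
  }
})

test_that("a single model makes interaction a no-op", {
  set.seed(2)
  X <- list(matrix(rnorm(40), 10))
  st <- make_state(X, mu = 1, P = matrix(1, 1, 1))
  out <- imm_interact(st)
  expect_identical(out$state$X[[1]], X[[1]])
  expect_equal(out$b, 1)
})

test_that("propagation is the exact linear map under zero process noise", {
  set.seed(3)
  X <- list(matrix(rnorm(40), 10))
  st <- make_state(X, mu = 1, P = matrix(1, 1, 1), accel_noise = 0)
  out <- imm_propagate(st, z = c(0, 0))
  expect_equal(out$state$X[[1]], X[[1]] %*% t(st$models[[1]]$F))
})

test_that("weights favour zero residuals and normalise per model", {
  # one particle exactly at the observation gets the maximal raw weight
  X <- list(rbind(c(5, 5, 0, 0), c(9, 9, 0, 0), c(3, 1, 0, 0)))
  st <- make_state(X, mu = 1, P = matrix(1, 1, 1), accel_noise = 0, dt = 0)
  st$models[[1]]$F <- diag(4)                      # hold particles in place
  out <- imm_propagate(st, z = c(5, 5))
  expect_equal(which.max(out$state$W[[1]]), 1L)
  expect_equal(sum(out$state$W[[1]]), 1)
  # unanimous zero weights collapse to uniform with a flag
  out2 <- imm_propagate(st, z = c(5e7, 5e7))
  expect_true(out2$collapsed)
  expect_equal(out2$state$W[[1]], rep(1 / 3, 3))
})

test_that("systematic resampling preserves uniform multisets and copies a
           unit-weight particle", {
  set.seed(4)
  X <- list(matrix(rnorm(40), 10))
  st <- make_state(X, mu = 1, P = matrix(1, 1, 1))
  out <- imm_resample(st)
  expect_equal(out$state$X[[1]][order(out$state$X[[1]][, 1]), ],
               X[[1]][order(X[[1]][, 1]), ])
  expect_equal(out$state$W[[1]], rep(0.1, 10))
  expect_equal(out$xhat[1, ], colMeans(X[[1]]))
  st$W[[1]] <- c(rep(0, 6), 1, rep(0, 3))
  out <- imm_resample(st)
  expect_true(all(apply(out$state$X[[1]], 1,
                        function(r) all(r == X[[1]][7, ]))))
})

test_that("model probabilities update by likelihood times prior factor", {
  set.seed(5)
  # identical particle clouds: equal likelihoods, so mu follows b
  Xc <- matrix(rnorm(40, sd = 0.1), 10)
  st <- make_state(list(Xc, Xc), mu = c(0.3, 0.7),
                   P = rbind(c(0.9, 0.1), c(0.1, 0.9)))
  out <- imm_update_model_probs(st, z = colMeans(Xc)[1:2], b = c(0.5, 0.5))
  expect_equal(out$state$mu, c(0.5, 0.5))
  expect_equal(sum(out$state$mu), 1)
  # a vastly better-fitting model takes (almost) all probability
  Xfar <- Xc; Xfar[, 1] <- Xfar[, 1] + 100
  st2 <- make_state(list(Xc, Xfar), mu = c(0.5, 0.5),
                    P = rbind(c(0.9, 0.1), c(0.1, 0.9)))
  out2 <- imm_update_model_probs(st2, z = colMeans(Xc)[1:2],
                                 b = c(0.5, 0.5))
  expect_gt(out2$state$mu[1], 1 - 1e-8)
  expect_equal(out2$report$B,
               sum(out2$report$lambda * c(0.5, 0.5)))
})

test_that("a full step fuses per-model estimates by model probability", {
  set.seed(6)
  cfg <- default_config()$filter
  cfg$n_particles <- 100L
  st <- imm_init(c(0, 0), cfg, dt = 0.1)
  stp <- imm_step(st, c(0.05, -0.02))
  expect_equal(stp$estimate$x,
               as.vector(stp$estimate$mu %*% stp$estimate$per_model))
  expect_equal(sum(stp$estimate$mu), 1)
})

test_that("weights and model probabilities stay normalised over a long run", {
  set.seed(7)
  cfg <- default_config()$filter
  cfg$n_particles <- 100L
  st <- imm_init(c(0, 0), cfg, dt = 0.1)
  z <- c(0, 0)
  for (k in seq_len(500)) {
    z <- z + c(0.05, 0.02) + rnorm(2, 0, 0.1)
    stp <- imm_step(st, z)
    st <- stp$state
    expect_equal(sum(st$mu), 1, tolerance = 1e-12)
    for (m in seq_along(st$W))
      expect_equal(sum(st$W[[m]]), 1, tolerance = 1e-12)
  }
  expect_equal(st$k, 500L)
})

test_that("identical configuration and seed give bit-identical estimates", {
  cfg <- default_config()$filter
  cfg$n_particles <- 150L
  z <- cbind(seq(0, 4, length.out = 30), seq(0, 2, length.out = 30))
  a <- imm_filter(z, cfg, dt = 0.1, seed = 99)
  b <- imm_filter(z, cfg, dt = 0.1, seed = 99)
  expect_identical(a$estimates, b$estimates)
  c <- imm_filter(z, cfg, dt = 0.1, seed = 100)
  expect_false(identical(a$estimates$X, c$estimates$X))
})

test_that("missing observations coast the filter instead of stopping it", {
  cfg <- default_config()$filter
  cfg$n_particles <- 150L
  z <- cbind(seq(0, 4, length.out = 30), 0)
  z[10:12, ] <- NA
  fit <- imm_filter(z, cfg, dt = 0.1, seed = 3)
  expect_false(anyNA(fit$estimates$X))
  expect_false(fit$estimates$observed[10])
})

test_that("the particle filter approaches the Kalman solution as N grows", {
  dt <- 0.1
  gaps <- sapply(c(100L, 500L, 2000L), function(N) {
    ratios <- sapply(1:8, function(sd) {
      set.seed(sd)
      sim <- simulate_cv_truth(40, dt, q_sd = 0.4, r_sd = 0.25)
      cfg <- default_config()$filter
      cfg$models <- "cv"; cfg$n_particles <- N
      cfg$accel_noise <- 0.4; cfg$obs_noise <- 0.25
      cfg$init_pos_spread <- 0.25; cfg$init_vel_spread <- 1
      fit <- imm_filter(sim$Z, cfg, dt, seed = 7000 + sd)
      kf <- oracle_kalman(sim$Z, sim$F, sim$G, sim$H, 0.4, 0.25,
                          c(sim$Z[1, ], 0, 0),
                          diag(c(0.25^2, 0.25^2, 1, 1)))
      pf_rmse <- sqrt(mean((fit$estimates$X - sim$X[, 1])^2 +
                           (fit$estimates$Y - sim$X[, 2])^2))
      kf_rmse <- sqrt(mean((kf[, 1] - sim$X[, 1])^2 +
                           (kf[, 2] - sim$X[, 2])^2))
      pf_rmse / kf_rmse
    })
    mean(ratios)
  })
  expect_true(all(diff(gaps) < 0))     # gap to the Kalman optimum shrinks
  expect_lt(gaps[3], 1.1)
})

test_that("the MAP model tracks the true mode on separable dynamics", {
  dt <- 0.5
  accs <- sapply(1:5, function(sd) {
    set.seed(sd)
    tj <- switching_truth(80, dt, omega = 1.0, leg = 20, speed = 1.5)
    z <- tj$X + matrix(rnorm(160, 0, 0.1), ncol = 2)
    cfg <- default_config()$filter
    cfg$models <- c("cv", "ct_left"); cfg$turn_rate <- 1.0
    cfg$obs_noise <- 0.1; cfg$accel_noise <- 0.2; cfg$n_particles <- 400L
    fit <- imm_filter(z, cfg, dt, seed = 40 + sd)
    map <- c("straight", "turn")[apply(fit$estimates[, c("mu_cv",
                                                         "mu_ct_left")],
                                       1, which.max)]
    mean((map == tj$modes)[16:80])
  })
  expect_gt(mean(accs), 0.6)
  expect_true(all(accs > 0.6))
})
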