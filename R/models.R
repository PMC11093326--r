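#' Motion models for the IMM particle filter
#'
#' Each model describes one hypothesis about target dynamics on the ground
#' plane, with state `x = (X, Y, Vx, Vy)` (metres, metres/second, north-east
#' axes) and discrete time step `dt` seconds:
#'
#' * state transition `x_k = F x_{k-1} + G u_{k-1}` with white acceleration
#'   `u ~ N(0, sigma_a^2 I_2)` entering through `G`
#'   (`dt^2/2` on position, `dt` on velocity);
#' * observation `z_k = H x_k + v_k`, by default the ground-plane position
#'   with `v ~ N(0, sigma_z^2 I_2)`.
#'
#' `mm_cv()` is the nearly-constant-velocity model; `mm_ct()` is a
#' coordinated turn at fixed rate `omega` (rad/s, positive =
#' anti-clockwise). A model is a plain list with fields `name`, `F`, `G`,
#' `H`, `sample_u(n)` (process-noise sampler) and `dv(resid)` (observation-
#' noise density on residual rows), so user-defined models with the same
#' state dimension drop in freely.
#'
#' @param dt time step in seconds.
#' @param accel_noise process-noise (white acceleration) standard deviation
#'   in m/s^2.
#' @param obs_noise observation-noise standard deviation in metres per axis.
#' @param omega turn rate in rad/s.
#' @param name model label.
#' @param ... passed to the internal constructor: `jump_frac` (fraction of
#'   particles drawing heavy-tailed process noise each step, default 0.05)
#'   and `jump_scale` (their acceleration-noise multiplier, default 8).
#' @return A motion-model list.
#' @export
mm_cv <- function(dt, accel_noise, obs_noise, name = "cv", ...) {
  F <- rbind(c(1, 0, dt, 0),
             c(0, 1, 0, dt),
             c(0, 0, 1, 0),
             c(0, 0, 0, 1))
  make_model(name, F, dt, accel_noise, obs_noise, ...)
}

#' @rdname mm_cv
#' @export
mm_ct <- function(dt, omega, accel_noise, obs_noise,
                  name = sprintf("ct(%+.2g)", omega), ...) {
  if (abs(omega) < 1e-12) return(mm_cv(dt, accel_noise, obs_noise, name, ...))
  wt <- omega * dt
  s <- sin(wt); c <- cos(wt)
  F <- rbind(c(1, 0, s / omega, -(1 - c) / omega),
             c(0, 1, (1 - c) / omega, s / omega),
             c(0, 0, c, -s),
             c(0, 0, s, c))
  make_model(name, F, dt, accel_noise, obs_noise, ...)
}

make_model <- function(name, F, dt, accel_noise, obs_noise,
                       jump_frac = 0.05, jump_scale = 8) {
  G <- rbind(c(dt^2 / 2, 0),
             c(0, dt^2 / 2),
             c(dt, 0),
             c(0, dt))
  H <- rbind(c(1, 0, 0, 0),
             c(0, 1, 0, 0))
  force(accel_noise); force(obs_noise); force(jump_frac); force(jump_scale)
  list(name = name, F = F, G = G, H = H,
       obs_noise = obs_noise, accel_noise = accel_noise,
       # heavy-tailed process noise: a small fraction of particles draw
       # from a much wider acceleration so the filter can re-acquire after
       # abrupt maneuvers (direction reversals) outside the model set
       sample_u = function(n) {
         sd <- rep(accel_noise, n)
         if (jump_frac > 0)
           sd[stats::runif(n) < jump_frac] <- accel_noise * jump_scale
         matrix(stats::rnorm(2 * n, 0, rep(sd, 2)), ncol = 2)
       },
       # observation-noise density evaluated on residual rows (N x 2)
       dv = function(resid) {
         q <- rowSums(resid^2) / obs_noise^2
         exp(-q / 2) / (2 * pi * obs_noise^2)
       })
}

#' Build the model set named in a filter configuration
#'
#' Recognised names: `"cv"`, `"ct_left"` (turn rate `+turn_rate`),
#' `"ct_right"` (`-turn_rate`). Entries of `filter_cfg$custom_models` (a
#' named list of model lists) are taken verbatim.
#'
#' @param filter_cfg the `filter` section of a `herd_config`.
#' @param dt time step in seconds.
#' @return List of motion models.
#' @export
build_models <- function(filter_cfg, dt) {
  lapply(filter_cfg$models, function(nm) {
    if (!is.null(filter_cfg$custom_models[[nm]]))
      return(filter_cfg$custom_models[[nm]])
    jf <- if (!is.null(filter_cfg$jump_frac)) filter_cfg$jump_frac else 0.05
    js <- if (!is.null(filter_cfg$jump_scale)) filter_cfg$jump_scale else 8
    switch(nm,
      cv = mm_cv(dt, filter_cfg$accel_noise, filter_cfg$obs_noise,
                 jump_frac = jf, jump_scale = js),
      ct_left = mm_ct(dt, filter_cfg$turn_rate, filter_cfg$accel_noise,
                      filter_cfg$obs_noise, name = "ct_left",
                      jump_frac = jf, jump_scale = js),
      ct_right = mm_ct(dt, -filter_cfg$turn_rate, filter_cfg$accel_noise,
                       filter_cfg$obs_noise, name = "ct_right",
                       jump_frac = jf, jump_scale = js),
      stop("unknown motion model: ", nm))
  })
}
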