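#' Default configuration
#'
#' One nested list drives the whole pipeline, with three sections:
#'
#' * `tracker` — two-stage association: stage-1 gate factor `kappa`
#'   (gate radius = `kappa * sqrt(w*h)` of the candidate track's last box),
#'   stage-2 factor `kappa2` (applied to the same formula; drifted positions
#'   are less certain), detection `score_threshold`, exponential-moving-
#'   average weight `alpha` for the motion vector, stranding `lifespan`
#'   (initial health points, default 20 frames), `stage2` on/off, and the
#'   drift direction used for stranded candidates (`"forward"` or
#'   `"backward"`, i.e. the negated motion vector).
#' * `filter` — IMM particle filter: motion-model names, particles per model
#'   `n_particles`, Markov `self_prob` (diagonal of the model transition
#'   matrix; off-diagonal mass spread uniformly) or a full `transition`
#'   matrix, coordinated-turn rate `turn_rate` (rad/s), process noise
#'   `accel_noise` (m/s^2), observation noise `obs_noise` (m per axis),
#'   initialisation spreads, and the `seed`.
#' * `scenario` — synthetic-scenario generator: see [simulate_scenario()].
#' * `camera` — pinhole intrinsics used by both the simulator and the
#'   geolocation chain.
#'
#' @return A nested list of class `herd_config`.
#' @export
default_config <- function() {
  cfg <- list(
    tracker = list(
      kappa = 1.0,
      kappa2 = 1.5,
      score_threshold = 0.3,
      alpha = 0.5,
      lifespan = 20L,
      stage2 = TRUE,
      stage2_direction = "forward"
    ),
    filter = list(
      models = c("cv", "ct_left", "ct_right"),
      n_particles = 500L,
      self_prob = 0.9,
      transition = NULL,
      turn_rate = 0.4,
      accel_noise = 0.4,
      jump_frac = 0.05,
      jump_scale = 8,
      obs_noise = 0.25,
      init_pos_spread = 0.5,
      init_vel_spread = 1.0,
      seed = NULL
    ),
    camera = list(f = 400, width = 1280, height = 720, u0 = 640, v0 = 360),
    scenario = list(
      type = "markov",
      n_targets = 6L,
      n_frames = 80L,
      frame_rate = 10,
      arena = c(16, 28),
      margin = 1.5,
      footprint = c(2.4, 0.9),
      speed_range = c(0.5, 1.5),
      turn_rate = 0.4,
      switch_prob = 0.05,
      altitude = 10,
      pos_jitter = 0.15,
      att_jitter = 0.01,
      center_noise = 1.5,
      size_noise = 0.05,
      p_miss = 0.02,
      fp_rate = 0.1,
      occ_iou = 0.3,
      score_true = c(8, 2),
      score_false = c(2, 5),
      gap = 5L,
      seed = 1L
    )
  )
  class(cfg) <- "herd_config"
  cfg
}

#' Load a configuration document
#'
#' Reads a YAML document with any subset of the `tracker` / `filter` /
#' `camera` / `scenario` sections; missing keys are filled with the
#' documented defaults (see [default_config()]) and the result is validated.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @param overrides named nested list merged over the file contents
#'   (useful programmatically).
#' @return A validated `herd_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    doc <- yaml::read_yaml(path)
    if (!is.null(doc)) cfg <- merge_deep(cfg, doc)
  }
  if (length(overrides)) cfg <- merge_deep(cfg, overrides)
  if (!is.null(cfg$filter$transition) && !is.matrix(cfg$filter$transition)) {
    tr <- cfg$filter$transition
    cfg$filter$transition <- do.call(rbind, lapply(tr, as.numeric))
  }
  cfg <- normalize_config(cfg)
  validate_config(cfg)
  class(cfg) <- "herd_config"
  cfg
}

merge_deep <- function(base, over) {
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]]) && !is.null(names(over[[k]]))) {
      base[[k]] <- merge_deep(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

normalize_config <- function(cfg) {
  cfg$tracker$lifespan <- as.integer(cfg$tracker$lifespan)
  cfg$filter$n_particles <- as.integer(cfg$filter$n_particles)
  cfg$scenario$n_targets <- as.integer(cfg$scenario$n_targets)
  cfg$scenario$n_frames <- as.integer(cfg$scenario$n_frames)
  cfg$scenario$gap <- as.integer(cfg$scenario$gap)
  for (k in c("arena", "footprint", "speed_range", "score_true", "score_false"))
    if (!is.null(cfg$scenario[[k]])) cfg$scenario[[k]] <- as.numeric(cfg$scenario[[k]])
  cfg$filter$models <- as.character(cfg$filter$models)
  cfg
}

validate_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  tr <- cfg$tracker
  chk(is.finite(tr$lifespan) && tr$lifespan >= 1L, "tracker.lifespan")
  chk(tr$kappa > 0, "tracker.kappa")
  chk(tr$kappa2 > 0, "tracker.kappa2")
  chk(tr$alpha > 0 && tr$alpha <= 1, "tracker.alpha")
  chk(tr$score_threshold >= 0 && tr$score_threshold <= 1,
      "tracker.score_threshold")
  chk(tr$stage2_direction %in% c("forward", "backward"),
      "tracker.stage2_direction")
  fl <- cfg$filter
  chk(fl$n_particles >= 1L, "filter.n_particles")
  chk(length(fl$models) >= 1L, "filter.models")
  chk(fl$self_prob >= 0 && fl$self_prob <= 1, "filter.self_prob")
  if (!is.null(fl$transition)) {
    M <- length(fl$models)
    ok <- is.matrix(fl$transition) && all(dim(fl$transition) == c(M, M)) &&
      all(fl$transition >= 0) &&
      all(abs(rowSums(fl$transition) - 1) < 1e-8)
    chk(ok, "filter.transition")
  }
  chk(fl$obs_noise > 0, "filter.obs_noise")
  chk(fl$accel_noise >= 0, "filter.accel_noise")
  sc <- cfg$scenario
  chk(sc$altitude > 0, "scenario.altitude")
  chk(sc$n_targets >= 1L, "scenario.n_targets")
  chk(sc$n_frames >= 1L, "scenario.n_frames")
  chk(sc$frame_rate > 0, "scenario.frame_rate")
  for (k in c("switch_prob", "p_miss", "occ_iou"))
    chk(sc[[k]] >= 0 && sc[[k]] <= 1, paste0("scenario.", k))
  chk(sc$fp_rate >= 0, "scenario.fp_rate")
  chk(all(sc$footprint > 0), "scenario.footprint")
  chk(all(sc$arena > 2 * sc$margin), "scenario.arena")
  cam <- cfg$camera
  chk(cam$f > 0, "camera.f")
  chk(cam$u0 > 0 && cam$u0 < cam$width && cam$v0 > 0 && cam$v0 < cam$height,
      "camera.principal_point")
  if (length(bad))
    stop("invalid configuration value(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Model transition matrix implied by a configuration
#'
#' Diagonal `self_prob`, off-diagonal mass uniform — unless a full
#' `transition` matrix was supplied.
#'
#' @param filter_cfg the `filter` section of a `herd_config`.
#' @return An `M x M` row-stochastic matrix.
#' @export
transition_matrix <- function(filter_cfg) {
  M <- length(filter_cfg$models)
  if (!is.null(filter_cfg$transition)) return(filter_cfg$transition)
  if (M == 1L) return(matrix(1, 1, 1))
  p <- filter_cfg$self_prob
  P <- matrix((1 - p) / (M - 1), M, M)
  diag(P) <- p
  P
}

#' Built-in scenario presets
#'
#' * `"separated"` — well-separated parallel straight movers, corruption
#'   off: the tracker must reproduce ground truth exactly.
#' * `"crossing"` — two targets on the same lane; the faster one overtakes
#'   the slower and is occluded (dropped) for exactly `gap` frames. Fully
#'   deterministic; the occlusion-recovery acceptance scenario.
#' * `"maneuvering"` — one target alternating straight legs and coordinated
#'   turns; the IMM-PF acceptance scenario.
#'
#' @param name preset name.
#' @param ... scenario-section overrides (e.g. `gap = 25`).
#' @return A `herd_config`.
#' @export
preset_config <- function(name = c("separated", "crossing", "maneuvering"),
                          ...) {
  name <- match.arg(name)
  ov <- list(...)
  sc <- switch(name,
    separated = list(type = "separated", n_targets = 4L, n_frames = 60L,
                     pos_jitter = 0, att_jitter = 0, center_noise = 0,
                     size_noise = 0, p_miss = 0, fp_rate = 0, occ_iou = 1,
                     score_true = NULL),
    crossing = list(type = "crossing", n_targets = 2L, n_frames = 70L,
                    pos_jitter = 0, att_jitter = 0, center_noise = 0,
                    size_noise = 0, p_miss = 0, fp_rate = 0, occ_iou = 0.5,
                    score_true = NULL, gap = 5L),
    maneuvering = list(type = "maneuvering", n_targets = 1L, n_frames = 100L,
                       speed_range = c(1.2, 1.2), turn_rate = 0.6)
  )
  sc[names(ov)] <- ov
  over <- list(scenario = sc)
  # the filter model registry mirrors the simulator's turn rate
  if (!is.null(sc$turn_rate)) over$filter <- list(turn_rate = sc$turn_rate)
  load_config(overrides = over)
}

#' @export
print.herd_config <- function(x, ...) {
  cat("<herd_config>\n")
  cat(sprintf("  tracker: kappa %g / %g, score >= %g, alpha %g, lifespan %d, stage2 %s\n",
              x$tracker$kappa, x$tracker$kappa2, x$tracker$score_threshold,
              x$tracker$alpha, x$tracker$lifespan, x$tracker$stage2))
  cat(sprintf("  filter : %s, N = %d/model, obs sd %g m\n",
              paste(x$filter$models, collapse = "+"), x$filter$n_particles,
              x$filter$obs_noise))
  cat(sprintf("  scenario: %s, %d targets, %d frames @ %g fps, altitude %g m\n",
              x$scenario$type, x$scenario$n_targets, x$scenario$n_frames,
              x$scenario$frame_rate, x$scenario$altitude))
  invisible(x)
}
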