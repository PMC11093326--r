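#' Pixel to ground-plane geolocation
#'
#' Three right-handed frames are involved (conventions fixed package-wide):
#'
#' * **C** (camera): origin at the optical centre, `z` along the optical
#'   axis, `x` image-right, `y` image-down.
#' * **I** (IMU / body): `x` forward, `y` right, `z` down. At zero gimbal
#'   angles the optical axis points forward; the gimbal applies pan about
#'   the body `z` axis, then tilt about the panned `y` axis
#'   (tilt = -90 degrees is nadir).
#' * **L** (local geographic): north-east-down; `X` north, `Y` east, `Z`
#'   down. The attitude rotation I -> L is intrinsic yaw-pitch-roll
#'   (Z-Y-X order).
#'
#' The line-of-sight angles of a unit vector in L are the height angle
#' `rho = arccos(v_Z)` (0 = straight down) and the field-of-view direction
#' angle `eps = atan2(v_Y, v_X)` (azimuth from north, positive toward
#' east). Lever arms between the camera, IMU and GPS origins are neglected:
#' direction vectors rotate, positions come from the GPS origin.
#'
#' @name geolocation
NULL

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

# camera axes expressed in body axes at zero gimbal:
# cam x (right) -> body y, cam y (down) -> body z, cam z (optical) -> body x
CAM_MOUNT <- rbind(c(0, 0, 1),
                   c(1, 0, 0),
                   c(0, 1, 0))

#' Rotation from camera frame to local geographic frame
#'
#' @param pose one UAV pose (a single-row `uav_poses` data frame or a list
#'   with fields `roll`, `pitch`, `yaw`, `pan`, `tilt`).
#' @return 3x3 rotation matrix `R` with `v_L = R %*% v_C`.
#' @export
camera_rotation <- function(pose) {
  r_ic <- rot_z(pose$pan) %*% rot_y(pose$tilt) %*% CAM_MOUNT
  r_li <- rot_z(pose$yaw) %*% rot_y(pose$pitch) %*% rot_x(pose$roll)
  r_li %*% r_ic
}

#' Back-project a pixel to a unit line-of-sight vector in the camera frame
#'
#' Pinhole model: `((x_p - u0)/f, (y_p - v0)/f, 1)`, normalised.
#'
#' @param px pixel coordinates `(x_p, y_p)`.
#' @param intrinsics a [camera_intrinsics()] object.
#' @return Unit 3-vector in the camera frame.
#' @export
pixel_to_los_camera <- function(px, intrinsics) {
  if (px[1] < 0 || px[1] > intrinsics$width ||
      px[2] < 0 || px[2] > intrinsics$height)
    stop("pixel outside image bounds")
  v <- c((px[1] - intrinsics$u0) / intrinsics$f,
         (px[2] - intrinsics$v0) / intrinsics$f, 1)
  v / sqrt(sum(v^2))
}

#' Rotate a camera-frame direction into the geographic frame
#'
#' @param vec unit vector in the camera frame.
#' @param pose UAV pose (attitude + gimbal angles).
#' @return Unit vector in the north-east-down frame.
#' @export
camera_to_geographic <- function(vec, pose) {
  as.vector(camera_rotation(pose) %*% vec)
}

#' Line-of-sight angles of a geographic-frame direction
#'
#' @param vec unit vector in the north-east-down frame.
#' @return List with `rho` (height angle, radians in \[0, pi\]; 0 is
#'   straight down) and `eps` (azimuth from north, `(-pi, pi]`; 0 by
#'   convention at nadir where it is undefined).
#' @export
los_angles <- function(vec) {
  n <- sqrt(sum(vec^2))
  if (n == 0) stop("zero line-of-sight vector")
  vec <- vec / n
  list(rho = acos(max(-1, min(1, vec[3]))), eps = atan2(vec[2], vec[1]))
}

#' Intersect a sight ray with the flat ground plane
#'
#' The ground is the plane `Z = ground_z` in the north-east-down frame;
#' with the UAV near `Z = 0`, `ground_z` is its altitude above ground. The
#' ray descends only when `rho < pi/2`; otherwise an invalid point is
#' returned (no exception).
#'
#' @param pose UAV pose (fields `X`, `Y`, `Z` used).
#' @param vec unit direction in the geographic frame.
#' @param ground_z down-coordinate of the ground plane in metres.
#' @return List `(X, Y, valid)`.
#' @export
ray_ground_intersect <- function(pose, vec, ground_z) {
  dz <- ground_z - pose$Z
  if (dz <= 0) stop("UAV must be above the ground plane")
  if (vec[3] <= 1e-12)
    return(list(X = NA_real_, Y = NA_real_, valid = FALSE))
  t <- dz / vec[3]
  list(X = pose$X + t * vec[1], Y = pose$Y + t * vec[2], valid = TRUE)
}

#' Project a ground point into the image (simulator-side inverse)
#'
#' @param p ground point `(X, Y)` (metres, geographic frame).
#' @param pose UAV pose.
#' @param intrinsics camera intrinsics.
#' @param ground_z down-coordinate of the ground plane.
#' @return List `(x, y, visible)` — pixel coordinates, `visible = FALSE`
#'   when the point lies behind the camera plane.
#' @export
project_ground_point <- function(p, pose, intrinsics, ground_z) {
  R <- camera_rotation(pose)
  vL <- c(p[1] - pose$X, p[2] - pose$Y, ground_z - pose$Z)
  vC <- as.vector(crossprod(R, vL))
  if (vC[3] <= 1e-9) return(list(x = NA_real_, y = NA_real_, visible = FALSE))
  list(x = intrinsics$u0 + intrinsics$f * vC[1] / vC[3],
       y = intrinsics$v0 + intrinsics$f * vC[2] / vC[3],
       visible = TRUE)
}

#' Geolocate one pixel through a pose
#'
#' Convenience composition pixel -> camera LOS -> geographic LOS -> ground
#' intersection.
#'
#' @inheritParams pixel_to_los_camera
#' @inheritParams ray_ground_intersect
#' @return List `(X, Y, valid)`.
#' @export
pixel_to_ground <- function(px, pose, intrinsics, ground_z) {
  vC <- pixel_to_los_camera(px, intrinsics)
  vL <- camera_to_geographic(vC, pose)
  ray_ground_intersect(pose, vL, ground_z)
}

#' Geolocate tracker output and fuse per-identity with the IMM-PF
#'
#' For every identity in the tracker output, box centres are geolocated
#' frame by frame (pixel -> line of sight -> flat-ground intersection using
#' the pose of that frame); the resulting ground observations feed one
#' IMM-PF instance per identity, which also coasts through frames where the
#' identity is missing or its ray does not meet the ground. With
#' `filter = FALSE` the raw per-frame intersections are returned instead.
#'
#' @param tracks id-bearing `frame_table` (tracker output or ground truth).
#' @param poses a `uav_poses` table covering every frame with a detection.
#' @param intrinsics camera intrinsics.
#' @param config a `herd_config` (filter section, frame rate, altitude).
#' @param filter fuse with the IMM-PF (`TRUE`) or report raw intersections.
#' @param ground_z down-coordinate of the ground plane; defaults to the
#'   configured altitude.
#' @return Data frame `frame, id, X, Y, Vx, Vy, valid`.
#' @export
localize_tracks <- function(tracks, poses, intrinsics,
                            config = default_config(), filter = TRUE,
                            ground_z = config$scenario$altitude) {
  tracks <- as_frame_table(tracks)
  if (anyNA(tracks$id)) stop("localize_tracks needs id-bearing tracks")
  dt <- 1 / config$scenario$frame_rate
  pose_idx <- match(tracks$frame, poses$frame)
  if (anyNA(pose_idx))
    stop("missing pose for frame ",
         tracks$frame[which(is.na(pose_idx))[1]])
  # raw per-frame ground intersections
  n <- nrow(tracks)
  rawX <- rawY <- rep(NA_real_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    pose <- poses[pose_idx[i], ]
    g <- pixel_to_ground(c(tracks$cx[i], tracks$cy[i]), pose, intrinsics,
                         ground_z)
    rawX[i] <- g$X; rawY[i] <- g$Y; valid[i] <- g$valid
  }
  if (!filter) {
    return(data.frame(frame = tracks$frame, id = tracks$id,
                      X = rawX, Y = rawY, Vx = NA_real_, Vy = NA_real_,
                      valid = valid))
  }
  base_seed <- if (!is.null(config$filter$seed)) config$filter$seed else 1L
  out <- list()
  for (tid in sort(unique(tracks$id))) {
    sel <- which(tracks$id == tid & valid)
    if (!length(sel)) next
    f0 <- min(tracks$frame[sel]); f1 <- max(tracks$frame[sel])
    frames <- seq(f0, f1)
    z <- matrix(NA_real_, length(frames), 2)
    z[match(tracks$frame[sel], frames), ] <- cbind(rawX[sel], rawY[sel])
    seed <- (as.integer(base_seed) + 7919L * (tid %% 262139L)) %% 2147483647L
    fit <- imm_filter(z, config$filter, dt, seed = seed)
    e <- fit$estimates
    out[[length(out) + 1L]] <-
      data.frame(frame = frames, id = tid, X = e$X, Y = e$Y,
                 Vx = e$Vx, Vy = e$Vy, valid = e$observed)
  }
  if (!length(out))
    return(data.frame(frame = integer(), id = integer(), X = numeric(),
                      Y = numeric(), Vx = numeric(), Vy = numeric(),
                      valid = logical()))
  res <- do.call(rbind, out)
  res[order(res$frame, res$id), , drop = FALSE]
}
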