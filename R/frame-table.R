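#' Per-frame detection tables
#'
#' A `frame_table` is the package's in-memory form of a MOTChallenge-style
#' detection or annotation file: one row per observed bounding box, with
#' columns `frame` (1-based integer), `id` (integer identity, `NA` for raw
#' detections), `cx`, `cy` (box centre, pixels), `w`, `h` (box size, pixels)
#' and `score` (confidence in \[0, 1\]). Rows are kept sorted by
#' `(frame, id)`; within one frame no identity may appear twice.
#'
#' On disk boxes are stored MOTChallenge-style as `(left, top, width,
#' height)`; in memory they are centre + size. Image coordinates have their
#' origin at the top-left corner, x rightward, y downward, and boxes are
#' half-open `[left, left+w) x [top, top+h)`.
#'
#' @param frame,id,cx,cy,w,h,score vectors of equal length (recycled where
#'   sensible); `id` may contain `NA`.
#' @return A `data.frame` of class `frame_table`.
#' @examples
#' ft <- frame_table(frame = 1, id = 5, cx = 25, cy = 40, w = 30, h = 40,
#'                   score = 0.9)
#' frame_range(ft)
#' @export
frame_table <- function(frame = integer(), id = NA_integer_, cx = numeric(),
                        cy = numeric(), w = numeric(), h = numeric(),
                        score = 1) {
  n <- max(length(frame), length(cx))
  if (n == 0L) {
    df <- data.frame(frame = integer(), id = integer(), cx = numeric(),
                     cy = numeric(), w = numeric(), h = numeric(),
                     score = numeric())
    class(df) <- c("frame_table", "data.frame")
    return(df)
  }
  df <- data.frame(frame = as.integer(rep_len(frame, n)),
                   id = as.integer(rep_len(id, n)),
                   cx = as.numeric(rep_len(cx, n)),
                   cy = as.numeric(rep_len(cy, n)),
                   w = as.numeric(rep_len(w, n)),
                   h = as.numeric(rep_len(h, n)),
                   score = as.numeric(rep_len(score, n)))
  as_frame_table(df)
}

#' Coerce a data frame to a validated `frame_table`
#'
#' @param df a data frame with columns `frame`, `id`, `cx`, `cy`, `w`, `h`,
#'   `score`.
#' @return The sorted, validated `frame_table`.
#' @export
as_frame_table <- function(df) {
  need <- c("frame", "id", "cx", "cy", "w", "h", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("frame_table is missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  df$frame <- as.integer(df$frame)
  df$id <- as.integer(df$id)
  validate_frame_table(df)
  ord <- order(df$frame, df$id, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("frame_table", "data.frame")
  df
}

validate_frame_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$frame) || any(df$frame < 1L))
    stop("frame indices must be integers >= 1")
  if (any(!is.finite(df$w)) || any(!is.finite(df$h)) ||
      any(df$w <= 0) || any(df$h <= 0))
    stop("box sizes must be positive and finite")
  if (any(df$score < 0 | df$score > 1, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  with_id <- !is.na(df$id)
  if (any(with_id)) {
    key <- paste(df$frame[with_id], df$id[with_id])
    if (anyDuplicated(key))
      stop("duplicate id within a frame: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  invisible(df)
}

#' First and last frame of a table
#' @param ft a `frame_table`.
#' @return Integer vector `c(first, last)`, or `c(NA, NA)` when empty.
#' @export
frame_range <- function(ft) {
  if (nrow(ft) == 0L) return(c(NA_integer_, NA_integer_))
  range(ft$frame)
}

#' @export
print.frame_table <- function(x, ...) {
  fr <- frame_range(x)
  cat(sprintf("<frame_table> %d boxes, frames %s-%s, %d identities\n",
              nrow(x), fr[1], fr[2], length(unique(x$id[!is.na(x$id)]))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Read a MOTChallenge-format detection/annotation file
#'
#' Each line must have at least 7 comma-separated fields:
#' `frame, id, bb_left, bb_top, bb_width, bb_height, conf`; any further
#' fields are ignored. `id = -1` denotes an identity-free raw detection and
#' maps to `NA`. Boxes are converted from `(left, top, w, h)` to
#' centre + size.
#'
#' @param path path to the text file (or a connection readable by
#'   [readLines()]).
#' @return A `frame_table`.
#' @seealso [write_mot()]
#' @export
read_mot <- function(path) {
  if (is.character(path) && !file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(frame_table())
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 7L))
    stop("malformed MOT line ", which(nf < 7L)[1], ": expected >= 7 fields, got ",
         nf[which(nf < 7L)[1]])
  m <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[1:7])),
                numeric(7)))
  bad <- which(apply(m, 1, anyNA))
  if (length(bad))
    stop("malformed MOT line ", bad[1], ": non-numeric field")
  if (any(m[, 5] <= 0 | m[, 6] <= 0))
    stop("non-positive box size on line ", which(m[, 5] <= 0 | m[, 6] <= 0)[1])
  id <- as.integer(m[, 2])
  id[id < 0L] <- NA_integer_
  frame_table(frame = as.integer(m[, 1]), id = id,
              cx = m[, 3] + m[, 5] / 2, cy = m[, 4] + m[, 6] / 2,
              w = m[, 5], h = m[, 6], score = m[, 7])
}

#' Write a `frame_table` in MOTChallenge result format
#'
#' One line per record, fields `frame,id,left,top,w,h,score,-1,-1,-1`,
#' ordered by `(frame, id)`. Every record must carry an identity (tracker
#' output or ground truth); use `require_id = FALSE` to write raw detections
#' with `id = -1`.
#'
#' @param ft a `frame_table`.
#' @param path output file path.
#' @param require_id error on records without an identity (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_mot <- function(ft, path, require_id = TRUE) {
  ft <- as_frame_table(ft)
  if (require_id && anyNA(ft$id))
    stop("record without id; tracker output and ground truth must be id-bearing")
  id <- ifelse(is.na(ft$id), -1L, ft$id)
  lines <- sprintf("%d,%d,%s,%s,%s,%s,%s,-1,-1,-1",
                   ft$frame, id,
                   fmt_num(ft$cx - ft$w / 2), fmt_num(ft$cy - ft$h / 2),
                   fmt_num(ft$w), fmt_num(ft$h), fmt_num(ft$score))
  writeLines(lines, path)
  invisible(path)
}

# compact, round-trip-stable numeric formatting
fmt_num <- function(x) {
  out <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  sub("\\.?0+$", "", out)
}

#' Read / write UAV pose sequences
#'
#' Poses are stored as CSV with header
#' `frame,X,Y,Z,roll,pitch,yaw,pan,tilt`: position in the local geographic
#' (north-east-down) frame in metres, attitude angles and gimbal pan/tilt in
#' radians. With the package's conventions the ground plane sits at a fixed
#' down-coordinate (see [ray_ground_intersect()]).
#'
#' @param path CSV file path.
#' @return `read_poses()`: a data frame of class `uav_poses`.
#' @export
read_poses <- function(path) {
  df <- utils::read.csv(path)
  as_uav_poses(df)
}

#' @rdname read_poses
#' @param poses a `uav_poses` data frame.
#' @export
write_poses <- function(poses, path) {
  utils::write.csv(as.data.frame(poses), path, row.names = FALSE)
  invisible(path)
}

as_uav_poses <- function(df) {
  need <- c("frame", "X", "Y", "Z", "roll", "pitch", "yaw", "pan", "tilt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pose table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  ang <- as.matrix(df[c("roll", "pitch", "yaw", "pan", "tilt")])
  if (any(!is.finite(ang))) stop("non-finite pose angle")
  if (any(df$yaw <= -pi | df$yaw > pi))
    stop("yaw must lie in (-pi, pi]")
  df$frame <- as.integer(df$frame)
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("uav_poses", "data.frame")
  df
}

#' Pinhole camera intrinsics
#'
#' @param f focal length in pixels (> 0).
#' @param width,height image size in pixels.
#' @param u0,v0 principal point in pixels; defaults to the image centre.
#' @return A list of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(f, width, height, u0 = width / 2,
                              v0 = height / 2) {
  stopifnot(is.numeric(f), length(f) == 1L)
  if (f <= 0) stop("focal length must be positive")
  if (u0 <= 0 || u0 >= width || v0 <= 0 || v0 >= height)
    stop("principal point must lie strictly inside the image")
  structure(list(f = f, width = width, height = height, u0 = u0, v0 = v0),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> f = %g px, image %g x %g, pp (%g, %g)\n",
              x$f, x$width, x$height, x$u0, x$v0))
  invisible(x)
}
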