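# Skeleton-based subject localization: frame rotation, distances, motion.

#' Rotate a joint from the tilted camera frame to the reference frame
#'
#' The camera is mounted on a pole, tilted about its x axis by angle A
#' (degrees), so detected joint coordinates live in a rotated frame. The
#' reference frame is recovered by left-multiplying with the rotation
#' matrix about x:
#' \deqn{p_0 = [x,\; \cos A\, y - \sin A\, z,\; \sin A\, y + \cos A\, z]}
#'
#' @param p_rot numeric length-3 point in the rotated frame, or an n x 3
#'   matrix of points (one per row).
#' @param angle_deg camera tilt angle A in degrees (default -30).
#' @return point(s) in the reference frame, same shape as the input.
#' @seealso [rotate_to_rotated()] for the inverse transform.
#' @export
#' @examples
#' rotate_to_reference(c(0, 0, 1), -30)  # c(0, 0.5, 0.8660254)
rotate_to_reference <- function(p_rot, angle_deg = -30) {
  a <- deg2rad(angle_deg)
  R <- matrix(c(1, 0, 0,
                0, cos(a), -sin(a),
                0, sin(a), cos(a)), nrow = 3, byrow = TRUE)
  if (is.matrix(p_rot)) {
    stopifnot(ncol(p_rot) == 3L)
    return(p_rot %*% t(R))
  }
  stop_if_not_point3(p_rot, "p_rot")
  as.numeric(R %*% p_rot)
}

#' Rotate a joint from the reference frame into the tilted camera frame
#'
#' Inverse of [rotate_to_reference()]: applies the transpose of the
#' rotation matrix. Used by the simulator to emit skeleton samples the way
#' a tilted camera would report them.
#'
#' @param p_ref numeric length-3 point (or n x 3 matrix) in the reference
#'   frame.
#' @inheritParams rotate_to_reference
#' @return point(s) in the rotated frame.
#' @export
rotate_to_rotated <- function(p_ref, angle_deg = -30) {
  rotate_to_reference(p_ref, -angle_deg)
}

#' Euclidean distance between a joint and a radar
#'
#' @param joint,radar_pos numeric length-3 points in the reference frame.
#' @return distance in meters.
#' @export
distance_to_radar <- function(joint, radar_pos) {
  stop_if_not_point3(joint, "joint")
  stop_if_not_point3(radar_pos, "radar_pos")
  sqrt(sum((joint - radar_pos)^2))
}

#' Midpoint of the two shoulders
#'
#' The shoulder midpoint serves as the reference point for the movement
#' trajectory in motion detection.
#'
#' @param l,r numeric length-3 left and right shoulder positions.
#' @return numeric length-3 midpoint.
#' @export
shoulder_midpoint <- function(l, r) {
  stop_if_not_point3(l, "l")
  stop_if_not_point3(r, "r")
  (l + r) / 2
}

#' Classify a subject as moving or stationary
#'
#' Average speed of the shoulder midpoint over the window: total path
#' length divided by elapsed time. The subject is moving when it exceeds
#' the threshold (default 0.7 m/s, about slow walking). Path length rather
#' than net displacement is used so back-and-forth movement is not
#' mistaken for stillness.
#'
#' @param midpoints n x 3 matrix of shoulder midpoints (reference frame),
#'   one row per skeleton sample, in time order.
#' @param times numeric vector of the n sample times, seconds.
#' @param threshold_mps speed threshold in m/s (default 0.7).
#' @return `"moving"` or `"stationary"`.
#' @export
detect_motion <- function(midpoints, times, threshold_mps = 0.7) {
  if (is.numeric(midpoints) && !is.matrix(midpoints)) {
    midpoints <- matrix(midpoints, ncol = 3, byrow = TRUE)
  }
  stopifnot(is.matrix(midpoints), ncol(midpoints) == 3L,
            length(times) == nrow(midpoints), threshold_mps > 0)
  n <- nrow(midpoints)
  if (n < 2L) {
    message("detect_motion: single skeleton sample; reporting stationary")
    return("stationary")
  }
  elapsed <- times[n] - times[1L]
  if (elapsed <= 0) stop("times must be strictly increasing", call. = FALSE)
  steps <- sqrt(rowSums((midpoints[-1L, , drop = FALSE] -
                           midpoints[-n, , drop = FALSE])^2))
  speed <- sum(steps) / elapsed
  if (speed > threshold_mps) "moving" else "stationary"
}

#' Read / write skeleton joint streams as CSV
#'
#' Long format with a header: `time_s, subject_id, joint, x, y, z`, where
#' `joint` is one of `chest`, `l_shoulder`, `r_shoulder` and coordinates
#' are in the rotated camera frame (as the camera reports them).
#'
#' @param path file path.
#' @return `read_skeleton_csv` returns the data.frame;
#'   `write_skeleton_csv` returns `path` invisibly.
#' @export
read_skeleton_csv <- function(path) {
  if (!file.exists(path)) stop("skeleton file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "subject_id", "joint", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("skeleton CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_skeleton_csv
#' @param skeletons skeleton data.frame.
#' @export
write_skeleton_csv <- function(skeletons, path) {
  utils::write.csv(skeletons, path, row.names = FALSE)
  invisible(path)
}

# Joints of one subject inside a time window, rotated to the reference
# frame and arranged per-frame. Frames missing any of the three joints are
# dropped; if more than half the frames are dropped the subject is treated
# as moving by the caller (fail-safe), signalled via `degraded`.
subject_window_joints <- function(skeletons, subject_id, t_start, t_end,
                                  angle_deg) {
  sk <- skeletons[skeletons$subject_id == subject_id &
                    skeletons$time_s >= t_start & skeletons$time_s < t_end, ]
  if (nrow(sk) == 0L) {
    return(list(n = 0L, degraded = TRUE))
  }
  frames <- split(sk, sk$time_s)
  total <- length(frames)
  rows <- lapply(frames, function(fr) {
    need <- c("chest", "l_shoulder", "r_shoulder")
    if (!all(need %in% fr$joint)) return(NULL)
    g <- function(j) {
      p <- as.numeric(fr[fr$joint == j, c("x", "y", "z")][1L, ])
      rotate_to_reference(p, angle_deg)
    }
    list(t = fr$time_s[1L], chest = g("chest"),
         l_shoulder = g("l_shoulder"), r_shoulder = g("r_shoulder"))
  })
  rows <- Filter(Negate(is.null), rows)
  kept <- length(rows)
  if (kept == 0L) return(list(n = 0L, degraded = TRUE))
  times <- vapply(rows, `[[`, numeric(1), "t")
  o <- order(times)
  rows <- rows[o]
  pick <- function(j) t(vapply(rows, `[[`, numeric(3), j))
  list(n = kept, degraded = kept < total / 2,
       times = times[o],
       chest = pick("chest"),
       l_shoulder = pick("l_shoulder"),
       r_shoulder = pick("r_shoulder"))
}
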