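#' Radar pose within a scene
#'
#' One IR-UWB radar: an integer id, a 3D position in the reference camera
#' frame (x right, y down, z forward, origin at the camera focal point) and
#' a boresight direction in the horizontal xz plane.
#'
#' @param id integer radar identifier (used in file names and assignments).
#' @param position numeric length-3 position (m), reference frame.
#' @param boresight numeric length-2 direction `(x, z)` the radar faces;
#'   normalized to unit length.
#' @return list of class `radar_pose`.
#' @export
radar_pose <- function(id, position, boresight) {
  stopifnot(length(id) == 1L)
  stop_if_not_point3(position, "position")
  stopifnot(is.numeric(boresight), length(boresight) == 2L)
  nb <- vec_norm(boresight)
  if (nb == 0) stop("boresight must be a non-zero direction", call. = FALSE)
  structure(list(id = as.integer(id), position = as.numeric(position),
                 boresight = as.numeric(boresight) / nb),
            class = "radar_pose")
}

#' Scene configuration
#'
#' Single source of truth for the monitoring geometry and thresholds: the
#' camera tilt angle, the radar poses, the radar beam and range limits, the
#' range resolution, and the decision thresholds used by motion detection
#' and radar selection.
#'
#' Defaults reflect a typical deployment: a ceiling-pole camera tilted
#' down by 30 degrees, X4-class radars with a 60 degree beam (30 degree
#' half-angle), 5.22 cm range resolution recording out to 9.4 m (180
#' complete range bins), a reliable detection range of 5 m, a slow-walking
#' motion threshold of 0.7 m/s, and a minimum inter-subject separation of
#' 6 range bins (about 30 cm) on a shared radar.
#'
#' @param radars list of [radar_pose()] entries.
#' @param rotation_angle_deg camera tilt about its x axis, degrees
#'   (default -30).
#' @param beam_half_angle_deg half of the radar beam solid angle, degrees.
#' @param max_detect_range_m maximum distance (m) at which a subject counts
#'   as covered by a radar.
#' @param range_res_m range resolution, meters per range bin.
#' @param max_range_m recorded distance span of the radar matrix, m.
#' @param motion_threshold_mps average-speed threshold separating moving
#'   from stationary subjects, m/s.
#' @param min_bin_separation minimum difference, in range bins, between two
#'   subjects' chest distances to a shared radar.
#' @param slow_rate_hz common slow-time sampling rate, Hz.
#' @return list of class `scene_config`; `n_bins` is derived as the number
#'   of complete range bins within `max_range_m`.
#' @export
#' @examples
#' sc <- scene_config(radars = list(radar_pose(1, c(0, 0.5, 0), c(0, 1))))
#' sc$n_bins  # 180
scene_config <- function(radars,
                         rotation_angle_deg = -30,
                         beam_half_angle_deg = 30,
                         max_detect_range_m = 5,
                         range_res_m = 0.0522,
                         max_range_m = 9.4,
                         motion_threshold_mps = 0.7,
                         min_bin_separation = 6L,
                         slow_rate_hz = 17) {
  stopifnot(is.list(radars), length(radars) >= 1L,
            all(vapply(radars, inherits, logical(1), "radar_pose")))
  ids <- vapply(radars, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("radar ids must be unique", call. = FALSE)
  for (nm in c("beam_half_angle_deg", "max_detect_range_m", "range_res_m",
               "max_range_m", "motion_threshold_mps", "slow_rate_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a positive number", nm), call. = FALSE)
    }
  }
  stopifnot(min_bin_separation >= 0)
  structure(list(
    rotation_angle_deg = rotation_angle_deg,
    radars = radars[order(ids)],
    beam_half_angle_deg = beam_half_angle_deg,
    max_detect_range_m = max_detect_range_m,
    range_res_m = range_res_m,
    max_range_m = max_range_m,
    n_bins = as.integer(floor(max_range_m / range_res_m)),
    motion_threshold_mps = motion_threshold_mps,
    min_bin_separation = as.integer(min_bin_separation),
    slow_rate_hz = slow_rate_hz
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("scene_config: %d radar(s), camera tilt %g deg\n",
              length(x$radars), x$rotation_angle_deg))
  for (r in x$radars) {
    cat(sprintf("  radar %d at (%.2f, %.2f, %.2f), boresight (%.2f, %.2f)\n",
                r$id, r$position[1], r$position[2], r$position[3],
                r$boresight[1], r$boresight[2]))
  }
  cat(sprintf("  %d bins x %.4f m, beam half-angle %g deg, range < %g m\n",
              x$n_bins, x$range_res_m, x$beam_half_angle_deg,
              x$max_detect_range_m))
  invisible(x)
}

#' Read / write a scene configuration as YAML
#'
#' The YAML layout mirrors the `scene_config` fields; radars are a list of
#' maps with keys `id`, `position` (3 numbers) and `boresight` (2 numbers).
#'
#' @param path file path.
#' @return `read_scene_config` returns a `scene_config`;
#'   `write_scene_config` returns `path` invisibly.
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("scene config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$radars)) stop("scene config has no 'radars' entry", call. = FALSE)
  radars <- lapply(y$radars, function(r) {
    radar_pose(r$id, as.numeric(r$position), as.numeric(r$boresight))
  })
  args <- y[setdiff(names(y), "radars")]
  args <- args[names(args) %in% names(formals(scene_config))]
  do.call(scene_config, c(list(radars = radars), args))
}

#' @rdname read_scene_config
#' @param scene a `scene_config`.
#' @export
write_scene_config <- function(scene, path) {
  stopifnot(inherits(scene, "scene_config"))
  y <- list(
    rotation_angle_deg = scene$rotation_angle_deg,
    beam_half_angle_deg = scene$beam_half_angle_deg,
    max_detect_range_m = scene$max_detect_range_m,
    range_res_m = scene$range_res_m,
    max_range_m = scene$max_range_m,
    motion_threshold_mps = scene$motion_threshold_mps,
    min_bin_separation = scene$min_bin_separation,
    slow_rate_hz = scene$slow_rate_hz,
    radars = lapply(scene$radars, function(r) {
      list(id = r$id, position = r$position, boresight = r$boresight)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
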