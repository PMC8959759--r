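# Multi-radar selection from beam coverage, body orientation and
# inter-subject range-bin separation.

#' Is a subject inside a radar's detection area?
#'
#' True when the chest lies within the radar's beam (angle between the
#' boresight and the radar-to-chest direction, measured in the horizontal
#' xz plane, at most the beam half-angle) and closer than the reliable
#' detection range. For a radar with boresight along +z this reduces to
#' the familiar test 60 deg < arctan(|dz|/|dx|) <= 90 deg together with
#' dist < 5 m; the vector form supports radars mounted on any wall.
#'
#' @param chest numeric length-3 chest position, reference frame.
#' @param radar a [radar_pose()].
#' @param beam_half_angle_deg beam half-angle, degrees (default 30).
#' @param max_detect_range_m detection range limit, meters (default 5).
#' @return logical.
#' @export
in_detection_area <- function(chest, radar, beam_half_angle_deg = 30,
                              max_detect_range_m = 5) {
  stop_if_not_point3(chest, "chest")
  stopifnot(inherits(radar, "radar_pose"))
  if (distance_to_radar(chest, radar$position) >= max_detect_range_m) {
    return(FALSE)
  }
  d <- c(chest[1] - radar$position[1], chest[3] - radar$position[3])
  nd <- vec_norm(d)
  if (nd == 0) return(TRUE)  # on top of the radar: trivially in range
  cosang <- clamp(sum(d * radar$boresight) / nd, -1, 1)
  rad2deg(acos(cosang)) <= beam_half_angle_deg
}

#' Body orientation angle toward a radar
#'
#' The angle at the shoulder midpoint M between the right shoulder R and
#' the radar D, all projected onto the horizontal xz plane, computed by the
#' law of cosines:
#' \deqn{\angle RMD = \arccos\frac{RM^2 + MD^2 - RD^2}{2\, RM\, MD}}
#' A subject squarely facing the radar gives 90 degrees; a radar collinear
#' with the shoulder axis gives 0 (beyond the right shoulder) or 180
#' (beyond the left shoulder).
#'
#' @param l_shoulder,r_shoulder numeric length-3 shoulder positions,
#'   reference frame.
#' @param radar_pos numeric length-3 radar position.
#' @return angle in degrees, in \[0, 180\].
#' @export
#' @examples
#' orientation_angle(c(-0.2, 0, 2), c(0.2, 0, 2), c(0, 0, 0))  # 90
orientation_angle <- function(l_shoulder, r_shoulder, radar_pos) {
  stop_if_not_point3(l_shoulder, "l_shoulder")
  stop_if_not_point3(r_shoulder, "r_shoulder")
  stop_if_not_point3(radar_pos, "radar_pos")
  R <- r_shoulder[c(1, 3)]
  M <- (l_shoulder + r_shoulder)[c(1, 3)] / 2
  D <- radar_pos[c(1, 3)]
  RM <- vec_norm(R - M)
  MD <- vec_norm(D - M)
  RD <- vec_norm(D - R)
  if (RM == 0 || MD == 0) {
    stop("degenerate geometry: coincident shoulders or radar at the midpoint",
         call. = FALSE)
  }
  rad2deg(acos(clamp((RM^2 + MD^2 - RD^2) / (2 * RM * MD), -1, 1)))
}

#' Assign one radar to each stationary subject
#'
#' Each subject gets, among the radars covering it
#' ([in_detection_area()]), the one whose orientation angle is closest to
#' 90 degrees — with one physical restriction. When another subject
#' inside the same radar's detection area sits within
#' `min_bin_separation` range bins (about 30 cm at 5.22 cm per bin) of
#' the same chest distance, both chests echo into the same narrow band of
#' range bins and neither respiratory signal can be isolated there: that
#' radar is unusable for the subject, whoever it is oriented toward. The
#' subject then takes the covering radar with the next-best orientation
#' angle (`fallback_separation`); a subject left with no usable covering
#' radar is reported `uncovered` rather than handed a corrupted signal.
#' Ties on |angle - 90| break toward the lower radar id; because
#' usability depends only on the geometry, the outcome is independent of
#' the order subjects are listed.
#'
#' @param subjects list; each element a list with `subject_id`, `chest`,
#'   `l_shoulder`, `r_shoulder` (reference frame).
#' @param scene a [scene_config()].
#' @return data.frame with one row per subject: `subject_id`, `radar_id`
#'   (NA when uncovered), `orientation_angle_deg` (angle to the selected
#'   radar, NA when uncovered), `chest_distance_m`, and `reason`, one of
#'   `best_angle`, `fallback_separation`, `uncovered`.
#' @export
assign_radars <- function(subjects, scene) {
  stopifnot(inherits(scene, "scene_config"), is.list(subjects))
  ids <- vapply(subjects, function(s) as.numeric(s$subject_id), numeric(1))
  o <- order(ids)
  subjects <- subjects[o]
  ids <- ids[o]
  sep_m <- scene$min_bin_separation * scene$range_res_m
  n <- length(subjects)

  covered <- vapply(scene$radars, function(r) {
    vapply(subjects, function(s) {
      in_detection_area(s$chest, r, scene$beam_half_angle_deg,
                        scene$max_detect_range_m)
    }, logical(1))
  }, logical(n))
  covered <- matrix(covered, nrow = n)   # subjects x radars
  dist <- vapply(scene$radars, function(r) {
    vapply(subjects, function(s) {
      distance_to_radar(s$chest, r$position)
    }, numeric(1))
  }, numeric(n))
  dist <- matrix(dist, nrow = n)

  # radar r is corrupted for subject i if another covered subject sits
  # within sep_m of the same range
  usable <- covered
  for (r in seq_along(scene$radars)) {
    for (i in seq_len(n)) {
      if (!covered[i, r]) next
      others <- setdiff(which(covered[, r]), i)
      if (any(abs(dist[others, r] - dist[i, r]) < sep_m)) {
        usable[i, r] <- FALSE
      }
    }
  }

  res <- lapply(seq_len(n), function(i) {
    s <- subjects[[i]]
    cand_r <- which(covered[i, ])
    if (length(cand_r) > 0L) {
      ang <- vapply(cand_r, function(r) {
        orientation_angle(s$l_shoulder, s$r_shoulder,
                          scene$radars[[r]]$position)
      }, numeric(1))
      ord <- order(abs(ang - 90),
                   vapply(scene$radars[cand_r], `[[`, integer(1), "id"))
      cand_r <- cand_r[ord]
      ang <- ang[ord]
      ok <- usable[i, cand_r]
      if (any(ok)) {
        k <- which(ok)[1L]
        r <- cand_r[k]
        return(data.frame(
          subject_id = ids[i], radar_id = scene$radars[[r]]$id,
          orientation_angle_deg = ang[k], chest_distance_m = dist[i, r],
          reason = if (k == 1L) "best_angle" else "fallback_separation"))
      }
    }
    data.frame(subject_id = ids[i], radar_id = NA_integer_,
               orientation_angle_deg = NA_real_,
               chest_distance_m = min(dist[i, ]), reason = "uncovered")
  })
  do.call(rbind, res)
}
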