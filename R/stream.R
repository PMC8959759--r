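# Sliding-window orchestration of the full per-window pipeline.

#' Sliding analysis windows over a recording
#'
#' Overlapping fixed-length windows: with window length T and overlap m,
#' the n-th window covers \[(n-1)(T-m), nT-(n-1)m\] — a stride of T-m
#' seconds (3 s at the defaults T = 15, m = 12). Windows never extend past
#' the end of the stream; a stream shorter than one window yields no
#' windows.
#'
#' @param stream_length_s recording length, seconds.
#' @param window_s window length T, seconds (default 15).
#' @param overlap_s overlap m, seconds (default 12); `window_s` must
#'   exceed `overlap_s`.
#' @return data.frame with columns `window_index`, `start_s`, `end_s`.
#' @export
#' @examples
#' sliding_windows(18)  # [0,15], [3,18]
sliding_windows <- function(stream_length_s, window_s = 15,
                            overlap_s = 12) {
  if (!(window_s > overlap_s && overlap_s >= 0)) {
    stop("need window_s > overlap_s >= 0", call. = FALSE)
  }
  if (stream_length_s < window_s) {
    return(data.frame(window_index = integer(0), start_s = numeric(0),
                      end_s = numeric(0)))
  }
  stride <- window_s - overlap_s
  n <- floor((stream_length_s - window_s) / stride) + 1L
  starts <- (seq_len(n) - 1L) * stride
  data.frame(window_index = seq_len(n), start_s = starts,
             end_s = starts + window_s)
}

# one result row skeleton
window_result_row <- function(window_index, t_start, t_end, subject_id,
                              status, radar_id = NA_integer_,
                              orientation_angle_deg = NA_real_,
                              chest_distance_m = NA_real_,
                              range_bin = NA_integer_,
                              reason = NA_character_,
                              classifier_label = NA_character_,
                              label = NA_character_,
                              label_source = NA_character_,
                              sqi_passed = NA,
                              rr_bpm = NA_real_) {
  data.frame(window_index = window_index, t_start = t_start, t_end = t_end,
             subject_id = subject_id, status = status, radar_id = radar_id,
             orientation_angle_deg = orientation_angle_deg,
             chest_distance_m = chest_distance_m, range_bin = range_bin,
             reason = reason, classifier_label = classifier_label,
             label = label, label_source = label_source,
             sqi_passed = sqi_passed, rr_bpm = rr_bpm)
}

#' Run the full pipeline on one analysis window
#'
#' Per subject seen in the window's skeleton slice: motion detection on
#' the shoulder midpoints (moving subjects yield a status-only result);
#' for the stationary subjects jointly, radar assignment from beam
#' coverage, orientation and range-bin separation; then, per assigned
#' subject, per-window preprocessing (background subtraction + SVD
#' clutter removal), respiratory-signal extraction at the chest range,
#' pattern classification plus morphological discrimination; and, only
#' when the final label is eupnea and the signal quality index passed,
#' respiration-band filtering and rate estimation. The skeleton runs at a
#' much lower rate than the radar, so the subject's position within the
#' window is the mean of its skeleton samples — safe for a stationary
#' subject.
#'
#' @param scene a [scene_config()].
#' @param radar_matrices named list of full-recording [radar_matrix()]
#'   objects; names (or `radar_id` fields) identify the radar. Radars
#'   listed in the scene but missing here make their assigned subjects
#'   `uncovered`.
#' @param skeletons skeleton data.frame (rotated frame) covering the
#'   window.
#' @param window numeric `c(start_s, end_s)` of the window.
#' @param classifier an `rp_classifier` from [train_classifier()].
#' @param window_index index recorded in the result rows (default 1).
#' @return data.frame of one result row per subject (see
#'   `window_result_row` fields). The invariant that `rr_bpm` is present
#'   only for stationary, eupnea-labeled, quality-passing subjects is
#'   asserted on every call.
#' @export
process_window <- function(scene, radar_matrices, skeletons, window,
                           classifier, window_index = 1L) {
  stopifnot(inherits(scene, "scene_config"), length(window) == 2L,
            inherits(classifier, "rp_classifier"))
  t0 <- window[1L]
  t1 <- window[2L]
  mat_ids <- vapply(radar_matrices, `[[`, numeric(1), "radar_id")
  subject_ids <- sort(unique(skeletons$subject_id))

  rows <- list()
  stationary <- list()
  for (sid in subject_ids) {
    jw <- subject_window_joints(skeletons, sid, t0, t1,
                                scene$rotation_angle_deg)
    if (jw$n == 0L || jw$degraded) {
      # unusable skeleton: fail safe, treat as moving
      rows[[length(rows) + 1L]] <-
        window_result_row(window_index, t0, t1, sid, "moving")
      next
    }
    mids <- (jw$l_shoulder + jw$r_shoulder) / 2
    status <- detect_motion(mids, jw$times, scene$motion_threshold_mps)
    if (status == "moving") {
      rows[[length(rows) + 1L]] <-
        window_result_row(window_index, t0, t1, sid, "moving")
    } else {
      stationary[[length(stationary) + 1L]] <- list(
        subject_id = sid,
        chest = colMeans(jw$chest),
        l_shoulder = colMeans(jw$l_shoulder),
        r_shoulder = colMeans(jw$r_shoulder))
    }
  }

  if (length(stationary) > 0L) {
    assign <- assign_radars(stationary, scene)
    for (i in seq_len(nrow(assign))) {
      a <- assign[i, ]
      if (is.na(a$radar_id) || !(a$radar_id %in% mat_ids)) {
        reason <- if (is.na(a$radar_id)) a$reason else "radar_data_missing"
        if (reason == "radar_data_missing") {
          message(sprintf("no radar matrix for radar %d; subject %s uncovered",
                          a$radar_id, a$subject_id))
        }
        rows[[length(rows) + 1L]] <-
          window_result_row(window_index, t0, t1, a$subject_id,
                            "stationary",
                            orientation_angle_deg = a$orientation_angle_deg,
                            chest_distance_m = a$chest_distance_m,
                            reason = reason)
        next
      }
      m <- radar_matrices[[match(a$radar_id, mat_ids)]]
      mw <- preprocess_radar_matrix(slice_radar_matrix(m, t0, t1))
      chunk <- extract_respiratory_signal(mw, a$chest_distance_m,
                                          subject_id = a$subject_id)
      clab <- classify(classifier, chunk)
      final <- discriminate(clab, chunk)
      q <- evaluate_signal_quality(chunk)
      rr <- NA_real_
      if (final$label == "eupnea" && q$passed) {
        est <- estimate_rr(bandpass_filter(chunk))
        rr <- est$rr_bpm
      }
      rows[[length(rows) + 1L]] <-
        window_result_row(window_index, t0, t1, a$subject_id, "stationary",
                          radar_id = a$radar_id,
                          orientation_angle_deg = a$orientation_angle_deg,
                          chest_distance_m = a$chest_distance_m,
                          range_bin = chunk$range_bin, reason = a$reason,
                          classifier_label = clab$label,
                          label = final$label,
                          label_source = final$source,
                          sqi_passed = q$passed, rr_bpm = rr)
    }
  }

  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  # workflow gate: RR only for stationary, quality-passing eupnea
  bad <- !is.na(out$rr_bpm) &
    (out$status != "stationary" | is.na(out$label) |
       out$label != "eupnea" | !out$sqi_passed %in% TRUE)
  stopifnot(!any(bad))
  out
}

#' Run the pipeline over a recorded (or simulated) session
#'
#' Reads the scene configuration, the per-radar matrix CSVs
#' (`radar_<id>.csv`) and the skeleton stream (`skeleton.csv`) from
#' `input_dir`, slides 15-s windows at a 3-s stride across the recording,
#' processes each window with [process_window()] and writes one flat
#' result row per (window, subject) to `output_path` as CSV. Malformed
#' rows in the skeleton stream are skipped with a warning. Deterministic
#' given identical inputs.
#'
#' @param config_path scene-config YAML path.
#' @param input_dir directory holding `radar_<id>.csv` files and
#'   `skeleton.csv`.
#' @param output_path CSV path for the window-result log.
#' @param classifier an `rp_classifier`, or a path to one saved with
#'   [saveRDS()].
#' @param window_s,overlap_s window geometry overrides (defaults 15, 12).
#' @return the window-result data.frame, invisibly (also written to
#'   `output_path`).
#' @export
run_pipeline <- function(config_path, input_dir, output_path, classifier,
                         window_s = 15, overlap_s = 12) {
  scene <- read_scene_config(config_path)
  if (is.character(classifier)) classifier <- readRDS(classifier)
  stopifnot(inherits(classifier, "rp_classifier"))
  if (!dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir, call. = FALSE)
  }
  sk_path <- file.path(input_dir, "skeleton.csv")
  if (!file.exists(sk_path)) {
    stop("no skeleton.csv in ", input_dir, call. = FALSE)
  }
  skeletons <- read_skeleton_csv(sk_path)
  bad <- !stats::complete.cases(skeletons[c("time_s", "x", "y", "z")])
  if (any(bad)) {
    warning(sprintf("skipping %d malformed skeleton row(s)", sum(bad)))
    skeletons <- skeletons[!bad, , drop = FALSE]
  }
  mats <- list()
  for (r in scene$radars) {
    p <- file.path(input_dir, sprintf("radar_%d.csv", r$id))
    if (file.exists(p)) {
      mats[[length(mats) + 1L]] <-
        read_radar_csv(p, r$id, scene$slow_rate_hz, scene$range_res_m)
    } else {
      message("no data file for radar ", r$id)
    }
  }
  if (length(mats) == 0L) {
    stop("no radar_<id>.csv files found in ", input_dir, call. = FALSE)
  }
  length_s <- min(vapply(mats, function(m) {
    nrow(m$values) / m$slow_rate_hz
  }, numeric(1)))
  wins <- sliding_windows(length_s, window_s, overlap_s)
  res <- lapply(seq_len(nrow(wins)), function(i) {
    process_window(scene, mats, skeletons,
                   c(wins$start_s[i], wins$end_s[i]), classifier,
                   window_index = wins$window_index[i])
  })
  log <- do.call(rbind, res)
  utils::write.csv(log, output_path, row.names = FALSE)
  invisible(log)
}
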