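# Scene and waveform simulator: respiratory waveforms, radar matrices,
# skeleton streams and labeled training databases.

PATTERNS <- c("eupnea", "csr", "kussmaul", "apnea", "nonstationary")

#' Parameters of a simulated respiratory pattern
#'
#' Describes one breathing pattern for the waveform generator. The five
#' supported patterns are eupnea (normal breathing), Cheyne-Stokes
#' respiration (csr: crescendo-decrescendo cycles with apnea gaps),
#' Kussmaul respiration (deep and rapid), apnea (breathing cessation) and
#' nonstationary (movement artifacts uncorrelated with breathing).
#'
#' @param pattern one of `"eupnea"`, `"csr"`, `"kussmaul"`, `"apnea"`,
#'   `"nonstationary"`.
#' @param rate_bpm breathing rate, breaths per minute; must lie in
#'   \[6, 40\] for the breathing patterns (ignored for nonstationary).
#' @param amplitude peak chest displacement, arbitrary amplitude units.
#' @param csr_period_s full Cheyne-Stokes cycle length in seconds
#'   (crescendo + decrescendo + apnea gap); must exceed 15 s, the analysis
#'   chunk length, as CSR cycles do physiologically.
#' @param apnea_fraction fraction of the pattern spent in apnea, in
#'   \[0, 1\]: for `apnea`, the gated flat part of the window; for `csr`,
#'   the silent tail of each cycle.
#' @param noise_sd standard deviation of additive white sensor noise, in
#'   amplitude units.
#' @param seed integer seed making the waveform reproducible; NULL draws
#'   from the ambient RNG stream.
#' @return list of class `pattern_params`.
#' @export
pattern_params <- function(pattern, rate_bpm = 15, amplitude = 1,
                           csr_period_s = 40, apnea_fraction = 0.3,
                           noise_sd = 0.02, seed = NULL) {
  if (!is.character(pattern) || length(pattern) != 1L ||
      !(pattern %in% PATTERNS)) {
    stop("unknown pattern: must be one of ",
         paste(PATTERNS, collapse = ", "), call. = FALSE)
  }
  if (pattern != "nonstationary" && (rate_bpm < 6 || rate_bpm > 40)) {
    stop("rate_bpm must lie in [6, 40] for breathing patterns",
         call. = FALSE)
  }
  if (pattern == "csr" && csr_period_s <= 15) {
    stop("csr_period_s must exceed 15 s (one analysis chunk)",
         call. = FALSE)
  }
  if (apnea_fraction < 0 || apnea_fraction > 1) {
    stop("apnea_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(amplitude >= 0, noise_sd >= 0)
  structure(list(pattern = pattern, rate_bpm = rate_bpm,
                 amplitude = amplitude, csr_period_s = csr_period_s,
                 apnea_fraction = apnea_fraction, noise_sd = noise_sd,
                 seed = seed),
            class = "pattern_params")
}

# smooth unit-variance-ish noise for cycle-to-cycle physiological jitter
smooth_noise <- function(n, rate_hz, tau_s = 3) {
  a <- exp(-1 / (tau_s * rate_hz))
  z <- as.numeric(stats::filter(stats::rnorm(n), a, method = "recursive"))
  z * sqrt(1 - a^2)
}

#' Generate one respiratory displacement waveform
#'
#' Produces a chest-displacement time series with the morphology of the
#' requested breathing pattern:
#' * `eupnea` — a quasi-sinusoid at `rate_bpm` with mild cycle-to-cycle
#'   frequency and amplitude jitter;
#' * `kussmaul` — the same generative form; deep rapid breathing is
#'   expressed through the larger `amplitude` and higher `rate_bpm` a
#'   Kussmaul episode carries;
#' * `apnea` — breathing with a contiguous flat (cessation) segment
#'   covering `apnea_fraction` of the window; with `amplitude = 0` the
#'   output is pure sensor noise;
#' * `csr` — a carrier at `rate_bpm` under a raised-cosine
#'   crescendo-decrescendo envelope of period `csr_period_s`, silent for
#'   the final `apnea_fraction` of each cycle;
#' * `nonstationary` — a random walk with occasional step artifacts,
#'   uncorrelated with breathing.
#' White noise of sd `noise_sd` is added to every pattern.
#'
#' @param params a [pattern_params()].
#' @param duration_s signal duration, seconds (> 0).
#' @param rate_hz sampling rate, Hz (default 17).
#' @return numeric vector of `round(duration_s * rate_hz)` displacement
#'   samples.
#' @export
#' @examples
#' w <- gen_respiratory_waveform(pattern_params("eupnea", 15, seed = 1), 15)
#' length(w)  # 255
gen_respiratory_waveform <- function(params, duration_s, rate_hz = 17) {
  stopifnot(inherits(params, "pattern_params"),
            duration_s > 0, rate_hz > 0)
  n <- round(duration_s * rate_hz)
  with_seed(params$seed, {
    t <- (seq_len(n) - 1L) / rate_hz
    f0 <- params$rate_bpm / 60
    # chunks are cut from an ongoing breath stream: arbitrary initial phase
    phase0 <- stats::runif(1, 0, 2 * pi)
    base_breathing <- function() {
      finst <- f0 * (1 + 0.03 * smooth_noise(n, rate_hz))
      phase <- phase0 + 2 * pi * cumsum(finst) / rate_hz
      env <- 1 + 0.05 * smooth_noise(n, rate_hz)
      params$amplitude * env * sin(phase)
    }
    x <- switch(params$pattern,
      eupnea = base_breathing(),
      kussmaul = base_breathing(),
      apnea = {
        b <- base_breathing()
        gap <- round(params$apnea_fraction * n)
        if (gap > 0) {
          start <- if (gap >= n) 1L else sample.int(n - gap + 1L, 1L)
          b[start:(start + gap - 1L)] <- 0
        }
        b
      },
      csr = {
        period <- params$csr_period_s
        breath_len <- period * (1 - params$apnea_fraction)
        u <- t %% period
        env <- ifelse(u < breath_len,
                      0.5 * (1 - cos(2 * pi * u / breath_len)), 0)
        params$amplitude * env * sin(phase0 + 2 * pi * f0 * t)
      },
      nonstationary = {
        drift <- cumsum(stats::rnorm(n, 0, params$amplitude * 0.15))
        n_steps <- stats::rpois(1, 2)
        if (n_steps > 0) {
          at <- sample.int(n, n_steps)
          for (i in seq_len(n_steps)) {
            drift[at[i]:n] <- drift[at[i]:n] +
              stats::runif(1, 1, 3) * params$amplitude * sample(c(-1, 1), 1)
          }
        }
        drift
      },
      stop("unknown pattern: ", params$pattern, call. = FALSE))
    x + stats::rnorm(n, 0, params$noise_sd)
  })
}

#' Script of one simulated subject
#'
#' Ground-truth trajectory, facing direction and breathing schedule for a
#' subject in a simulated scene. Chest positions are given as waypoints in
#' the reference camera frame and interpolated linearly in time; shoulders
#' are placed symmetrically about the chest, perpendicular to the facing
#' direction in the horizontal plane, so their separation is constant.
#'
#' Facing convention: `facing_deg = 0` faces +z (away from the camera),
#' 180 faces -z; the facing unit vector in the xz plane is
#' `(sin a, cos a)`.
#'
#' @param subject_id integer identifier.
#' @param waypoints data.frame with columns `time_s, x, y, z` (chest,
#'   reference frame, meters).
#' @param facing_deg facing angle in degrees; a scalar or one value per
#'   waypoint (interpolated).
#' @param pattern_schedule list of `list(start_s, end_s, params)` entries
#'   with non-overlapping intervals; outside all intervals the chest is
#'   still.
#' @param shoulder_halfwidth_m half the shoulder separation, meters
#'   (default 0.2).
#' @return list of class `subject_script`.
#' @export
subject_script <- function(subject_id, waypoints, facing_deg,
                           pattern_schedule, shoulder_halfwidth_m = 0.2) {
  stopifnot(is.data.frame(waypoints),
            all(c("time_s", "x", "y", "z") %in% names(waypoints)),
            nrow(waypoints) >= 1L, shoulder_halfwidth_m > 0)
  if (length(facing_deg) == 1L) {
    facing_deg <- rep(facing_deg, nrow(waypoints))
  }
  stopifnot(length(facing_deg) == nrow(waypoints))
  ivals <- lapply(pattern_schedule, function(sch) {
    stopifnot(!is.null(sch$start_s), !is.null(sch$end_s),
              inherits(sch$params, "pattern_params"),
              sch$start_s < sch$end_s)
    c(sch$start_s, sch$end_s)
  })
  if (length(ivals) > 1L) {
    o <- order(vapply(ivals, `[`, numeric(1), 1L))
    ivals <- ivals[o]
    for (i in seq_len(length(ivals) - 1L)) {
      if (ivals[[i]][2] > ivals[[i + 1L]][1]) {
        stop("pattern_schedule intervals must not overlap", call. = FALSE)
      }
    }
  }
  structure(list(subject_id = as.integer(subject_id),
                 waypoints = waypoints[order(waypoints$time_s), ],
                 facing_deg = facing_deg,
                 pattern_schedule = pattern_schedule,
                 shoulder_halfwidth_m = shoulder_halfwidth_m),
            class = "subject_script")
}

# ground-truth pose (reference frame) of a scripted subject at times `t`
script_pose <- function(script, t) {
  wp <- script$waypoints
  itp <- function(v) {
    if (nrow(wp) == 1L) rep(v[1L], length(t))
    else stats::approx(wp$time_s, v, xout = t, rule = 2)$y
  }
  chest <- cbind(itp(wp$x), itp(wp$y), itp(wp$z))
  a <- deg2rad(itp(script$facing_deg))
  facing <- cbind(sin(a), cos(a))             # xz plane
  right <- cbind(-facing[, 2L], facing[, 1L]) # subject's right, xz plane
  w <- script$shoulder_halfwidth_m
  r_sh <- chest + cbind(right[, 1L] * w, 0, right[, 2L] * w)
  l_sh <- chest - cbind(right[, 1L] * w, 0, right[, 2L] * w)
  list(chest = chest, l_shoulder = l_sh, r_shoulder = r_sh,
       facing = facing)
}

# breathing displacement of a scripted subject over [0, duration_s)
script_waveform <- function(script, duration_s, rate_hz = 17) {
  n <- round(duration_s * rate_hz)
  w <- numeric(n)
  for (sch in script$pattern_schedule) {
    i0 <- round(sch$start_s * rate_hz) + 1L
    i1 <- min(round(sch$end_s * rate_hz), n)
    if (i0 > n || i1 < i0) next
    seg <- gen_respiratory_waveform(sch$params,
                                    duration_s = (i1 - i0 + 1L) / rate_hz,
                                    rate_hz = rate_hz)
    w[i0:i1] <- seg[seq_len(i1 - i0 + 1L)]
  }
  w
}

#' Simulate the radar matrix of one radar observing scripted subjects
#'
#' Additive echo model: each range bin carries a static clutter amplitude
#' (constant over slow time) plus white noise; a subject at chest distance
#' `d` modulates the bin `round(d / range_res_m)` — with triangular
#' spillover to the two adjacent bins — by its breathing waveform, scaled
#' by an orientation gain. The gain is the cosine of the angle between the
#' subject's facing direction and the subject-to-radar direction, clipped
#' at zero, and is zero when the chest is outside the radar's detection
#' area, so a subject facing away from or outside the beam contributes no
#' breathing signal. Subjects beyond the recorded range contribute
#' nothing (a message is emitted).
#'
#' The `clutter_sd` knob scales both disturbance components: static
#' per-bin clutter is drawn with sd `10 * clutter_sd` and the white
#' slow-time noise has sd `clutter_sd`.
#'
#' @param scene a [scene_config()].
#' @param radar_id id of the radar to simulate (must be in the scene).
#' @param scripts list of [subject_script()]s.
#' @param duration_s recording length, seconds.
#' @param clutter_sd clutter/noise scale, amplitude units (default 0.05).
#' @param seed integer seed for clutter and noise (default 1).
#' @return a [radar_matrix()] of shape
#'   `(round(duration_s * slow_rate_hz), n_bins)`.
#' @export
gen_radar_matrix <- function(scene, radar_id, scripts, duration_s,
                             clutter_sd = 0.05, seed = 1) {
  stopifnot(inherits(scene, "scene_config"), duration_s > 0)
  ids <- vapply(scene$radars, `[[`, integer(1), "id")
  if (!(radar_id %in% ids)) stop("radar_id not in scene", call. = FALSE)
  radar <- scene$radars[[match(radar_id, ids)]]
  rate <- scene$slow_rate_hz
  n <- round(duration_s * rate)
  nb <- scene$n_bins
  with_seed(seed, {
    clutter <- stats::rnorm(nb, 0, 10 * clutter_sd)
    vals <- matrix(rep(clutter, each = n), nrow = n) +
      matrix(stats::rnorm(n * nb, 0, clutter_sd), nrow = n)
    t <- (seq_len(n) - 1L) / rate
    for (script in scripts) {
      pose <- script_pose(script, t)
      dists <- sqrt(rowSums(sweep(pose$chest, 2L, radar$position)^2))
      if (all(round(dists / scene$range_res_m) >= nb)) {
        message(sprintf("subject %d outside radar %d max range; skipped",
                        script$subject_id, radar_id))
        next
      }
      wav <- script_waveform(script, duration_s, rate)
      # orientation gain per sample
      to_radar <- cbind(radar$position[1] - pose$chest[, 1L],
                        radar$position[3] - pose$chest[, 3L])
      nr <- sqrt(rowSums(to_radar^2))
      nr[nr == 0] <- 1
      gain <- rowSums(pose$facing * to_radar / nr)
      gain <- pmax(gain, 0)
      covered <- vapply(seq_len(n), function(i) {
        in_detection_area(pose$chest[i, ], radar, scene$beam_half_angle_deg,
                          scene$max_detect_range_m)
      }, logical(1))
      gain[!covered] <- 0
      bins <- round(dists / scene$range_res_m)
      contrib <- gain * wav
      for (k in c(-1L, 0L, 1L)) {
        wk <- if (k == 0L) 1 else 0.5   # triangular spread over +-1 bin
        b <- bins + k
        ok <- b >= 0L & b < nb
        if (any(ok)) {
          idx <- cbind(which(ok), b[ok] + 1L)
          vals[idx] <- vals[idx] + wk * contrib[ok]
        }
      }
    }
    radar_matrix(vals, radar_id, rate, scene$range_res_m)
  })
}

#' Simulate a skeleton joint stream
#'
#' Emits chest and shoulder positions of every scripted subject at `fps`
#' frames per second, in the rotated camera frame (the inverse of the
#' tilt-correction rotation applied to the ground-truth reference-frame
#' positions) with isotropic Gaussian position noise — i.e. the way a
#' tilted depth camera would report them.
#'
#' @param scene a [scene_config()].
#' @param scripts list of [subject_script()]s.
#' @param duration_s stream length, seconds.
#' @param fps skeleton frame rate, Hz (default 1, the tracker's rate).
#' @param noise_sd_m per-coordinate position noise sd, meters (default 0).
#' @param seed integer seed (default 1).
#' @return data.frame with columns `time_s, subject_id, joint, x, y, z`
#'   (rotated frame).
#' @export
gen_skeleton_stream <- function(scene, scripts, duration_s, fps = 1,
                                noise_sd_m = 0, seed = 1) {
  stopifnot(inherits(scene, "scene_config"), fps > 0, duration_s > 0)
  t <- seq(0, duration_s - 1 / fps, by = 1 / fps)
  with_seed(seed, {
    out <- lapply(scripts, function(script) {
      pose <- script_pose(script, t)
      one_joint <- function(name, pts) {
        rot <- rotate_to_rotated(pts, scene$rotation_angle_deg)
        rot <- rot + matrix(stats::rnorm(length(rot), 0, noise_sd_m),
                            ncol = 3L)
        data.frame(time_s = t, subject_id = script$subject_id,
                   joint = name, x = rot[, 1L], y = rot[, 2L],
                   z = rot[, 3L])
      }
      rbind(one_joint("chest", pose$chest),
            one_joint("l_shoulder", pose$l_shoulder),
            one_joint("r_shoulder", pose$r_shoulder))
    })
    df <- do.call(rbind, out)
    df[order(df$time_s, df$subject_id, df$joint), , drop = FALSE]
  })
}

# per-class parameter draws for the training database; ranges are the
# study conditions the classifier is trained under
draw_pattern_params <- function(label, seed) {
  ru <- function(a, b) stats::runif(1, a, b)
  switch(label,
    eupnea = pattern_params("eupnea", rate_bpm = ru(14, 22),
                            amplitude = ru(0.8, 1.2),
                            noise_sd = ru(0.02, 0.06), seed = seed),
    kussmaul = pattern_params("kussmaul", rate_bpm = ru(25, 38),
                              amplitude = ru(2, 3),
                              noise_sd = ru(0.02, 0.06), seed = seed),
    apnea = pattern_params("apnea", rate_bpm = ru(14, 22),
                           amplitude = ru(0.5, 1),
                           apnea_fraction = ru(0.7, 1),
                           noise_sd = ru(0.02, 0.06), seed = seed),
    csr = pattern_params("csr", rate_bpm = ru(16, 24),
                         amplitude = ru(0.8, 1.5),
                         csr_period_s = ru(30, 60),
                         apnea_fraction = ru(0.2, 0.4),
                         noise_sd = ru(0.02, 0.06), seed = seed),
    nonstationary = pattern_params("nonstationary",
                                   amplitude = ru(0.8, 1.5),
                                   noise_sd = ru(0.02, 0.06), seed = seed))
}

#' Generate a labeled respiratory-chunk training database
#'
#' Balanced database of 15-s breath chunks over the five respiration
#' patterns, with per-chunk physiological parameters drawn from
#' class-typical ranges (eupnea 14-22 bpm, the monitored-adult resting
#' range the 15-s quality criteria are designed around; Kussmaul 25-38
#' bpm at 2-3x amplitude; apnea mostly-flat windows; CSR cycles of
#' 30-60 s with a 16-24 bpm hyperpnea-phase carrier, cut from
#' the crescendo/decrescendo portion of the cycle, where the pattern's
#' amplitude-modulated morphology lives; nonstationary random-walk
#' artifacts). The default of 50 chunks per class yields a 250-chunk
#' database.
#'
#' @param n_per_class chunks per pattern class (default 50).
#' @param chunk_s chunk duration, seconds (default 15).
#' @param rate_hz sampling rate, Hz (default 17).
#' @param seed integer seed (default 1).
#' @return list of class `resp_database` with fields `chunks` (list of
#'   [resp_chunk()]s), `labels` (factor) and `rate_hz`.
#' @export
gen_training_database <- function(n_per_class = 50, chunk_s = 15,
                                  rate_hz = 17, seed = 1) {
  stopifnot(n_per_class >= 1)
  n_chunk <- round(chunk_s * rate_hz)
  with_seed(seed, {
    chunks <- list()
    labels <- character(0)
    for (label in PATTERNS) {
      for (i in seq_len(n_per_class)) {
        p <- draw_pattern_params(label, seed = NULL)
        x <- if (label == "csr") {
          # cut the chunk from the breathing (modulated) part of the cycle
          breath_len <- p$csr_period_s * (1 - p$apnea_fraction)
          full <- gen_respiratory_waveform(p, p$csr_period_s, rate_hz)
          start_s <- stats::runif(1, 0, max(breath_len - chunk_s, 0))
          i0 <- round(start_s * rate_hz) + 1L
          full[i0:(i0 + n_chunk - 1L)]
        } else {
          gen_respiratory_waveform(p, chunk_s, rate_hz)
        }
        chunks[[length(chunks) + 1L]] <-
          resp_chunk(x[seq_len(n_chunk)], rate_hz = rate_hz)
        labels <- c(labels, label)
      }
    }
    structure(list(chunks = chunks,
                   labels = factor(labels, levels = PATTERNS),
                   rate_hz = rate_hz),
              class = "resp_database")
  })
}

#' @export
print.resp_database <- function(x, ...) {
  cat(sprintf("resp_database: %d chunks at %g Hz\n",
              length(x$chunks), x$rate_hz))
  print(table(x$labels))
  invisible(x)
}

#' Save / load a chunk database as CSV
#'
#' Wide plain-text format: one row per chunk, sample columns `s1..sN`
#' followed by a `label` column.
#'
#' @param db a `resp_database`.
#' @param path file path.
#' @return `save_database` returns `path` invisibly; `load_database`
#'   returns a `resp_database`.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "resp_database"))
  m <- do.call(rbind, lapply(db$chunks, `[[`, "samples"))
  df <- as.data.frame(m)
  names(df) <- paste0("s", seq_len(ncol(df)))
  df$label <- as.character(db$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_database
#' @param rate_hz sampling rate of the stored chunks, Hz.
#' @export
load_database <- function(path, rate_hz = 17) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lab <- df$label
  m <- as.matrix(df[setdiff(names(df), "label")])
  chunks <- lapply(seq_len(nrow(m)), function(i) {
    resp_chunk(as.numeric(m[i, ]), rate_hz = rate_hz)
  })
  structure(list(chunks = chunks, labels = factor(lab, levels = PATTERNS),
                 rate_hz = rate_hz),
            class = "resp_database")
}

#' Simulate a full scene: radar CSVs plus skeleton CSV
#'
#' Convenience wrapper writing one radar matrix CSV per radar in the
#' scene (`radar_<id>.csv`) and a skeleton stream (`skeleton.csv`) to an
#' output directory, as a recording session would.
#'
#' @param scene a [scene_config()].
#' @param scripts list of [subject_script()]s.
#' @param duration_s recording length, seconds.
#' @param out_dir output directory (created if missing).
#' @param clutter_sd clutter/noise scale (default 0.05).
#' @param skeleton_noise_sd_m skeleton position noise, meters.
#' @param fps skeleton frame rate, Hz.
#' @param seed integer seed.
#' @return invisibly, the vector of written file paths.
#' @export
simulate_scene <- function(scene, scripts, duration_s, out_dir,
                           clutter_sd = 0.05, skeleton_noise_sd_m = 0.005,
                           fps = 1, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in scene$radars) {
    m <- gen_radar_matrix(scene, r$id, scripts, duration_s, clutter_sd,
                          seed = seed + r$id)
    p <- file.path(out_dir, sprintf("radar_%d.csv", r$id))
    write_radar_csv(m, p)
    paths <- c(paths, p)
  }
  sk <- gen_skeleton_stream(scene, scripts, duration_s, fps,
                            skeleton_noise_sd_m, seed = seed + 1000L)
  p <- file.path(out_dir, "skeleton.csv")
  write_skeleton_csv(sk, p)
  invisible(c(paths, p))
}
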