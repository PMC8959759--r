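# Shared scene fixtures and builders, constructed in code.

# single front-wall radar on the z axis
one_radar_scene <- function() {
  scene_config(radars = list(radar_pose(1, c(0, 0.5, 0), c(0, 1))))
}

# lab-style layout: front wall + two side walls
three_radar_scene <- function() {
  scene_config(radars = list(
    radar_pose(1, c(0, 0.5, 0), c(0, 1)),
    radar_pose(2, c(-2.5, 0.5, 2.5), c(1, 0)),
    radar_pose(3, c(2.5, 0.5, 2.5), c(-1, 0))))
}

# stationary subject script breathing one pattern for the whole duration
still_subject <- function(subject_id, chest, facing_deg, params,
                          duration_s) {
  subject_script(
    subject_id,
    data.frame(time_s = 0, x = chest[1], y = chest[2], z = chest[3]),
    facing_deg = facing_deg,
    pattern_schedule = list(list(start_s = 0, end_s = duration_s,
                                 params = params)))
}

# subject walking in a straight line at constant speed along +x
walking_subject <- function(subject_id, start, speed_mps, duration_s) {
  subject_script(
    subject_id,
    data.frame(time_s = c(0, duration_s),
               x = c(start[1], start[1] + speed_mps * duration_s),
               y = start[2], z = start[3]),
    facing_deg = 90,
    pattern_schedule = list())
}

# geometric subject (no script): chest + shoulders from a facing angle
posed_subject <- function(subject_id, chest, facing_deg,
                          halfwidth = 0.2) {
  a <- facing_deg * pi / 180
  f <- c(sin(a), cos(a))
  right <- c(-f[2], f[1])
  list(subject_id = subject_id, chest = chest,
       r_shoulder = chest + halfwidth * c(right[1], 0, right[2]),
       l_shoulder = chest - halfwidth * c(right[1], 0, right[2]))
}

# simulate one stationary eupnea subject and return the extracted chunk
# (preprocessed, 15 s) together with the ground truth
simulated_chunk <- function(rate_bpm = 15, clutter_sd = 0.05, seed = 1,
                            chest_z = 2.09, duration_s = 15) {
  sc <- one_radar_scene()
  scr <- still_subject(1, c(0, 0.5, chest_z), 180,
                       pattern_params("eupnea", rate_bpm, seed = seed),
                       duration_s)
  m <- gen_radar_matrix(sc, 1, list(scr), duration_s,
                        clutter_sd = clutter_sd, seed = seed + 50000L)
  chunk <- extract_respiratory_signal(preprocess_radar_matrix(m), chest_z)
  list(chunk = chunk, true_bin = round(chest_z / sc$range_res_m),
       scene = sc, matrix = m)
}
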