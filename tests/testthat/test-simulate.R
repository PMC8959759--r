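test_that("waveform generator output has the requested length and is seeded", {
  p <- pattern_params("eupnea", 15, seed = 1)
  w1 <- gen_respiratory_waveform(p, 15, 17)
  w2 <- gen_respiratory_waveform(p, 15, 17)
  expect_length(w1, 255L)
  expect_identical(w1, w2)
  w3 <- gen_respiratory_waveform(pattern_params("eupnea", 15, seed = 2), 15)
  expect_false(identical(w1, w3))
})

test_that("pattern parameter validation enforces physiological ranges", {
  expect_error(pattern_params("sighing"), "unknown pattern")
  expect_error(pattern_params("eupnea", rate_bpm = 50), "\\[6, 40\\]")
  expect_error(pattern_params("csr", csr_period_s = 10), "15 s")
  expect_error(pattern_params("apnea", apnea_fraction = 1.5), "\\[0, 1\\]")
  expect_silent(pattern_params("nonstationary", rate_bpm = 0))
})

test_that("eupnea at 15 bpm yields 3-4 prominent peaks in 15 s", {
  for (s in 1:10) {
    w <- gen_respiratory_waveform(pattern_params("eupnea", 15, seed = s), 15)
    ext <- detect_breath_extrema(w, 17)
    expect_gte(nrow(ext$peaks), 3L)
    expect_lte(nrow(ext$peaks), 4L)
  }
})

test_that("eupnea dominant frequency equals the scripted rate within one DFT bin", {
  for (rate in c(12, 15, 20)) {
    w <- gen_respiratory_waveform(
      pattern_params("eupnea", rate, noise_sd = 0, seed = rate), 15, 17)
    sp <- Mod(stats::fft(w - mean(w)))[2:(length(w) %/% 2)]
    f <- (seq_along(sp)) * 17 / length(w)
    expect_equal(f[which.max(sp)], rate / 60, tolerance = 17 / 255)
  }
})

test_that("zero-amplitude apnea is pure noise with no valid breaths", {
  w <- gen_respiratory_waveform(
    pattern_params("apnea", amplitude = 0, noise_sd = 0.05, seed = 3), 15)
  q <- evaluate_signal_quality(resp_chunk(w))
  expect_false(q$passed)
})

test_that("CSR chunks cut from a single phase have monotone peak amplitudes", {
  p <- pattern_params("csr", rate_bpm = 20, csr_period_s = 40,
                      apnea_fraction = 0.25, noise_sd = 0, seed = 4)
  w <- gen_respiratory_waveform(p, 40, 17)
  breath_len <- 40 * 0.75             # 30 s of modulated breathing
  crescendo <- w[1:(15 * 17)]         # first half of the envelope rises
  decrescendo <- w[(15 * 17 + 1):(30 * 17)]
  expect_true(evaluate_csr_pattern(resp_chunk(crescendo)))
  expect_true(evaluate_csr_pattern(resp_chunk(decrescendo)))
})

test_that("radar matrix places maximum variance at the chest's range bin", {
  sim <- simulated_chunk(rate_bpm = 15, seed = 5)
  m <- preprocess_radar_matrix(sim$matrix)
  vars <- apply(m$values[, 38:44], 2, stats::var)  # bins 37..43
  expect_equal(37L + which.max(vars) - 1L, 40L)    # round(2.09/0.0522)
})

test_that("clutter-only scene is rank one up to noise", {
  sc <- one_radar_scene()
  m <- gen_radar_matrix(sc, 1, list(), 15, clutter_sd = 0.5, seed = 6)
  out <- svd_clutter_removal(m, 1)
  # static clutter gone; the residual energy is the white noise floor
  expect_lt(norm(out$values, "F")^2 / norm(m$values, "F")^2, 0.05)
})

test_that("a subject facing away contributes no breathing power", {
  sc <- one_radar_scene()
  mk <- function(facing) {
    scr <- still_subject(1, c(0, 0.5, 2.09), facing,
                         pattern_params("eupnea", 15, seed = 7), 15)
    gen_radar_matrix(sc, 1, list(scr), 15, clutter_sd = 0.05, seed = 8)
  }
  band_power <- function(m) {
    x <- preprocess_radar_matrix(m)$values[, 41]
    y <- bandpass_filter(resp_chunk(x))
    sum(y$samples^2)
  }
  facing_power <- band_power(mk(180))  # toward the radar
  away_power <- band_power(mk(0))      # 180 deg away: gain clipped to 0
  expect_lt(away_power, facing_power / 100)
})

test_that("skeleton stream round-trips to ground truth with zero noise", {
  sc <- one_radar_scene()
  scr <- still_subject(1, c(0.3, 0.6, 2.5), 150,
                       pattern_params("eupnea", 15, seed = 9), 10)
  sk <- gen_skeleton_stream(sc, list(scr), 10, fps = 1, noise_sd_m = 0,
                            seed = 10)
  chest <- sk[sk$joint == "chest", ]
  for (i in seq_len(nrow(chest))) {
    p <- rotate_to_reference(as.numeric(chest[i, c("x", "y", "z")]),
                             sc$rotation_angle_deg)
    expect_equal(p, c(0.3, 0.6, 2.5), tolerance = 1e-9)
  }
  # shoulder separation constant
  ls <- sk[sk$joint == "l_shoulder", c("x", "y", "z")]
  rs <- sk[sk$joint == "r_shoulder", c("x", "y", "z")]
  sep <- as.numeric(sqrt(rowSums((ls - rs)^2)))
  expect_equal(sep, rep(0.4, length(sep)), tolerance = 1e-9)
})

test_that("scripted motion is classified against the 0.7 m/s threshold", {
  sc <- one_radar_scene()
  status_of <- function(script) {
    sk <- gen_skeleton_stream(sc, list(script), 15, fps = 1,
                              noise_sd_m = 0, seed = 11)
    jw <- respiradar:::subject_window_joints(sk, script$subject_id, 0, 15,
                                             sc$rotation_angle_deg)
    detect_motion((jw$l_shoulder + jw$r_shoulder) / 2, jw$times)
  }
  still <- still_subject(1, c(0, 0.5, 2), 180,
                         pattern_params("eupnea", 15, seed = 12), 15)
  expect_equal(status_of(still), "stationary")
  expect_equal(status_of(walking_subject(2, c(-2, 0.5, 2), 1.2, 15)),
               "moving")
})

test_that("training database is balanced, sized and deterministic", {
  db <- gen_training_database(n_per_class = 2, seed = 42)
  expect_length(db$chunks, 10L)
  expect_equal(as.numeric(table(db$labels)), rep(2, 5))
  expect_true(all(vapply(db$chunks, function(ch) length(ch$samples),
                         numeric(1)) == 255))
  db2 <- gen_training_database(n_per_class = 2, seed = 42)
  expect_identical(db$chunks, db2$chunks)
  tiny <- gen_training_database(n_per_class = 1, chunk_s = 15, rate_hz = 17,
                                seed = 1)
  expect_length(tiny$chunks, 5L)
  expect_length(tiny$chunks[[1]]$samples, 255L)
})

test_that("radar matrix generation is deterministic under a fixed seed", {
  sc <- one_radar_scene()
  scr <- still_subject(1, c(0, 0.5, 2), 180,
                       pattern_params("eupnea", 15, seed = 1), 15)
  m1 <- gen_radar_matrix(sc, 1, list(scr), 15, seed = 99)
  m2 <- gen_radar_matrix(sc, 1, list(scr), 15, seed = 99)
  expect_identical(m1$values, m2$values)
})

test_that("a subject beyond the recorded range contributes nothing", {
  sc <- one_radar_scene()
  scr <- still_subject(1, c(0, 0.5, 12), 180,
                       pattern_params("eupnea", 15, seed = 1), 15)
  expect_message(m <- gen_radar_matrix(sc, 1, list(scr), 15, seed = 13),
                 "outside")
  empty <- gen_radar_matrix(sc, 1, list(), 15, seed = 13)
  expect_identical(m$values, empty$values)
})

test_that("database CSV round-trips chunks and labels", {
  db <- gen_training_database(n_per_class = 1, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  save_database(db, path)
  back <- load_database(path)
  expect_equal(as.character(back$labels), as.character(db$labels))
  expect_equal(back$chunks[[3]]$samples, db$chunks[[3]]$samples,
               tolerance = 1e-12)
})
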