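test_that("instantaneous-frequency features recover a sinusoid's frequency", {
  x <- sin(2 * pi * 0.25 * (0:254) / 17)
  f <- extract_features(resp_chunk(x))
  expect_equal(unname(f["if_mean"]), 0.25, tolerance = 0.02)
  expect_lt(f["ste_variability"] / f["ste_max"], 0.02)
  expect_lt(f["peak_amp_variability"], 0.01)
  expect_length(f, 13L)
})

test_that("an all-zero chunk takes the degenerate feature path", {
  f <- extract_features(resp_chunk(rep(0, 255)))
  expect_equal(unname(f["n_peaks"]), 0)
  expect_true(all(f[c("peak_amp_variability", "peak_amp_mean",
                      "peak_amp_max", "if_variability", "if_mean",
                      "if_max", "if_min", "if_range")] == 0))
  expect_true(all(is.finite(f)))
})

test_that("short-term energy features tile the chunk into three 5-s segments", {
  # energy confined to the middle third
  x <- c(rep(0, 85), rep(2, 85), rep(0, 85))
  f <- extract_features(resp_chunk(x))
  expect_equal(unname(f["ste_max"]), 85 * 4)
  expect_equal(unname(f["ste_min"]), 0)
  expect_equal(unname(f["ste_range"]), 85 * 4)
})

test_that("SQI passes regular breathing and fails irregular or sparse chunks", {
  # peaks 56, 64, 72 samples apart at 16 Hz: intervals 3.5, 4, 4.5 s,
  # NSD = 0.125 (every quantity exactly representable)
  good <- make_bump_signal(c(20, 76, 140, 212))
  q <- evaluate_signal_quality(resp_chunk(good, rate_hz = 16))
  expect_true(q$passed)
  expect_equal(q$n_valid_breaths, 3L)
  expect_equal(q$interval_nsd, 0.125)
  # only 3 peaks -> 2 valid intervals -> fail, however regular
  sparse <- make_bump_signal(c(34, 119, 204))
  expect_false(evaluate_signal_quality(resp_chunk(sparse))$passed)
  # white noise fails
  set.seed(51)
  expect_false(evaluate_signal_quality(resp_chunk(stats::rnorm(255)))$passed)
})

test_that("SQI interval-regularity boundary: NSD of exactly 0.25 fails", {
  # intervals 48, 64, 80 samples at 16 Hz = 3, 4, 5 s: sd/mean = 1/4
  x <- make_bump_signal(c(20, 68, 132, 212))
  q <- evaluate_signal_quality(resp_chunk(x, rate_hz = 16))
  expect_equal(q$n_valid_breaths, 3L)
  expect_identical(q$interval_nsd, 0.25)
  expect_false(q$passed)
})

test_that("peaks with prominence exactly 0.15 are not relevant extrema", {
  # staircase with 3-sample plateaus so the median filter is the identity:
  # a main peak of height 1 and a secondary peak rising from the 0
  # baseline, whose prominence is its height exactly
  seg <- function(a, b, k) seq(a, b, length.out = k)
  build <- function(second_top) {
    c(rep(0, 3), seg(0, 1, 7), rep(1, 3), seg(1, 0, 7), rep(0, 3),
      seg(0, second_top, 4), rep(second_top, 3),
      seg(second_top, 0, 4), rep(0, 3))
  }
  at <- detect_breath_extrema(build(0.15), rate_hz = 17)
  expect_equal(nrow(at$peaks), 1L)          # 0.15 prominence excluded
  above <- detect_breath_extrema(build(0.20), rate_hz = 17)
  expect_equal(nrow(above$peaks), 2L)       # 0.20 prominence retained
})

test_that("SQI is invariant to positive affine amplitude transforms", {
  sim <- simulated_chunk(rate_bpm = 16, seed = 52)
  base <- evaluate_signal_quality(sim$chunk)
  for (ab in list(c(3, 0), c(0.01, -5), c(100, 42))) {
    tr <- sim$chunk
    tr$samples <- ab[1] * sim$chunk$samples + ab[2]
    q <- evaluate_signal_quality(tr)
    expect_equal(q$passed, base$passed)
    expect_equal(q$n_valid_breaths, base$n_valid_breaths)
    expect_equal(q$interval_nsd, base$interval_nsd)
  }
})

test_that("CSR morphology test requires strict crescendo then decrescendo", {
  fs <- 17
  idx <- round(c(1, 4, 7, 10, 13) * fs) + 1
  expect_true(evaluate_csr_pattern(
    resp_chunk(make_bump_signal(idx, c(0.2, 0.5, 1.0, 0.6, 0.3)))))
  # no strict rise/fall
  expect_false(evaluate_csr_pattern(
    resp_chunk(make_bump_signal(idx[1:3], c(1, 1, 1)))))
  # rises after the boundary at the first peak
  expect_false(evaluate_csr_pattern(
    resp_chunk(make_bump_signal(idx[1:3], c(1.0, 0.5, 0.8)))))
  # a single peak cannot be a cycle
  expect_false(evaluate_csr_pattern(
    resp_chunk(make_bump_signal(idx[1], 1))))
})

test_that("discriminator truth table matches the override rules", {
  fs <- 17
  idx4 <- round(c(1, 5, 9, 13) * fs) + 1
  csr_chunk <- resp_chunk(make_bump_signal(idx4, c(0.3, 0.6, 1.0, 0.7)))
  flat_csr <- resp_chunk(make_bump_signal(idx4, c(1, 0.5, 0.8, 0.6)))
  set.seed(53)
  noise <- resp_chunk(stats::rnorm(255))

  confirmed <- discriminate("csr", csr_chunk)
  expect_equal(confirmed$label, "csr")
  expect_equal(confirmed$source, "classifier")

  demoted <- discriminate("csr", flat_csr)
  expect_equal(demoted$label, "eupnea")
  expect_equal(demoted$source, "discriminator_override")

  lowq <- discriminate("eupnea", noise)
  expect_equal(lowq$label, "nonstationary")
  expect_equal(lowq$source, "discriminator_override")

  # apnea bypasses the quality gate
  apnea <- discriminate("apnea", resp_chunk(rep(0, 255)))
  expect_equal(apnea$label, "apnea")

  # quality-passing non-CSR labels are kept
  kept <- discriminate("eupnea", csr_chunk)
  expect_equal(kept$label, "eupnea")
  expect_equal(kept$source, "classifier")
})

test_that("discriminator is idempotent", {
  fs <- 17
  chunks <- list(
    resp_chunk(make_bump_signal(round(c(1, 5, 9, 13) * fs) + 1,
                                c(0.3, 0.6, 1.0, 0.7))),
    resp_chunk(rep(0, 255)),
    resp_chunk({set.seed(54); stats::rnorm(255)}))
  for (lab in c("eupnea", "csr", "apnea", "nonstationary")) {
    for (ch in chunks) {
      once <- discriminate(lab, ch)
      twice <- discriminate(once$label, ch)
      expect_equal(twice$label, once$label)
    }
  }
})

test_that("classifier training is seeded, schema-checked and rejects one class", {
  db <- gen_training_database(n_per_class = 10, seed = 55)
  m1 <- train_classifier(db, seed = 3)
  m2 <- train_classifier(db, seed = 3)
  test_db <- gen_training_database(n_per_class = 4, seed = 56)
  p1 <- vapply(test_db$chunks, function(ch) classify(m1, ch)$label,
               character(1))
  p2 <- vapply(test_db$chunks, function(ch) classify(m2, ch)$label,
               character(1))
  expect_identical(p1, p2)
  expect_error(classify(m1, c(a = 1, b = 2)), "schema")
  feats <- respiradar:::database_features(db)
  one_class <- rep(factor("eupnea", levels = levels(db$labels)), nrow(feats))
  expect_error(train_classifier(feats, one_class), "2 classes")
})

test_that("held-out chunks of distinctive patterns are classified correctly", {
  db <- gen_training_database(n_per_class = 25, seed = 57)
  model <- train_classifier(db, seed = 57)
  held <- gen_training_database(n_per_class = 10, seed = 58)
  for (lab in c("kussmaul", "apnea", "nonstationary")) {
    idx <- which(held$labels == lab)
    pred <- vapply(idx, function(i) classify(model, held$chunks[[i]])$label,
                   character(1))
    expect_gt(mean(pred == lab), 0.5)
  }
})
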