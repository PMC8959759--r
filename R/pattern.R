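# Respiration-pattern classification: statistical features, random-forest
# classifier, signal quality index and the morphological discriminator.

FEATURE_NAMES <- c("peak_amp_variability", "peak_amp_mean", "peak_amp_max",
                   "n_peaks",
                   "if_variability", "if_mean", "if_max", "if_min",
                   "if_range",
                   "ste_variability", "ste_max", "ste_min", "ste_range")

#' Breath peaks and troughs of a chunk
#'
#' The common breath detector: median filter (kernel 5) to improve SNR,
#' min-max normalization to \[0, 1\], then local extrema with topographic
#' prominence strictly greater than `prominence` (default 0.15). A
#' zero-range (flat) chunk yields no extrema.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate, Hz.
#' @param prominence prominence threshold on the normalized scale.
#' @return list with data.frames `peaks` and `troughs` (columns `index`,
#'   `height` on the normalized scale, `prominence`) and the normalized
#'   signal `normalized`.
#' @export
detect_breath_extrema <- function(x, rate_hz = 17, prominence = 0.15) {
  stopifnot(is.numeric(x), length(x) >= 5L)
  med <- as.numeric(stats::runmed(x, k = 5L, endrule = "median"))
  rng <- range(med)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (rng[2L] == rng[1L]) {
    return(list(peaks = empty, troughs = empty,
                normalized = rep(0, length(med))))
  }
  z <- (med - rng[1L]) / (rng[2L] - rng[1L])
  list(peaks = find_peaks(z, prominence),
       troughs = find_troughs(z, prominence),
       normalized = z)
}

#' Statistical features of a respiratory chunk
#'
#' The 13-dimensional feature vector feeding the pattern classifier,
#' spanning three groups:
#' * time domain (signal peaks): standard deviation, mean and maximum of
#'   the detected peak amplitudes (raw amplitude scale) and the number of
#'   peaks;
#' * time-frequency domain: standard deviation, mean, max, min and range
#'   of the instantaneous frequency, obtained from the Hilbert-transform
#'   analytic signal as the derivative of the unwrapped phase over 2*pi,
#'   with 0.5 s trimmed at each end against edge artifacts;
#' * short-term energy: standard deviation, max, min and range of the
#'   signal energy over three non-overlapping 5-s segments of the 15-s
#'   chunk.
#'
#' Peaks are located with the breath detector ([detect_breath_extrema()]);
#' their amplitudes are read off the raw chunk. A chunk with no detected
#' peaks gets zero peak statistics; a constant chunk additionally gets
#' zero instantaneous-frequency statistics.
#'
#' @param chunk a [resp_chunk()] or numeric vector.
#' @return named numeric vector of 13 features.
#' @export
extract_features <- function(chunk) {
  x <- chunk_samples(chunk)
  rate <- chunk_rate(chunk)
  stopifnot(length(x) >= 2 * rate)
  sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)

  ext <- detect_breath_extrema(x, rate)
  if (nrow(ext$peaks) > 0L) {
    amps <- x[ext$peaks$index]
    pk <- c(sd0(amps), mean(amps), max(amps), nrow(ext$peaks))
  } else {
    pk <- c(0, 0, 0, 0)
  }

  if (max(x) == min(x)) {
    iff <- c(0, 0, 0, 0, 0)
  } else {
    f <- instantaneous_frequency(x, rate, trim_s = 0.5)
    iff <- c(sd0(f), mean(f), max(f), min(f), max(f) - min(f))
  }

  seg_len <- floor(length(x) / 3L)
  energies <- vapply(0:2, function(k) {
    sum(x[(k * seg_len + 1L):((k + 1L) * seg_len)]^2)
  }, numeric(1))
  ste <- c(sd0(energies), max(energies), min(energies),
           max(energies) - min(energies))

  stats::setNames(c(pk, iff, ste), FEATURE_NAMES)
}

# feature matrix of a whole database
database_features <- function(db) {
  stopifnot(inherits(db, "resp_database"))
  t(vapply(db$chunks, extract_features, numeric(length(FEATURE_NAMES))))
}

#' Train the respiration-pattern classifier
#'
#' Random forest over the 13 statistical features of
#' [extract_features()], 100 trees by default, seeded for
#' reproducibility. Other forest hyperparameters stay at library
#' defaults.
#'
#' @param db a labeled `resp_database` (see [gen_training_database()]),
#'   or a feature matrix if `labels` is given.
#' @param labels factor of class labels (only when `db` is a matrix).
#' @param n_trees number of trees (default 100).
#' @param seed integer seed (default 1).
#' @return list of class `rp_classifier` wrapping the forest and the
#'   feature schema. Persist with [saveRDS()]/[readRDS()].
#' @export
train_classifier <- function(db, labels = NULL, n_trees = 100, seed = 1) {
  if (inherits(db, "resp_database")) {
    feats <- database_features(db)
    labels <- db$labels
  } else {
    feats <- as.matrix(db)
    stopifnot(!is.null(labels), nrow(feats) == length(labels))
    labels <- factor(labels)
  }
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) {
    stop("training database must contain at least 2 classes", call. = FALSE)
  }
  colnames(feats) <- FEATURE_NAMES
  model <- with_seed(seed, {
    randomForest::randomForest(x = feats, y = labels, ntree = n_trees)
  })
  structure(list(model = model, feature_names = FEATURE_NAMES,
                 n_trees = n_trees, seed = seed),
            class = "rp_classifier")
}

#' @export
print.rp_classifier <- function(x, ...) {
  cat(sprintf("rp_classifier: random forest, %d trees, %d features\n",
              x$n_trees, length(x$feature_names)))
  invisible(x)
}

#' A respiration-pattern label
#'
#' @param label one of the five pattern names.
#' @param source `"classifier"` or `"discriminator_override"`.
#' @return list of class `pattern_label`.
#' @export
pattern_label <- function(label, source = "classifier") {
  stopifnot(label %in% PATTERNS,
            source %in% c("classifier", "discriminator_override"))
  structure(list(label = label, source = source), class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("pattern_label: %s (%s)\n", x$label, x$source))
  invisible(x)
}

#' Classify a chunk's feature vector
#'
#' @param classifier an [train_classifier()] model.
#' @param features named feature vector from [extract_features()] (or a
#'   [resp_chunk()], whose features are extracted first).
#' @return a [pattern_label()] with source `"classifier"`.
#' @export
classify <- function(classifier, features) {
  stopifnot(inherits(classifier, "rp_classifier"))
  if (inherits(features, "resp_chunk")) features <- extract_features(features)
  if (is.null(names(features)) ||
      !all(classifier$feature_names %in% names(features))) {
    stop("feature vector does not match the classifier's schema",
         call. = FALSE)
  }
  fm <- matrix(features[classifier$feature_names], nrow = 1L,
               dimnames = list(NULL, classifier$feature_names))
  lab <- as.character(predict(classifier$model, fm))
  pattern_label(lab, "classifier")
}

#' Signal quality index of a respiratory chunk
#'
#' Morphological quality check on one 15-s chunk. Peaks and troughs are
#' detected with the breath detector; each pair of consecutive peaks
#' enclosing at least one trough counts as a valid breath interval.
#' The chunk passes when (i) the normalized standard deviation (SD/mean)
#' of the valid breath intervals is below 0.25 — only moderate
#' cycle-duration variation — and (ii) there are at least 3 valid breath
#' intervals in the chunk.
#'
#' @param chunk a [resp_chunk()] or numeric vector.
#' @return list of class `quality_report`: `n_valid_breaths`,
#'   `breath_intervals_s`, `interval_nsd`, `passed`.
#' @export
evaluate_signal_quality <- function(chunk) {
  x <- chunk_samples(chunk)
  rate <- chunk_rate(chunk)
  stopifnot(length(x) >= 5L)
  ext <- detect_breath_extrema(x, rate)
  p <- ext$peaks$index
  tr <- ext$troughs$index
  intervals <- numeric(0)
  if (length(p) >= 2L) {
    for (i in seq_len(length(p) - 1L)) {
      if (any(tr > p[i] & tr < p[i + 1L])) {
        intervals <- c(intervals, (p[i + 1L] - p[i]) / rate)
      }
    }
  }
  n <- length(intervals)
  nsd <- if (n >= 2L && mean(intervals) > 0) {
    stats::sd(intervals) / mean(intervals)
  } else NA_real_
  passed <- n >= 3L && !is.na(nsd) && nsd < 0.25
  structure(list(n_valid_breaths = n, breath_intervals_s = intervals,
                 interval_nsd = nsd, passed = passed),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: %d valid breaths, interval NSD %s -> %s\n",
              x$n_valid_breaths,
              ifelse(is.na(x$interval_nsd), "NA",
                     sprintf("%.3f", x$interval_nsd)),
              if (x$passed) "pass" else "fail"))
  invisible(x)
}

#' Crescendo-decrescendo (Cheyne-Stokes) morphology test
#'
#' Detects the breath peaks of the chunk, locates the maximum-amplitude
#' peak as the boundary, and returns TRUE only when peak amplitudes
#' strictly increase up to the boundary and strictly decrease after it —
#' the tidal-volume envelope of a Cheyne-Stokes cycle. Fewer than two
#' peaks fail the test.
#'
#' @param chunk a [resp_chunk()] or numeric vector.
#' @return logical.
#' @export
evaluate_csr_pattern <- function(chunk) {
  x <- chunk_samples(chunk)
  rate <- chunk_rate(chunk)
  ext <- detect_breath_extrema(x, rate)
  amps <- ext$peaks$height
  k <- length(amps)
  if (k < 2L) return(FALSE)
  b <- which.max(amps)
  up <- if (b >= 2L) all(diff(amps[1:b]) > 0) else TRUE
  down <- if (b <= k - 1L) all(diff(amps[b:k]) < 0) else TRUE
  up && down
}

#' Confirm or override a classifier label (pattern discriminator)
#'
#' Morphological second stage of the pattern classification:
#' * an apnea label is kept as-is — an apnea chunk has no breaths and
#'   cannot satisfy the quality criteria by construction;
#' * any other chunk failing the signal quality index is relabeled
#'   `nonstationary` (low quality);
#' * a CSR label is confirmed only when the chunk also passes the
#'   crescendo-decrescendo morphology test; otherwise it becomes
#'   `eupnea`;
#' * remaining labels passing the quality index are kept.
#' The returned label's `source` is `"discriminator_override"` whenever
#' the label changed.
#'
#' @param classifier_label a [pattern_label()] or pattern name string.
#' @param chunk the same chunk the classifier saw.
#' @return the final [pattern_label()].
#' @export
discriminate <- function(classifier_label, chunk) {
  lab <- if (inherits(classifier_label, "pattern_label")) {
    classifier_label$label
  } else {
    stopifnot(classifier_label %in% PATTERNS)
    classifier_label
  }
  if (lab == "apnea") return(pattern_label("apnea", "classifier"))
  q <- evaluate_signal_quality(chunk)
  if (!q$passed) {
    return(pattern_label("nonstationary",
                         if (lab == "nonstationary") "classifier"
                         else "discriminator_override"))
  }
  if (lab == "csr") {
    if (evaluate_csr_pattern(chunk)) {
      return(pattern_label("csr", "classifier"))
    }
    return(pattern_label("eupnea", "discriminator_override"))
  }
  pattern_label(lab, "classifier")
}

#' k-fold cross-validated accuracy of the pattern classifier
#'
#' @param db a labeled `resp_database`.
#' @param k number of folds (default 10).
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed controlling fold assignment and forests.
#' @return list with `accuracy` (overall) and `fold_accuracy`.
#' @export
cross_validate_classifier <- function(db, k = 10, n_trees = 100, seed = 1) {
  feats <- database_features(db)
  labels <- db$labels
  n <- nrow(feats)
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(k), n))
    correct <- logical(n)
    for (fold in seq_len(k)) {
      test <- folds == fold
      model <- train_classifier(feats[!test, , drop = FALSE],
                                labels[!test], n_trees = n_trees,
                                seed = seed + fold)
      fm <- feats[test, , drop = FALSE]
      colnames(fm) <- FEATURE_NAMES
      pred <- as.character(predict(model$model, fm))
      correct[test] <- pred == as.character(labels[test])
    }
    list(accuracy = mean(correct),
         fold_accuracy = vapply(seq_len(k), function(f) {
           mean(correct[folds == f])
         }, numeric(1)))
  })
}

#' Evaluate a trained classifier on a labeled database
#'
#' Applies the classifier (with or without the discriminator stage) to
#' every chunk and reports a confusion matrix with per-class precision,
#' recall and F1.
#'
#' @param classifier an `rp_classifier`.
#' @param db a labeled `resp_database`.
#' @param discriminator apply [discriminate()] after the classifier
#'   (default TRUE).
#' @return list with `accuracy`, `confusion` (true x predicted) and
#'   `per_class` data.frame.
#' @export
evaluate_classifier <- function(classifier, db, discriminator = TRUE) {
  truth <- as.character(db$labels)
  pred <- vapply(seq_along(db$chunks), function(i) {
    lab <- classify(classifier, db$chunks[[i]])
    if (discriminator) lab <- discriminate(lab, db$chunks[[i]])
    lab$label
  }, character(1))
  confusion <- table(truth = factor(truth, PATTERNS),
                     predicted = factor(pred, PATTERNS))
  per_class <- do.call(rbind, lapply(PATTERNS, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1)
  }))
  list(accuracy = mean(pred == truth), confusion = confusion,
       per_class = per_class)
}
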