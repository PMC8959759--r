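# Respiratory-signal extraction from the radar matrix and respiration-rate
# estimation.

#' One respiratory waveform chunk
#'
#' A 15-s (by default) slow-time amplitude series extracted from a single
#' range bin of one radar, tied to a subject.
#'
#' @param samples numeric amplitude vector (255 samples at the default
#'   15 s x 17 Hz).
#' @param rate_hz sampling rate, Hz (default 17).
#' @param subject_id,radar_id,range_bin provenance (optional).
#' @param t_start chunk start time, seconds.
#' @return list of class `resp_chunk`.
#' @export
resp_chunk <- function(samples, rate_hz = 17, subject_id = NA,
                       radar_id = NA, range_bin = NA, t_start = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, rate_hz > 0)
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 subject_id = subject_id, radar_id = radar_id,
                 range_bin = range_bin, t_start = t_start),
            class = "resp_chunk")
}

#' @export
print.resp_chunk <- function(x, ...) {
  cat(sprintf(
    "resp_chunk: %d samples at %g Hz (%.1f s), subject %s, radar %s, bin %s\n",
    length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
    x$subject_id, x$radar_id, x$range_bin))
  invisible(x)
}

chunk_samples <- function(chunk) {
  if (inherits(chunk, "resp_chunk")) chunk$samples else as.numeric(chunk)
}

chunk_rate <- function(chunk, default = 17) {
  if (inherits(chunk, "resp_chunk")) chunk$rate_hz else default
}

#' Extract the respiratory signal at a subject's range
#'
#' Candidate range bins are a narrow window of +/- `halfwidth_bins` bins
#' (about the thickness of a human torso at 5.22 cm per bin) around
#' `round(chest_distance_m / range_res_m)`. Among the candidates, the bin
#' whose slow-time series has the largest variance carries the chest
#' micro-motion and is returned as the respiratory signal. The matrix is
#' expected to be preprocessed (background and clutter removed) so that
#' variance reflects motion, not static echo.
#'
#' @param m a preprocessed [radar_matrix()].
#' @param chest_distance_m chest-to-radar distance, meters.
#' @param halfwidth_bins candidate half-width in bins (default 3).
#' @param subject_id attached to the returned chunk (optional).
#' @return a [resp_chunk()]; its `range_bin` records the selected
#'   (0-based) bin.
#' @export
extract_respiratory_signal <- function(m, chest_distance_m,
                                       halfwidth_bins = 3L,
                                       subject_id = NA) {
  stopifnot(inherits(m, "radar_matrix"), halfwidth_bins >= 0)
  center <- round(chest_distance_m / m$range_res_m)
  if (chest_distance_m < 0 || center >= m$n_bins) {
    stop("chest distance beyond the recorded range", call. = FALSE)
  }
  cand <- clamp(seq(center - halfwidth_bins, center + halfwidth_bins),
                0L, m$n_bins - 1L)
  cand <- unique(cand)
  vars <- apply(m$values[, cand + 1L, drop = FALSE], 2L, stats::var)
  best <- cand[which.max(vars)]
  resp_chunk(m$values[, best + 1L], rate_hz = m$slow_rate_hz,
             subject_id = subject_id, radar_id = m$radar_id,
             range_bin = best, t_start = m$t0)
}

#' Respiration-band Butterworth filter
#'
#' Zero-phase (forward-backward) 3rd-order Butterworth bandpass with
#' cutoffs 0.1-0.5 Hz, i.e. 6-30 breaths/min, removing DC, residual
#' clutter drift and out-of-band noise before rate estimation.
#' Forward-backward application keeps peak times unshifted, which matters
#' for the interval-based rate estimator.
#'
#' @param chunk a [resp_chunk()] or numeric vector.
#' @param low_hz,high_hz band edges, Hz (defaults 0.1 and 0.5).
#' @param order filter order (default 3).
#' @return filtered chunk of the same class and length as the input.
#' @export
bandpass_filter <- function(chunk, low_hz = 0.1, high_hz = 0.5, order = 3) {
  if (low_hz >= high_hz || low_hz <= 0) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  rate <- chunk_rate(chunk)
  if (rate <= 2 * high_hz) {
    stop("sampling rate must exceed twice the upper cutoff", call. = FALSE)
  }
  x <- chunk_samples(chunk)
  x <- x - mean(x)  # take out DC first: filtfilt edge transients are
                    # proportional to the offset, and DC is out of band
  bf <- signal::butter(order, c(low_hz, high_hz) / (rate / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  if (inherits(chunk, "resp_chunk")) {
    chunk$samples <- y
    chunk
  } else y
}

#' Respiration rate from peak-to-peak intervals
#'
#' Detects breath peaks on the chunk (median filter, min-max
#' normalization, prominence > 0.15 — the same detector the signal
#' quality index uses), takes the mean interval `dt` between successive
#' peaks and reports `RR = 60 / dt` breaths per minute. Fewer than two
#' peaks yields a no-estimate result (`rr_bpm = NA`).
#'
#' @param chunk a bandpass-filtered [resp_chunk()] or numeric vector.
#' @return list of class `rr_estimate`: `rr_bpm`, `n_peaks`,
#'   `mean_interval_s`.
#' @export
#' @examples
#' x <- sin(2 * pi * 0.25 * (0:254) / 17)  # 15 bpm
#' estimate_rr(resp_chunk(x))$rr_bpm
estimate_rr <- function(chunk) {
  x <- chunk_samples(chunk)
  rate <- chunk_rate(chunk)
  ext <- detect_breath_extrema(x, rate)
  if (nrow(ext$peaks) < 2L) {
    return(structure(list(rr_bpm = NA_real_, n_peaks = nrow(ext$peaks),
                          mean_interval_s = NA_real_),
                     class = "rr_estimate"))
  }
  dt <- mean(diff(ext$peaks$index)) / rate
  structure(list(rr_bpm = 60 / dt, n_peaks = nrow(ext$peaks),
                 mean_interval_s = dt),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  if (is.na(x$rr_bpm)) {
    cat(sprintf("rr_estimate: no estimate (%d peak(s))\n", x$n_peaks))
  } else {
    cat(sprintf("rr_estimate: %.2f breaths/min (%d peaks, mean interval %.2f s)\n",
                x$rr_bpm, x$n_peaks, x$mean_interval_s))
  }
  invisible(x)
}
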