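# Radar matrix container, resampling, background subtraction and
# truncated-SVD clutter removal.

#' Radar slow-time x fast-time amplitude matrix
#'
#' The raw observation of one IR-UWB radar: rows are slow-time samples
#' (successive pulses, 17 Hz after resampling) and columns are fast-time
#' range bins (about 5.22 cm of distance each). Range bins are indexed
#' from 0, so bin `b` (distance roughly `b * range_res_m`) is matrix
#' column `b + 1`.
#'
#' @param values numeric matrix, slow time in rows, range bins in columns.
#' @param radar_id radar identifier.
#' @param slow_rate_hz slow-time sampling rate, Hz (default 17).
#' @param range_res_m range resolution, meters per bin (default 0.0522).
#' @param t0 time of the first row, seconds (default 0).
#' @return list of class `radar_matrix` with fields `values`, `radar_id`,
#'   `slow_rate_hz`, `range_res_m`, `t0`, `n_bins`.
#' @export
radar_matrix <- function(values, radar_id, slow_rate_hz = 17,
                         range_res_m = 0.0522, t0 = 0) {
  stopifnot(is.matrix(values), is.numeric(values),
            slow_rate_hz > 0, range_res_m > 0)
  structure(list(values = values, radar_id = radar_id,
                 slow_rate_hz = slow_rate_hz, range_res_m = range_res_m,
                 t0 = t0, n_bins = ncol(values)),
            class = "radar_matrix")
}

#' @export
print.radar_matrix <- function(x, ...) {
  cat(sprintf(
    "radar_matrix: radar %s, %d slow-time samples x %d range bins (%.1f s at %g Hz)\n",
    x$radar_id, nrow(x$values), x$n_bins, nrow(x$values) / x$slow_rate_hz,
    x$slow_rate_hz))
  invisible(x)
}

# slice rows covering [t_start, t_end) (seconds relative to t0)
slice_radar_matrix <- function(m, t_start, t_end) {
  stopifnot(inherits(m, "radar_matrix"))
  i0 <- round((t_start - m$t0) * m$slow_rate_hz) + 1L
  i1 <- round((t_end - m$t0) * m$slow_rate_hz)
  if (i0 < 1L || i1 > nrow(m$values)) {
    stop("requested window outside the recording", call. = FALSE)
  }
  radar_matrix(m$values[i0:i1, , drop = FALSE], m$radar_id, m$slow_rate_hz,
               m$range_res_m, t0 = t_start)
}

#' Resample a signal to a new rate by linear interpolation
#'
#' All streams in the pipeline are brought to a common slow-time rate
#' (17 Hz by default) before analysis. The signal is interpolated linearly
#' on its original time grid; the output spans the same duration. Linear
#' interpolation is adequate here because the respiration band (below
#' 0.5 Hz) sits far beneath the Nyquist rate.
#'
#' @param x numeric vector.
#' @param src_rate_hz original sampling rate, Hz.
#' @param dst_rate_hz target rate, Hz (default 17).
#' @return numeric vector of length `round(length(x) * dst / src)`.
#' @export
resample_signal <- function(x, src_rate_hz, dst_rate_hz = 17) {
  if (!is.numeric(src_rate_hz) || src_rate_hz <= 0 ||
      !is.numeric(dst_rate_hz) || dst_rate_hz <= 0) {
    stop("sampling rates must be positive", call. = FALSE)
  }
  stopifnot(is.numeric(x), length(x) >= 2L)
  n_out <- round(length(x) * dst_rate_hz / src_rate_hz)
  t_in <- (seq_along(x) - 1L) / src_rate_hz
  t_out <- (seq_len(n_out) - 1L) / dst_rate_hz
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Subtract per-bin background from a radar matrix
#'
#' Removes the static echo profile by subtracting a background amplitude
#' vector from every slow-time row. When no background is supplied it is
#' estimated as the per-bin mean over a calibration prefix (first
#' `calib_s` seconds), or over the whole matrix if the recording is
#' shorter than the prefix.
#'
#' @param m a [radar_matrix()].
#' @param background numeric vector of length `n_bins`, or NULL to
#'   estimate from the matrix.
#' @param calib_s calibration prefix length in seconds (default 5).
#' @return a `radar_matrix` of the same shape.
#' @export
remove_background <- function(m, background = NULL, calib_s = 5) {
  stopifnot(inherits(m, "radar_matrix"))
  if (is.null(background)) {
    k <- round(calib_s * m$slow_rate_hz)
    rows <- if (nrow(m$values) >= k && k >= 1L) seq_len(k)
            else seq_len(nrow(m$values))
    background <- colMeans(m$values[rows, , drop = FALSE])
  }
  if (length(background) != m$n_bins) {
    stop(sprintf("background length %d does not match %d range bins",
                 length(background), m$n_bins), call. = FALSE)
  }
  out <- m
  out$values <- sweep(m$values, 2L, background, `-`)
  out
}

#' Remove clutter with a truncated singular value decomposition
#'
#' Static clutter (walls, furniture) is constant over slow time and
#' dominates the leading singular components of the radar matrix.
#' Subtracting the rank-`n_components` reconstruction leaves the
#' slow-time-varying part of the echo — the chest micro-motion — intact.
#' One component (the default) suffices for purely static clutter, which
#' is exactly rank one.
#'
#' @param m a [radar_matrix()].
#' @param n_components number of leading singular components to remove;
#'   must satisfy `0 <= n_components < min(dim)`. 0 returns the input
#'   unchanged.
#' @return a `radar_matrix` of the same shape.
#' @export
svd_clutter_removal <- function(m, n_components = 1L) {
  stopifnot(inherits(m, "radar_matrix"))
  k <- n_components
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 0 ||
      k >= min(dim(m$values))) {
    stop("n_components must be an integer in [0, min(dim) - 1]",
         call. = FALSE)
  }
  if (k == 0L) return(m)
  s <- svd(m$values, nu = k, nv = k)
  low <- s$u %*% (diag(s$d[seq_len(k)], nrow = k) %*% t(s$v))
  out <- m
  out$values <- m$values - low
  out
}

#' Default per-window radar preprocessing
#'
#' Truncated-SVD clutter removal followed by background subtraction, the
#' standard preparation before respiratory-signal extraction. The SVD
#' acts on the raw matrix, where static clutter is still the dominant
#' singular direction; if the background (a per-bin mean estimated from
#' the matrix itself) were subtracted first, the respiratory modulation
#' would become the leading component and the truncation would strip it.
#' The subsequent background subtraction removes any residual per-bin
#' offset. With a separately recorded empty-room background vector,
#' subtract it explicitly with [remove_background()] before calling this.
#'
#' @param m a [radar_matrix()].
#' @param n_components singular components removed (default 1).
#' @return a preprocessed `radar_matrix`.
#' @export
preprocess_radar_matrix <- function(m, n_components = 1L) {
  remove_background(svd_clutter_removal(m, n_components))
}

#' Read / write radar matrices as CSV
#'
#' Plain headerless CSV, one slow-time sample per row, one range-bin
#' column per matrix column (180 at the default geometry).
#'
#' @param path file path.
#' @param radar_id radar identifier to attach on read.
#' @inheritParams radar_matrix
#' @return `read_radar_csv` returns a `radar_matrix`; `write_radar_csv`
#'   returns `path` invisibly.
#' @export
read_radar_csv <- function(path, radar_id, slow_rate_hz = 17,
                           range_res_m = 0.0522) {
  if (!file.exists(path)) stop("radar file not found: ", path, call. = FALSE)
  vals <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(vals) <- NULL
  radar_matrix(vals, radar_id, slow_rate_hz, range_res_m)
}

#' @rdname read_radar_csv
#' @param m a `radar_matrix`.
#' @export
write_radar_csv <- function(m, path) {
  stopifnot(inherits(m, "radar_matrix"))
  utils::write.table(m$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
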