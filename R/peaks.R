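#' Local maxima with topographic prominence
#'
#' Finds strict local maxima of a sequence and computes each peak's
#' topographic prominence: the drop from the peak to the higher of the two
#' key saddles, where each saddle is the minimum of the signal between the
#' peak and the nearest higher point on that side (or the signal edge).
#' This is the quantity thresholded at 0.15 on \[0,1\]-normalized
#' respiratory chunks throughout the signal quality index.
#'
#' Plateaus (runs of equal values) are treated as a single candidate at the
#' left edge of the run.
#'
#' @param x numeric vector.
#' @param min_prominence keep only peaks with prominence strictly greater
#'   than this value (default 0: keep all).
#' @return data.frame with columns `index`, `height`, `prominence`,
#'   one row per retained peak, ordered by index.
#' @export
#' @examples
#' x <- sin(2 * pi * 0.25 * seq(0, 15, by = 1 / 17))
#' find_peaks(x, min_prominence = 0.15)
find_peaks <- function(x, min_prominence = 0) {
  stopifnot(is.numeric(x))
  n <- length(x)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3L) return(empty)
  d <- diff(x)
  s <- sign(d)
  # carry the previous slope through flat runs so a plateau top counts once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(s[-length(s)] > 0 & s[-1L] < 0) + 1L
  if (length(idx) == 0L) return(empty)
  prom <- vapply(idx, function(i) {
    h <- x[i]
    left <- if (i == 1L) h else {
      higher <- which(x[seq_len(i - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(x[lo:(i - 1L)])
    }
    right <- if (i == n) h else {
      rest <- x[(i + 1L):n]
      higher <- which(rest > h)
      hi <- if (length(higher)) min(higher) - 1L else length(rest)
      min(rest[seq_len(hi)])
    }
    h - max(left, right)
  }, numeric(1))
  keep <- prom > min_prominence
  data.frame(index = idx[keep], height = x[idx[keep]],
             prominence = prom[keep])
}

#' Local minima with topographic prominence
#'
#' Troughs of `x`, computed as peaks of `-x`. `height` is reported on the
#' original scale of `x`.
#'
#' @inheritParams find_peaks
#' @return data.frame with columns `index`, `height`, `prominence`.
#' @export
find_troughs <- function(x, min_prominence = 0) {
  tr <- find_peaks(-x, min_prominence)
  tr$height <- -tr$height
  tr
}
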