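# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Scalar clamp.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vec_norm <- function(v) sqrt(sum(v^2))

deg2rad <- function(d) d * pi / 180

rad2deg <- function(r) r * 180 / pi

is_point3 <- function(p) is.numeric(p) && length(p) == 3L && all(is.finite(p))

stop_if_not_point3 <- function(p, name) {
  if (!is_point3(p)) {
    stop(sprintf("'%s' must be a finite numeric vector of length 3", name),
         call. = FALSE)
  }
}

# Unwrap a phase sequence (add multiples of 2*pi so jumps stay below pi).
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(phi[1L], phi[1L] + cumsum(d))
}

#' Analytic signal via the discrete Hilbert transform
#'
#' Computes the complex analytic signal of a real sequence by zeroing the
#' negative-frequency half of its DFT and doubling the positive half. The
#' imaginary part is the discrete Hilbert transform of the input; the phase
#' of the result carries the instantaneous frequency of a narrowband signal.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length as `x`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous frequency of a narrowband signal
#'
#' Derivative of the unwrapped analytic-signal phase divided by 2*pi. The
#' first and last `trim_s` seconds are discarded because the circular DFT
#' underlying the analytic signal distorts the phase near the edges.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param trim_s seconds discarded at each end (default 0.5).
#' @return numeric vector of instantaneous frequencies in Hz.
#' @keywords internal
instantaneous_frequency <- function(x, rate_hz, trim_s = 0.5) {
  phi <- unwrap_phase(Arg(analytic_signal(x)))
  f <- diff(phi) * rate_hz / (2 * pi)
  k <- round(trim_s * rate_hz)
  if (length(f) > 2 * k && k > 0) f <- f[(k + 1L):(length(f) - k)]
  f
}
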