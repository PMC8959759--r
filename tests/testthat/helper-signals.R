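# Constructed waveforms with exactly placed breath peaks.
#
# Each peak is a triangular bump with a 3-sample flat top centered at the
# requested sample index, so the kernel-5 median filter preserves it
# exactly and the detected peak (left edge of the top plateau) sits at a
# fixed offset from every requested index — peak-to-peak intervals are
# exact.
make_bump_signal <- function(peak_idx, amplitudes = 1, n = 255) {
  amplitudes <- rep_len(amplitudes, length(peak_idx))
  x <- numeric(n)
  ramp <- c(0.2, 0.4, 0.6, 0.8)
  shape <- c(ramp, 1, 1, 1, rev(ramp))   # 11 samples, top at 5..7
  for (k in seq_along(peak_idx)) {
    j <- peak_idx[k] + seq(-5L, 5L)
    ok <- j >= 1L & j <= n
    x[j[ok]] <- pmax(x[j[ok]], amplitudes[k] * shape[ok])
  }
  x
}
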