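# Independent brute-force oracle for the sliding-window spectral power:
# Hann-taper the 32-sample window centred on each valid sample, zero-pad to
# 64 and evaluate the DFT by explicit summation.
oracle_stft_db <- function(trace, fs, freqs, window_len = 32, pad_to = 64,
                           eps = 1e-12) {
  n <- length(trace)
  half <- window_len / 2
  centers <- seq(half + 1, n - half)
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(window_len) - 1) / window_len))
  bins <- round(freqs / (fs / pad_to))
  out <- matrix(0, length(centers), length(freqs))
  for (j in seq_along(centers)) {
    t <- centers[j]
    w <- c(trace[(t - half):(t + half - 1)] * taper,
           rep(0, pad_to - window_len))
    for (b in seq_along(bins)) {
      k <- bins[b]
      m <- seq_len(pad_to) - 1
      X <- sum(w * exp(-2i * pi * k * m / pad_to))
      out[j, b] <- 10 * log10(Mod(X)^2 + eps)
    }
  }
  out
}
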