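## The 40-feature temporal dataset: 4 cluster amplitudes plus 4 clusters x 9
## spectral-power features over time.

#' Linearly spaced frequency grid
#'
#' @param f_min,f_max inclusive endpoints in Hz.
#' @param n number of frequencies (>= 2).
#' @return numeric vector of `n` frequencies.
#' @examples
#' frequency_grid()        # 4, 8, ..., 36 Hz
#' @export
frequency_grid <- function(f_min = 4, f_max = 36, n = 9) {
  stopifnot_scalar_number(n, "n", lower = 2)
  if (f_max <= f_min) stop("`f_max` must exceed `f_min`", call. = FALSE)
  seq(f_min, f_max, length.out = n)
}

## Hann taper (periodic form, as used for spectral analysis windows).
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Sliding-window spectral power of one trace
#'
#' For each output sample, the 32-sample window centred on it (16 samples
#' before, 15 after plus the sample itself) is Hann-tapered, zero-padded to
#' `pad_to` samples and Fourier-transformed; power is the squared magnitude at
#' the DFT bin nearest each requested frequency, in dB as
#' `10 * log10(power + eps)`. Output is defined only where a full window fits:
#' `window_len / 2` samples are trimmed from each end of the trace.
#'
#' Zero-padding to 64 samples makes the default 4 Hz grid at 256 Hz land
#' exactly on DFT bins (bin spacing `fs / pad_to` = 4 Hz), so "nearest bin" is
#' exact for the default analysis.
#'
#' @param trace numeric vector of voltages (microvolts).
#' @param fs sampling rate, Hz.
#' @param freqs frequencies to evaluate, Hz (must not exceed `fs / 2`).
#' @param window_len sliding Hann window length in samples (even, default 32).
#' @param pad_to zero-padded DFT length (default 64).
#' @param eps floor added to power before the log (default 1e-12).
#' @return matrix of `length(trace) - window_len` rows (valid samples) by
#'   `length(freqs)` columns, in dB.
#' @export
stft_power <- function(trace, fs, freqs = frequency_grid(), window_len = 32,
                       pad_to = 2 * window_len, eps = 1e-12) {
  n <- length(trace)
  if (window_len %% 2 != 0) stop("`window_len` must be even", call. = FALSE)
  if (window_len > n) stop("`window_len` exceeds the trace length", call. = FALSE)
  if (any(freqs > fs / 2)) {
    stop(sprintf("requested frequency above the Nyquist rate %g Hz", fs / 2),
         call. = FALSE)
  }
  half <- window_len / 2
  centers <- seq(half + 1, n - half)          # trimmed output samples
  taper <- hann_window(window_len)
  ## window for center t: samples (t - half) .. (t + half - 1)
  win <- matrix(0, nrow = pad_to, ncol = length(centers))
  for (j in seq_along(centers)) {
    t <- centers[j]
    win[seq_len(window_len), j] <- trace[(t - half):(t + half - 1)] * taper
  }
  spec <- stats::mvfft(win)
  bin_hz <- fs / pad_to
  bins <- round(freqs / bin_hz) + 1L          # nearest DFT bin, 1-based
  p <- t(Mod(spec[bins, , drop = FALSE])^2)
  10 * log10(p + eps)
}

#' Build the 40-feature temporal tensor
#'
#' Amplitude features are the raw cluster voltages at the trimmed samples;
#' power features come from [stft_power()] per cluster. Feature order is
#' fixed: `amp_<cluster>` for the four clusters (occipital, parietal, central,
#' frontal), then `pow_<freq>Hz_<cluster>` looping frequencies within cluster.
#'
#' @param epochs a 4-cluster `epoch_set`.
#' @param freqs frequency grid (default [frequency_grid()]).
#' @param window_len,pad_to,eps passed to [stft_power()].
#' @return an object of class `temporal_features`: list with `values`
#'   (trials x trimmed samples x 40 array), `feature_names`, `times`
#'   (trimmed, ms), `labels`, `participant_id`, `group`.
#' @export
build_temporal_features <- function(epochs, freqs = frequency_grid(),
                                    window_len = 32, pad_to = 2 * window_len,
                                    eps = 1e-12) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$voltages)
  half <- window_len / 2
  keep <- seq(half + 1, d[2] - half)
  nf <- length(freqs)
  feature_names <- c(
    paste0("amp_", CLUSTERS),
    unlist(lapply(CLUSTERS, function(cl) paste0("pow_", freqs, "Hz_", cl)))
  )
  vals <- array(0, dim = c(d[1], length(keep), 4 + 4 * nf),
                dimnames = list(NULL, NULL, feature_names))
  for (ci in seq_along(CLUSTERS)) {
    vals[, , ci] <- epochs$voltages[, keep, ci]
    for (tr in seq_len(d[1])) {
      vals[tr, , 4 + (ci - 1) * nf + seq_len(nf)] <-
        stft_power(epochs$voltages[tr, , ci], epochs$fs, freqs,
                   window_len = window_len, pad_to = pad_to, eps = eps)
    }
  }
  structure(
    list(values = vals, feature_names = feature_names,
         times = epochs$times[keep], labels = epochs$labels,
         participant_id = epochs$participant_id, group = epochs$group),
    class = "temporal_features"
  )
}

#' @export
print.temporal_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<temporal_features> participant %s: %d trials x %d time points x %d features (%.1f..%.1f ms)\n",
    x$participant_id, d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}
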