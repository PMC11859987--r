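#' Short-time magnitude spectrogram
#'
#' Frames the waveform into windows of `window_len` samples with the given
#' overlap and returns the one-sided magnitude spectrum of each frame. No
#' taper is applied by default, so Parseval's relation holds exactly for the
#' non-overlapping case: the summed squared magnitudes equal
#' `window_len` times the waveform energy of the framed samples.
#'
#' @param samples Waveform in `[-1, 1]` (an all-zero waveform is allowed;
#'   downstream indices flag it).
#' @param sample_rate Sampling rate in Hz.
#' @param window_len Frame length in samples (default 512).
#' @param overlap Fractional overlap between frames in `[0, 1)` (default 0).
#' @return A list of class `spectrogram`: `magnitudes`
#'   (frequency x frame matrix, non-negative), `freq` (bin-centre
#'   frequencies, Hz, 0 to Nyquist), `frame_times` (s), `freq_bin_hz`,
#'   `window_len`, `overlap`, `sample_rate`.
#' @export
compute_spectrogram <- function(samples, sample_rate = 48000,
                                window_len = 512L, overlap = 0) {
  stopifnot(length(samples) >= window_len, overlap >= 0, overlap < 1)
  hop <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq(1L, length(samples) - window_len + 1L, by = hop)
  frames <- vapply(
    starts, function(s) samples[s:(s + window_len - 1L)],
    numeric(window_len)
  )
  spec <- stats::mvfft(frames)
  n_bins <- window_len %/% 2L + 1L
  mag <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  structure(
    list(
      magnitudes = mag,
      freq = (seq_len(n_bins) - 1) * sample_rate / window_len,
      frame_times = (starts - 1 + window_len / 2) / sample_rate,
      freq_bin_hz = sample_rate / window_len,
      window_len = window_len, overlap = overlap, sample_rate = sample_rate
    ),
    class = "spectrogram"
  )
}

# Accept either a waveform (with sample_rate) or a ready spectrogram.
as_spectrogram <- function(x, sample_rate = 48000, window_len = 512L,
                           overlap = 0) {
  if (inherits(x, "spectrogram")) {
    x
  } else {
    compute_spectrogram(x, sample_rate, window_len, overlap)
  }
}
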