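# Small audio fixtures, built in code at test time.

tone <- function(freq, duration_s = 0.5, sample_rate = 48000, amp = 0.8,
                 phase = 0.1) {
  tt <- seq_len(round(duration_s * sample_rate)) / sample_rate
  amp * sin(2 * pi * freq * tt + phase)
}

white <- function(duration_s = 0.5, sample_rate = 48000, amp = 0.5, seed = 1) {
  withr::with_seed(seed, amp * rnorm(round(duration_s * sample_rate)) / 4)
}

# a bed of chirps confined to 2-8 kHz riding on faint noise
chirp_bed <- function(duration_s = 1, sample_rate = 48000, seed = 1) {
  spec <- soundscape_spec(river_park_sites(), seed = seed)
  gen_audio_segment(spec, "1", 1,
    b = 0.8, a = 0,
    duration_s = duration_s, sample_rate = sample_rate
  )$samples
}

# a synthetic spectrogram object with prescribed magnitudes
fake_spectrogram <- function(magnitudes, sample_rate = 48000,
                             window_len = 512L) {
  n_bins <- nrow(magnitudes)
  structure(
    list(
      magnitudes = magnitudes,
      freq = (seq_len(n_bins) - 1) * sample_rate / window_len,
      frame_times = seq_len(ncol(magnitudes)) * window_len / sample_rate,
      freq_bin_hz = sample_rate / window_len,
      window_len = window_len, overlap = 0, sample_rate = sample_rate
    ),
    class = "spectrogram"
  )
}

# a small index matrix with hand-set timestamps for assembly tests
toy_index_rows <- function(n_sites = 2, n_windows = 30, step_s = 360,
                           seed = 1) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      site_id = as.character(seq_len(n_sites)),
      w = seq_len(n_windows)
    )
    ts <- as.POSIXct("2022-04-13 00:00:00", tz = "UTC") + (grid$w - 1) * step_s
    vals <- matrix(runif(nrow(grid) * 8), ncol = 8)
    colnames(vals) <- c("H", "ACI", "ADI", "AEI", "NDSI", "BI", "DSC", "ZCR")
    dplyr::bind_cols(
      tibble::tibble(site_id = grid$site_id, timestamp = ts),
      tibble::as_tibble(vals)
    )
  })
}
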