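# The eight eco-acoustic indices. All spectral indices share one magnitude
# spectrogram (512-sample frames, no overlap by default). dB values are dBFS
# with a full-scale sine as the 0 dB reference: a bin magnitude `m` from an
# unwindowed frame of length L maps to 20*log10(2*m/L).
#
# Silence policy: H and NDSI are undefined on silent input and return NA
# (flagged, never numeric 0); BI returns 0 by convention; ADI/AEI return NA
# when no time-frequency cell exceeds the occupancy threshold.

bin_dbfs <- function(mag, window_len) {
  20 * log10(pmax(2 * mag / window_len, 1e-12))
}

# Hilbert amplitude envelope via the analytic signal.
amplitude_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Acoustic entropy (H)
#'
#' Product of the temporal entropy of the normalized Hilbert amplitude
#' envelope and the spectral entropy of the normalized mean magnitude
#' spectrum, each divided by its log-cardinality, so the result lies in
#' `[0, 1]`. Values near 1 indicate spectro-temporal homogeneity (noise-like
#' sound); values near 0 a steady pure tone.
#'
#' @param samples Waveform in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param window_len Spectrogram frame length in samples.
#' @return A value in `[0, 1]`, or `NA` for silent input.
#' @export
compute_h <- function(samples, sample_rate = 48000, window_len = 512L) {
  if (all(samples == 0)) {
    warn("silent segment: H is undefined (NA)")
    return(NA_real_)
  }
  env <- amplitude_envelope(samples)
  p_t <- env / sum(env)
  h_t <- entropy_bits(p_t) / log2(length(env))
  sg <- compute_spectrogram(samples, sample_rate, window_len)
  mean_spec <- rowMeans(sg$magnitudes)
  p_f <- mean_spec / sum(mean_spec)
  h_f <- entropy_bits(p_f) / log2(length(p_f))
  h_t * h_f
}

#' Bioacoustic index (BI)
#'
#' Area under the mean dB spectrum within the biophony band (default
#' 2000-8000 Hz, half-open `[lo, hi)`), after subtracting the minimum dB
#' value in the band, integrated by the trapezoidal rule over frequency in
#' kHz. A spectrum flat across the band gives 0; silence gives 0 by
#' convention.
#'
#' @param samples Waveform or a [compute_spectrogram()] result.
#' @param sample_rate,window_len Spectrogram settings when `samples` is a
#'   waveform.
#' @param band Biophony band in Hz (default `c(2000, 8000)`).
#' @return A non-negative value (dB * kHz).
#' @export
compute_bi <- function(samples, sample_rate = 48000, window_len = 512L,
                       band = c(2000, 8000)) {
  sg <- as_spectrogram(samples, sample_rate, window_len)
  if (all(sg$magnitudes == 0)) {
    warn("silent segment: BI set to 0 by convention")
    return(0)
  }
  sel <- sg$freq >= band[1] & sg$freq < band[2]
  db <- bin_dbfs(rowMeans(sg$magnitudes[sel, , drop = FALSE]), sg$window_len)
  rel <- db - min(db)
  f_khz <- sg$freq[sel] / 1000
  sum(diff(f_khz) * (head(rel, -1) + tail(rel, -1)) / 2)
}

#' Acoustic complexity index (ACI)
#'
#' For each frequency bin within each temporal clump (default 5 s), the sum
#' of absolute differences of successive frame magnitudes divided by the
#' total magnitude in the clump; summed over bins and clumps. A spectrogram
#' constant in time gives 0.
#'
#' @inheritParams compute_bi
#' @param clump_s Temporal clump length in seconds (default 5).
#' @return A non-negative value.
#' @export
compute_aci <- function(samples, sample_rate = 48000, window_len = 512L,
                        clump_s = 5) {
  sg <- as_spectrogram(samples, sample_rate, window_len)
  m <- sg$magnitudes
  frames_per_clump <- max(2L, floor(clump_s * sg$sample_rate / sg$window_len))
  clump_id <- (seq_len(ncol(m)) - 1L) %/% frames_per_clump
  total <- 0
  for (cl in unique(clump_id)) {
    sub <- m[, clump_id == cl, drop = FALSE]
    if (ncol(sub) < 2L) next
    num <- rowSums(abs(sub[, -1L, drop = FALSE] - sub[, -ncol(sub), drop = FALSE]))
    den <- rowSums(sub)
    ok <- den > 0
    total <- total + sum(num[ok] / den[ok])
  }
  total
}

# Occupancy fraction of time-frequency cells above `db_threshold` for each
# 1 kHz band between 0 and `max_freq`. Shared by ADI and AEI.
band_occupancy <- function(sg, db_threshold = -50, band_hz = 1000,
                           max_freq = 10000) {
  db <- bin_dbfs(sg$magnitudes, sg$window_len)
  # bands are capped at the Nyquist frequency: with low sample rates fewer
  # than max_freq/band_hz bands exist
  top <- min(max_freq, sg$sample_rate / 2)
  edges <- seq(0, top, by = band_hz)
  if (length(edges) < 2L) abort("band_hz exceeds the Nyquist frequency")
  vapply(seq_len(length(edges) - 1L), function(i) {
    sel <- sg$freq >= edges[i] & sg$freq < edges[i + 1L]
    mean(db[sel, , drop = FALSE] > db_threshold)
  }, numeric(1))
}

#' Acoustic diversity (ADI) and evenness (AEI) indices
#'
#' Both are built on the occupancy fractions of 1 kHz bands between 0 and
#' `max_freq` Hz: the fraction of spectrogram cells in each band exceeding
#' `db_threshold` (dBFS). ADI is the Shannon entropy (natural log) of the
#' normalized occupancy vector, at most `log(n_bands)`; AEI is its Gini
#' coefficient, in `[0, 1]`. With no occupied cell both are undefined and
#' return `NA`.
#'
#' @inheritParams compute_bi
#' @param db_threshold Occupancy threshold in dBFS (default -50).
#' @param band_hz Band width in Hz (default 1000).
#' @param max_freq Upper frequency bound in Hz (default 10000).
#' @return ADI: value in `[0, log(n_bands)]`; AEI: value in `[0, 1]`.
#' @export
compute_adi <- function(samples, sample_rate = 48000, window_len = 512L,
                        db_threshold = -50, band_hz = 1000, max_freq = 10000) {
  sg <- as_spectrogram(samples, sample_rate, window_len)
  occ <- band_occupancy(sg, db_threshold, band_hz, max_freq)
  if (sum(occ) == 0) {
    warn("no occupied band: ADI undefined (NA)")
    return(NA_real_)
  }
  p <- occ / sum(occ)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname compute_adi
#' @export
compute_aei <- function(samples, sample_rate = 48000, window_len = 512L,
                        db_threshold = -50, band_hz = 1000, max_freq = 10000) {
  sg <- as_spectrogram(samples, sample_rate, window_len)
  occ <- band_occupancy(sg, db_threshold, band_hz, max_freq)
  if (sum(occ) == 0) {
    warn("no occupied band: AEI undefined (NA)")
    return(NA_real_)
  }
  n <- length(occ)
  sum(abs(outer(occ, occ, "-"))) / (2 * n * sum(occ))
}

#' Normalized difference soundscape index (NDSI)
#'
#' `(B - A) / (B + A)` where `B` is the mean spectral power in the biophony
#' band (default 2-8 kHz) and `A` the power in the anthrophony band (default
#' 1-2 kHz); bands are half-open `[lo, hi)`. Lies in `[-1, 1]`; silence is
#' undefined and returns `NA`.
#'
#' @inheritParams compute_bi
#' @param bio_band,anthro_band Frequency bands in Hz.
#' @return A value in `[-1, 1]`, or `NA` for silent input.
#' @export
compute_ndsi <- function(samples, sample_rate = 48000, window_len = 512L,
                         bio_band = c(2000, 8000), anthro_band = c(1000, 2000)) {
  sg <- as_spectrogram(samples, sample_rate, window_len)
  power <- rowMeans(sg$magnitudes^2)
  b <- sum(power[sg$freq >= bio_band[1] & sg$freq < bio_band[2]])
  a <- sum(power[sg$freq >= anthro_band[1] & sg$freq < anthro_band[2]])
  if (b + a == 0) {
    warn("no band power: NDSI undefined (NA)")
    return(NA_real_)
  }
  (b - a) / (b + a)
}

#' Dynamic spectral centroid (DSC)
#'
#' Temporal mean of the per-frame amplitude-weighted spectral centroid.
#' Frames with zero magnitude are skipped; an entirely silent segment
#' returns `NA`.
#'
#' @inheritParams compute_bi
#' @return Centroid frequency in Hz.
#' @export
compute_dsc <- function(samples, sample_rate = 48000, window_len = 512L) {
  sg <- as_spectrogram(samples, sample_rate, window_len)
  tot <- colSums(sg$magnitudes)
  ok <- tot > 0
  if (!any(ok)) {
    warn("silent segment: DSC undefined (NA)")
    return(NA_real_)
  }
  centroids <- colSums(sg$magnitudes[, ok, drop = FALSE] * sg$freq) / tot[ok]
  mean(centroids)
}

#' Zero crossing rate (ZCR)
#'
#' Number of sign changes between consecutive samples divided by `N - 1`;
#' zero samples count as positive. A pure tone of frequency `f0` gives
#' approximately `2 f0 / sample_rate`.
#'
#' @param samples Waveform.
#' @return A value in `[0, 1]`.
#' @export
compute_zcr <- function(samples) {
  s <- ifelse(samples >= 0, 1L, -1L)
  sum(s[-1L] != s[-length(s)]) / (length(samples) - 1L)
}

#' Compute all eight indices for one audio segment
#'
#' @param segment Either a waveform vector or a list with `samples`,
#'   `sample_rate` and optionally `site_id` and `start_time` (as produced by
#'   [gen_audio_segment()] or [read_wav()]).
#' @param sample_rate Sampling rate when `segment` is a bare vector.
#' @param window_len Spectrogram frame length (default 512 samples, no
#'   overlap).
#' @param ... Passed on to the individual index functions.
#' @return A one-row tibble with `site_id`, `timestamp` (when available) and
#'   columns `H, ACI, ADI, AEI, NDSI, BI, DSC, ZCR`.
#' @export
compute_indices <- function(segment, sample_rate = 48000, window_len = 512L,
                            ...) {
  if (is.list(segment)) {
    x <- segment$samples
    sample_rate <- segment$sample_rate %||% sample_rate
    site_id <- segment$site_id %||% NA_character_
    ts <- segment$start_time %||% as.POSIXct(NA)
  } else {
    x <- segment
    site_id <- NA_character_
    ts <- as.POSIXct(NA)
  }
  sg <- compute_spectrogram(x, sample_rate, window_len)
  tibble(
    site_id = site_id, timestamp = ts,
    H = compute_h(x, sample_rate, window_len),
    ACI = compute_aci(sg),
    ADI = compute_adi(sg),
    AEI = compute_aei(sg),
    NDSI = compute_ndsi(sg),
    BI = compute_bi(sg),
    DSC = compute_dsc(sg),
    ZCR = compute_zcr(x)
  )
}

#' Assemble per-segment index rows into an ordered index matrix
#'
#' Orders rows by site then timestamp, rejects duplicated (site, timestamp)
#' pairs, and identifies contiguity blocks: runs of windows whose spacing
#' equals the modal step (one block per site for continuous recordings;
#' duty-cycle pauses equal to the modal step also count as contiguous,
#' larger gaps split blocks).
#'
#' @param rows A data frame of per-segment index rows (`site_id`,
#'   `timestamp`, index columns), in any order.
#' @return A tibble ordered by site and time with an extra `block` column
#'   (integer id of the contiguity run within each site).
#' @export
assemble_series <- function(rows) {
  rows <- as_tibble(rows)
  if (!all(c("site_id", "timestamp") %in% names(rows))) {
    abort("rows need site_id and timestamp columns")
  }
  if (anyDuplicated(rows[c("site_id", "timestamp")])) {
    abort("duplicate (site_id, timestamp) rows")
  }
  out <- dplyr::arrange(rows, .data$site_id, .data$timestamp)
  out <- dplyr::group_by(out, .data$site_id)
  out <- dplyr::mutate(out, block = {
    gaps <- as.numeric(diff(.data$timestamp), units = "secs")
    step <- if (length(gaps)) min(gaps) else 0
    cumsum(c(1L, as.integer(gaps > 1.5 * step)))
  })
  dplyr::ungroup(out)
}
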