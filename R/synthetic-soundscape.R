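# Multi-site soundscape generator. Two latent drivers per site and window:
#   b(s,t)  biophony: a dawn-peaking circadian bump modulating a shared AR(1)
#           process; interior sites carry the process undelayed, edge sites
#           receive it `inter_site_lag` windows later, so information flows
#           interior -> edge by construction.
#   a(s,t)  anthrophony: road-traffic noise attenuated with perpendicular
#           distance from the road as (1 + d/d0)^(-decay_exponent), with a
#           diel traffic profile (quiet at night).
# The eight indices are monotone, noisy functions of (b, a): BI and ACI track
# biophony (BI also picks up high-frequency traffic leakage), NDSI/DSC/ZCR
# track the biophony fraction of total power, and H/ADI/AEI track spectral
# mixing, so a PCA over the eight columns recovers roughly two dimensions.

#' Specify a synthetic multi-site soundscape
#'
#' @param site_map A [site_map()]. Sites grouped `"internal"` carry the
#'   biophony driver undelayed; all other sites receive it `inter_site_lag`
#'   windows later.
#' @param protocol `"continuous"` (one unbroken recording of `duration_h`
#'   hours) or `"duty_cycle"` (`window_s` seconds on, `pause_s` seconds
#'   pause, for `days` days). The defaults reproduce the two field designs:
#'   3.5 h continuous yields 210 one-minute windows; 14 days of
#'   1-min-on/5-min-pause yields 3360 windows.
#' @param window_s Analysis window in seconds (default 60).
#' @param pause_s Pause between windows for the duty-cycle protocol (default
#'   300).
#' @param days Days of recording for the duty-cycle protocol (default 14).
#' @param duration_h Recording length in hours for the continuous protocol
#'   (default 3.5).
#' @param start Start time (POSIXct, UTC) of the deployment.
#' @param chorus_peak_hour Hour of the dawn-chorus peak, within 5-8
#'   (default 6.5).
#' @param chorus_width_h Width (hours) of the circadian bump (default 1.25).
#' @param chorus_amp Amplitude of the biophony driver (default 1).
#' @param road_noise_amp Amplitude of the traffic driver at the road edge
#'   (>= 0; 0 disables anthrophony).
#' @param decay_exponent Distance-decay exponent for road noise (> 0;
#'   default 1, a geometric-spreading surrogate).
#' @param inter_site_lag Lag in windows between interior and edge sites
#'   (default 1).
#' @param noise_sd Multiplier on all per-index observation noises
#'   (default 1).
#' @param seed Integer seed; all generated outputs are bit-reproducible.
#' @return A `soundscape_spec` list.
#' @export
soundscape_spec <- function(site_map,
                            protocol = c("duty_cycle", "continuous"),
                            window_s = 60, pause_s = 300, days = 14L,
                            duration_h = 3.5,
                            start = as.POSIXct("2022-04-13 00:00:00", tz = "UTC"),
                            chorus_peak_hour = 6.5, chorus_width_h = 1.25,
                            chorus_amp = 1, road_noise_amp = 1,
                            decay_exponent = 1, inter_site_lag = 1L,
                            noise_sd = 1, seed = 1L) {
  protocol <- match.arg(protocol)
  if (!inherits(site_map, "site_map")) abort("site_map must be a site_map object")
  if (nrow(site_map) == 0L) abort("site map is empty")
  if (!is_scalar_num(road_noise_amp) || road_noise_amp < 0) {
    abort("road_noise_amp must be >= 0")
  }
  if (!is_scalar_num(decay_exponent) || decay_exponent <= 0) {
    abort("decay_exponent must be > 0")
  }
  if (!is_count(inter_site_lag)) abort("inter_site_lag must be a count")
  if (chorus_peak_hour < 5 || chorus_peak_hour > 8) {
    warn("chorus_peak_hour outside the dawn interval 05:00-08:00")
  }
  structure(
    list(
      site_map = site_map, protocol = protocol, window_s = window_s,
      pause_s = pause_s, days = as.integer(days), duration_h = duration_h,
      start = start, chorus_peak_hour = chorus_peak_hour,
      chorus_width_h = chorus_width_h, chorus_amp = chorus_amp,
      road_noise_amp = road_noise_amp, decay_exponent = decay_exponent,
      inter_site_lag = as.integer(inter_site_lag), noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "soundscape_spec"
  )
}

# Window start times for a spec. Continuous: windows of window_s seconds back
# to back for duration_h hours. Duty cycle: one window every
# (window_s + pause_s) seconds for `days` days.
window_times <- function(spec) {
  if (spec$protocol == "continuous") {
    n <- floor(spec$duration_h * 3600 / spec$window_s)
    spec$start + (seq_len(n) - 1) * spec$window_s
  } else {
    step <- spec$window_s + spec$pause_s
    n <- floor(spec$days * 86400 / step)
    spec$start + (seq_len(n) - 1) * step
  }
}

# Circadian dawn-chorus bump in [0, 1], circular in hour-of-day.
chorus_bump <- function(hour, peak, width) {
  dh <- (hour - peak + 12) %% 24 - 12
  exp(-0.5 * (dh / width)^2)
}

# Diel traffic intensity profile in [0, 1]: quiet at night, busy by day.
traffic_profile <- function(hour) {
  0.15 + 0.85 * stats::plogis((hour - 7) / 1.2) * stats::plogis((21 - hour) / 1.2)
}

# Latent drivers b (biophony) and a (anthrophony) for every (site, window).
gen_drivers <- function(spec) {
  times <- window_times(spec)
  w <- length(times)
  sm <- spec$site_map
  hour <- as.numeric(format(times, "%H", tz = "UTC")) +
    as.numeric(format(times, "%M", tz = "UTC")) / 60
  bump <- chorus_bump(hour, spec$chorus_peak_hour, spec$chorus_width_h)
  delay <- ifelse(sm$group == "internal", 0L, spec$inter_site_lag)
  max_d <- max(delay)
  d_road <- if (!is.null(attr(sm, "road"))) road_distance(sm) else rep(1e6, nrow(sm))
  atten <- (1 + d_road / 50)^(-spec$decay_exponent)
  withr::with_seed(child_seed(spec$seed, 101L), {
    # shared AR(1) chorus modulation, padded so delayed sites can look back
    innov <- rnorm(w + max_d, sd = 1)
    m <- as.numeric(stats::filter(innov, 0.7, method = "recursive"))
    purrr::map_dfr(seq_len(nrow(sm)), function(i) {
      mod <- stats::plogis(m[seq_len(w) + max_d - delay[i]])
      b <- spec$chorus_amp * bump * (0.4 + 1.2 * mod) +
        abs(rnorm(w, sd = 0.03 * spec$noise_sd))
      a <- spec$road_noise_amp * atten[i] * traffic_profile(hour) *
        (1 + 0.1 * rnorm(w))
      tibble(
        site_id = sm$site_id[i], window = seq_len(w), timestamp = times,
        b = b, a = pmax(a, 0)
      )
    })
  })
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate per-site eco-acoustic index time series
#'
#' Fast path of the generator: index values are synthesized directly from the
#' latent biophony/anthrophony drivers, bypassing audio synthesis. Every
#' index respects its declared range (`H`, `AEI`, `ZCR` in `[0,1]`; `NDSI`
#' in `[-1,1]`; `ACI`, `ADI`, `BI`, `DSC` non-negative).
#'
#' @param spec A [soundscape_spec()].
#' @return A tibble with columns `site_id`, `timestamp` and the eight index
#'   columns `H, ACI, ADI, AEI, NDSI, BI, DSC, ZCR`, ordered by site then
#'   time. The latent drivers are attached as attribute `"drivers"` and the
#'   protocol as attribute `"protocol"`.
#' @examples
#' sm <- river_park_sites()
#' im <- gen_index_series(soundscape_spec(sm, days = 1, seed = 3))
#' dplyr::count(im, site_id)
#' @export
gen_index_series <- function(spec) {
  if (!inherits(spec, "soundscape_spec")) abort("spec must be a soundscape_spec")
  drv <- gen_drivers(spec)
  n <- nrow(drv)
  withr::with_seed(child_seed(spec$seed, 202L), {
    b <- drv$b
    a <- drv$a
    tot <- b + a
    p_bio <- ifelse(tot > 0, b / tot, 0.5)
    mixing <- 4 * p_bio * (1 - p_bio) # maximal when biophony ~ anthrophony
    s <- spec$noise_sd
    out <- drv[c("site_id", "timestamp")]
    out$H <- clamp01(0.30 + 0.35 * mixing + 0.25 * (1 - exp(-tot)) +
      rnorm(n, sd = 0.04 * s))
    out$ACI <- pmax(120 + 45 * b + rnorm(n, sd = 6 * s), 0)
    adi <- 1.2 + 0.9 * mixing + 0.5 * log1p(tot) + rnorm(n, sd = 0.08 * s)
    out$ADI <- pmin(pmax(adi, 0), log(10))
    out$AEI <- clamp01(1 - out$ADI / log(10) + rnorm(n, sd = 0.02 * s))
    out$NDSI <- pmin(pmax((b - a) / (tot + 0.2) + rnorm(n, sd = 0.05 * s), -1), 1)
    out$BI <- pmax(2.0 * b + 0.6 * (0.25 * a) + rnorm(n, sd = 0.12 * s), 0)
    out$DSC <- pmin(pmax(1000 + 4500 * p_bio + rnorm(n, sd = 150 * s), 0), 24000)
    out$ZCR <- clamp01(2 * out$DSC / 48000 + rnorm(n, sd = 0.01 * s))
  })
  structure(as_tibble(out),
    drivers = drv, protocol = spec$protocol, spec = spec
  )
}

#' Synthesize one 1-minute audio segment
#'
#' Audio path of the generator, for end-to-end testing of the index engine:
#' Poisson-arriving frequency-modulated chirps confined to the biophony band
#' (2-8 kHz) at a rate proportional to the biophony driver, plus colored
#' (low-passed, red-weighted) noise below 2 kHz with amplitude proportional
#' to the traffic driver. Peak amplitude never exceeds full scale.
#'
#' @param spec A [soundscape_spec()].
#' @param site_id Site to synthesize.
#' @param window Window number within the deployment timeline.
#' @param b,a Optional explicit driver values overriding the generated ones.
#' @param duration_s Segment length in seconds (default `spec$window_s`).
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @return A list with `samples`, `sample_rate`, `site_id`, `start_time`.
#' @export
gen_audio_segment <- function(spec, site_id, window = 1L, b = NULL, a = NULL,
                              duration_s = spec$window_s,
                              sample_rate = 48000) {
  if (!inherits(spec, "soundscape_spec")) abort("spec must be a soundscape_spec")
  sm <- spec$site_map
  if (!as.character(site_id) %in% sm$site_id) abort("unknown site_id")
  start_time <- window_times(spec)[window]
  if (is.null(b) || is.null(a)) {
    drv <- gen_drivers(spec)
    row <- drv[drv$site_id == as.character(site_id) & drv$window == window, ]
    if (nrow(row) == 0L) abort("window outside the deployment timeline")
    b <- b %||% row$b
    a <- a %||% row$a
  }
  n <- round(duration_s * sample_rate)
  site_pos <- match(as.character(site_id), sm$site_id)
  seg_seed <- child_seed(spec$seed, 1000L + site_pos * 10000L + window)
  withr::with_seed(seg_seed, {
    x <- numeric(n)
    # biophony: FM chirps in 2-8 kHz, Poisson arrivals at rate proportional
    # to the driver (b = 0 means no chirps at all)
    n_chirps <- rpois(1, lambda = 8 * b * duration_s)
    if (n_chirps > 0) {
      for (k in seq_len(n_chirps)) {
        dur <- runif(1, 0.08, 0.25)
        len <- round(dur * sample_rate)
        t0 <- sample.int(max(n - len, 1L), 1L)
        f0 <- runif(1, 2000, 7000)
        f1 <- min(max(f0 + runif(1, -1500, 1500), 2000), 8000)
        tt <- seq_len(len) / sample_rate
        inst_f <- f0 + (f1 - f0) * tt / dur
        env <- sin(pi * tt / dur)^2
        chirp <- 0.08 * env * sin(2 * pi * cumsum(inst_f) / sample_rate)
        idx <- t0:(t0 + len - 1L)
        x[idx] <- x[idx] + chirp
      }
    }
    # anthrophony: red-weighted noise low-passed below 2 kHz
    if (a > 0) {
      white <- rnorm(n)
      spec_w <- fft(white)
      freqs <- (seq_len(n) - 1) / n * sample_rate
      freqs <- pmin(freqs, sample_rate - freqs) # two-sided
      gain <- ifelse(freqs < 2000, 1 / (1 + freqs / 200), 0)
      red <- Re(fft(spec_w * gain, inverse = TRUE)) / n
      red <- red / max(sd(red), 1e-12)
      x <- x + 0.12 * a * red
    }
  })
  peak <- max(abs(x), 0)
  if (peak > 1) x <- x / peak
  list(
    samples = x, sample_rate = sample_rate,
    site_id = as.character(site_id), start_time = start_time
  )
}

#' Generate aural-survey labels from the latent drivers
#'
#' Emulates an expert aural survey: each (site, window) recording is labeled
#' with the closed vocabulary used in listening campaigns (birds singing
#' none/few/many; bird species none/<=2/>2; singing-activity quartile band;
#' traffic characteristics none/continuous/intermittent; traffic intensity
#' none/low/high; other sources none/presence), by thresholding the biophony
#' and anthrophony drivers attached to a generated index matrix.
#'
#' @param index_matrix Output of [gen_index_series()] (its `"drivers"`
#'   attribute is used).
#' @param thresholds Named list of cutpoints on the drivers:
#'   `birds_few`/`birds_many` on biophony, `traffic_low`/`traffic_high` on
#'   anthrophony.
#' @return A tibble with one labeled row per (site, window).
#' @export
gen_survey_labels <- function(index_matrix,
                              thresholds = list(
                                birds_few = 0.25, birds_many = 0.8,
                                traffic_low = 0.1, traffic_high = 0.45
                              )) {
  drv <- attr(index_matrix, "drivers")
  if (is.null(drv)) abort("index_matrix carries no drivers; generate it with gen_index_series()")
  th <- thresholds
  b <- drv$b
  a <- drv$a
  birds <- cut(b, c(-Inf, th$birds_few, th$birds_many, Inf),
    labels = c("none", "few", "many"), right = TRUE
  )
  activity <- clamp01(b / (th$birds_many * 1.25)) * 100
  act_band <- cut(activity, c(-1e-9, 0, 25, 50, 75, 100),
    labels = c("0", "(0,25]", "(25,50]", "(50,75]", "(75,100]"),
    right = TRUE
  )
  traffic_int <- cut(a, c(-Inf, th$traffic_low, th$traffic_high, Inf),
    labels = c("none", "low", "high"), right = TRUE
  )
  tibble(
    site_id = drv$site_id,
    timestamp = drv$timestamp,
    birds_singing = as.character(birds),
    bird_species = c(none = "none", few = "<=2", many = ">2")[as.character(birds)],
    singing_activity = as.character(act_band),
    traffic_characteristics = ifelse(a <= th$traffic_low, "none",
      ifelse(a > th$traffic_high, "continuous", "intermittent")
    ),
    traffic_intensity = as.character(traffic_int),
    other_sources = "none"
  )
}
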