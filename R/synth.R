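# Synthetic multichannel generator: band-limited common-source mixtures with
# implanted, timestamped connectivity-drop events, so the whole pipeline is
# testable without external recordings.

#' Synthetic recording specification
#'
#' Channels are mixtures `c_i(t) = a_i(t) s(t) + sqrt(1 - a_i(t)^2) eta_i(t)`
#' of one shared band-limited source `s` and independent band-limited noises
#' `eta_i` (all unit variance, filtered to `carrier_band_hz`), scaled by
#' `noise_sd`. At baseline every channel couples to the source with shared
#' variance fraction `coupling_base` (`a = sqrt(coupling_base)`). During an
#' event, a randomly drawn subset of `ceiling(event_channel_frac *
#' n_channels)` channels ramps (1 s raised-cosine-free linear ramps) down to
#' `coupling_drop` while the rest stay at baseline; the resulting three-level
#' edge-weight pattern is a deterministic heterogeneous-network event that
#' produces a network-entropy valley. Events are listed at their centre
#' times.
#'
#' Optional `artifact_times_s` injects short high-amplitude bursts (amplitude
#' `artifact_amplitude` times the signal scale, duration 0.2 s) to exercise
#' the artifact-thresholding preprocessor.
#'
#' @param n_channels number of channels (default 19, a 10-20 montage).
#' @param fs sampling rate in Hz (default 300).
#' @param duration_s recording length in seconds (default 600).
#' @param event_times_s event centre times (default six events uniformly
#'   spaced, `seq(55, 530, by = 95)`).
#' @param event_duration_s event length in seconds (default 8).
#' @param coupling_base baseline shared-variance fraction in (0, 1]
#'   (default 0.7).
#' @param coupling_drop in-event shared-variance fraction of affected
#'   channels, in `[0, coupling_base)` (default 0.1).
#' @param event_channel_frac fraction of channels affected per event
#'   (default 0.5).
#' @param noise_sd overall amplitude scale (default 1).
#' @param carrier_band_hz band of the carriers in Hz (default
#'   `c(18.75, 37.5)`).
#' @param artifact_times_s optional burst centre times.
#' @param artifact_amplitude burst amplitude multiplier (default 20).
#' @param seed integer seed; identical seeds give identical recordings.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 19L, fs = 300, duration_s = 600,
                       event_times_s = seq(55, 530, by = 95),
                       event_duration_s = 8,
                       coupling_base = 0.7, coupling_drop = 0.1,
                       event_channel_frac = 0.5,
                       noise_sd = 1, carrier_band_hz = c(18.75, 37.5),
                       artifact_times_s = NULL, artifact_amplitude = 20,
                       seed = NULL) {
  stopifnot(n_channels >= 2L, fs > 0, duration_s > 0,
            coupling_base > 0, coupling_base <= 1,
            coupling_drop >= 0, coupling_drop < coupling_base,
            event_channel_frac > 0, event_channel_frac <= 1,
            noise_sd > 0, event_duration_s > 0)
  event_times_s <- sort(as.numeric(event_times_s))
  window_s <- 10  # one analysis window at default settings
  half <- event_duration_s / 2
  if (length(event_times_s)) {
    if (any(event_times_s - half < window_s) ||
        any(event_times_s + half > duration_s - window_s)) {
      stop("events must fit inside the recording with a margin of one analysis window")
    }
    if (any(diff(event_times_s) < event_duration_s)) stop("overlapping events")
  }
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         duration_s = duration_s, event_times_s = event_times_s,
         event_duration_s = event_duration_s, coupling_base = coupling_base,
         coupling_drop = coupling_drop,
         event_channel_frac = event_channel_frac, noise_sd = noise_sd,
         carrier_band_hz = carrier_band_hz,
         artifact_times_s = artifact_times_s,
         artifact_amplitude = artifact_amplitude, seed = seed),
    class = "synth_spec"
  )
}

# Brick-wall FFT bandpass of white Gaussian noise, unit variance.
band_limited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  fr <- (0:(n - 1)) / n * fs
  keep <- (fr >= band[1] & fr <= band[2]) |
    ((fs - fr) >= band[1] & (fs - fr) <= band[2])
  y <- Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a synthetic recording with implanted events
#'
#' @param spec a [synth_spec()].
#' @return list with `recording` (an [eeg_recording()]) and `events` (an
#'   [event_table()] of the implanted event centres, source `"objective"`).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
  }
  n <- round(spec$fs * spec$duration_s)
  t <- (0:(n - 1)) / spec$fs
  s <- band_limited_noise(n, spec$fs, spec$carrier_band_hz)
  # per-channel shared-variance profile a_i(t)^2
  a2 <- matrix(spec$coupling_base, nrow = spec$n_channels, ncol = n)
  ramp <- 1  # seconds
  half <- spec$event_duration_s / 2
  for (c0 in spec$event_times_s) {
    n_aff <- ceiling(spec$event_channel_frac * spec$n_channels)
    affected <- sample(spec$n_channels, n_aff)
    shape <- numeric(n)
    up <- t >= c0 - half & t < c0 - half + ramp
    dn <- t > c0 + half - ramp & t <= c0 + half
    mid <- t >= c0 - half + ramp & t <= c0 + half - ramp
    shape[mid] <- 1
    shape[up] <- (t[up] - (c0 - half)) / ramp
    shape[dn] <- 1 - (t[dn] - (c0 + half - ramp)) / ramp
    prof <- spec$coupling_base + (spec$coupling_drop - spec$coupling_base) * shape
    a2[affected, ] <- pmin(a2[affected, , drop = FALSE],
                           matrix(prof, n_aff, n, byrow = TRUE))
  }
  a <- sqrt(a2)
  data <- matrix(0, nrow = spec$n_channels, ncol = n)
  for (i in seq_len(spec$n_channels)) {
    eta <- band_limited_noise(n, spec$fs, spec$carrier_band_hz)
    data[i, ] <- spec$noise_sd * (a[i, ] * s + sqrt(1 - a2[i, ]) * eta)
  }
  if (!is.null(spec$artifact_times_s)) {
    burst_len <- max(1L, round(0.2 * spec$fs))
    for (b0 in spec$artifact_times_s) {
      i0 <- round(b0 * spec$fs)
      idx <- (i0 + 1L):min(i0 + burst_len, n)
      ch <- sample(spec$n_channels, 1L)
      data[ch, idx] <- data[ch, idx] +
        spec$artifact_amplitude * spec$noise_sd *
          sin(2 * pi * 25 * t[idx])
    }
  }
  rec <- eeg_recording(data, fs = spec$fs)
  ev <- event_table(spec$event_times_s,
                    label = rep("coupling_drop", length(spec$event_times_s)),
                    source = rep("objective", length(spec$event_times_s)))
  list(recording = rec, events = ev)
}
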