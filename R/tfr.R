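# Time-frequency representation of the network-entropy series: a Meyer
# ("dmey") wavelet scalogram on a geometric grid of 1024 scales spanning the
# 0-0.5 Hz analysis band.

#' Scale to pseudo-frequency
#'
#' Standard scale/frequency map `f = fc / (scale * dt)`: scale 1 corresponds
#' to the wavelet's centre frequency at the series' sampling rate, and
#' frequency is inversely proportional to scale.
#'
#' @param scale positive scale (samples).
#' @param wavelet_center_freq_hz wavelet centre frequency in cycles per
#'   sample (see [wavelet_center_frequency()]).
#' @param dt_s sampling interval of the analysed series in seconds.
#' @return pseudo-frequency in Hz.
#' @export
scale_to_frequency <- function(scale, wavelet_center_freq_hz, dt_s) {
  if (any(scale <= 0) || dt_s <= 0 || wavelet_center_freq_hz <= 0) {
    stop("scale, centre frequency and dt must be positive")
  }
  wavelet_center_freq_hz / (scale * dt_s)
}

# Geometric pseudo-frequency grid: n points from f_max down to f_min.
scale_grid <- function(n, f_max, f_min) {
  stopifnot(f_min > 0, f_min < f_max)
  exp(seq(log(f_max), log(f_min), length.out = n))
}

#' Scalogram of a network-entropy series
#'
#' Continuous wavelet transform (real coefficients, see [cwt_spectral()]) of
#' the mean-removed NE series on a geometric grid of `cfg$n_scales`
#' pseudo-frequencies from `min(cfg$band_max_hz, fs_ne/2)` down to the lowest
#' frequency whose wavelet support (taken as 4 cycles) fits the record.
#' Power is the squared coefficient. A cone-of-influence vector (seconds to
#' the nearest record edge per epoch) is stored; periods longer than roughly
#' that distance are edge-affected.
#'
#' @param ne an [ne_series()].
#' @param cfg an [analysis_config()]; wavelet, scale count, band edges and
#'   DC handling are taken from it.
#' @return object of class `netent_scalogram`: list with `power`
#'   (n_scales x K), `freqs_hz` (decreasing), `scales`, `times_s`,
#'   `band_interest_hz`, `fs_ne`, `wavelet`, `coi_s`.
#' @export
ne_scalogram <- function(ne, cfg = analysis_config(1, sl_samples = 1)) {
  stopifnot(inherits(ne, "ne_series"))
  K <- length(ne$values)
  if (K < 16L) stop("NE series too short for a scalogram (need >= 16 epochs)")
  dt <- 1 / ne$fs_ne
  nyq <- ne$fs_ne / 2
  f_max <- min(cfg$band_max_hz, nyq)
  if (abs(cfg$band_max_hz - nyq) > 1e-9) {
    warning(sprintf(
      "configured band_max_hz (%g) differs from the NE Nyquist frequency (%g Hz); using %g Hz",
      cfg$band_max_hz, nyq, f_max
    ))
  }
  # lowest frequency whose wavelet support (~4 cycles) fits the record, but
  # never above half the band of interest so detection always has scales
  f_min <- min(4 / (K * dt), cfg$band_interest_hz[2] / 2)
  if (f_min >= f_max) f_min <- f_max / 4
  freqs <- scale_grid(cfg$n_scales, f_max, f_min)
  fc <- wavelet_center_frequency(cfg$wavelet_name)
  scales <- fc / (freqs * dt)
  x <- ne$values
  if (!cfg$keep_dc) x <- x - mean(x)
  if (all(x == 0)) {
    warning("constant NE series: scalogram power is identically zero")
    W <- matrix(0, nrow = length(scales), ncol = K)
  } else {
    W <- cwt_spectral(x, scales, wavelet = cfg$wavelet_name)
  }
  structure(
    list(power = W^2, freqs_hz = freqs, scales = scales,
         times_s = ne$epoch_times, band_interest_hz = cfg$band_interest_hz,
         fs_ne = ne$fs_ne, wavelet = cfg$wavelet_name,
         window_mult = cfg$window_mult,
         coi_s = pmin(ne$epoch_times - ne$epoch_times[1],
                      ne$epoch_times[K] - ne$epoch_times)),
    class = "netent_scalogram"
  )
}

#' @export
print.netent_scalogram <- function(x, ...) {
  cat(sprintf(
    "<netent_scalogram> %d scales x %d epochs, %s wavelet, %.4g-%.4g Hz, band of interest %g-%g Hz\n",
    nrow(x$power), ncol(x$power), x$wavelet,
    min(x$freqs_hz), max(x$freqs_hz),
    x$band_interest_hz[1], x$band_interest_hz[2]
  ))
  invisible(x)
}

#' Heatmap of a scalogram
#'
#' Quick base-graphics image of log power versus time and frequency, with
#' the band of interest marked.
#'
#' @param x a `netent_scalogram`.
#' @param ... passed to [graphics::image()].
#' @export
plot.netent_scalogram <- function(x, ...) {
  p <- log10(t(x$power) + 1e-300)
  graphics::image(x$times_s, rev(log10(x$freqs_hz)), p[, rev(seq_len(nrow(x$power)))],
                  xlab = "time (s)", ylab = "log10 frequency (Hz)",
                  main = "NE scalogram (log10 power)", ...)
  graphics::abline(h = log10(x$band_interest_hz[2]), lty = 2)
  invisible(x)
}
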