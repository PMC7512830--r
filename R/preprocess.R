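# Wavelet-domain preprocessing: select the 18.75-37.5 Hz dyadic detail band
# (at fs = 300 Hz) and suppress high-amplitude movement/muscle artifacts by
# zeroing outlying coefficients.

#' Wavelet band specification
#'
#' Describes the frequency band retained by [band_select()]. The band must be
#' a dyadic detail band of the sampling rate: `[fs/2^(d+1), fs/2^d]` for an
#' integer level `d`. For fs = 300 Hz and the default band 18.75-37.5 Hz,
#' `d = 3` (d1 = 75-150, d2 = 37.5-75, d3 = 18.75-37.5 Hz).
#'
#' @param fs sampling rate in Hz.
#' @param keep_band numeric pair, band edges in Hz (default
#'   `c(18.75, 37.5)`).
#' @param wavelet_name wavelet whose filter is used (default `"dmey"`).
#' @return object of class `wavelet_band_spec` with the resolved
#'   decomposition `level`.
#' @export
wavelet_band_spec <- function(fs, keep_band = c(18.75, 37.5),
                              wavelet_name = "dmey") {
  if (length(keep_band) != 2L || keep_band[1] >= keep_band[2]) {
    stop("keep_band must be an increasing pair")
  }
  if (keep_band[2] > fs / 2 + 1e-9) stop("keep_band exceeds the Nyquist frequency")
  d <- log2(fs / 2 / keep_band[2])
  lvl <- round(d) + 1L
  lo <- fs / 2^(lvl + 1L)
  hi <- fs / 2^lvl
  reltol <- function(a, b) abs(a - b) <= 1e-9 * max(abs(a), abs(b), 1)
  if (!(reltol(lo, keep_band[1]) && reltol(hi, keep_band[2]))) {
    stop(sprintf(
      "keep_band (%g, %g) Hz is not a dyadic detail band at fs = %g Hz (nearest: %g-%g Hz)",
      keep_band[1], keep_band[2], fs, lo, hi
    ))
  }
  structure(
    list(fs = fs, keep_band = keep_band, wavelet_name = wavelet_name,
         level = lvl),
    class = "wavelet_band_spec"
  )
}

# Decompose one channel to the spec's level and return the coefficient list.
band_decompose <- function(x, spec, h) {
  dwt(x, level = spec$level, h = h)
}

# Keep only the deepest detail subband (the spec's keep_band); zero the rest.
zero_other_subbands <- function(coefs, spec) {
  coefs$approx[] <- 0
  for (j in seq_along(coefs$detail)) {
    if (j != spec$level) coefs$detail[[j]][] <- 0
  }
  coefs
}

#' Wavelet band selection
#'
#' Per channel: multilevel DWT to the spec's level, zero every coefficient
#' subband except the detail band matching `keep_band`, reconstruct. Output
#' has the same shape and sampling rate as the input.
#'
#' @param rec an [eeg_recording()].
#' @param spec a [wavelet_band_spec()]; defaults to the 18.75-37.5 Hz band of
#'   the recording's sampling rate.
#' @return a band-limited [eeg_recording()].
#' @export
band_select <- function(rec, spec = wavelet_band_spec(rec$fs)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "wavelet_band_spec"))
  h <- if (identical(spec$wavelet_name, "dmey")) dmey_filter() else
    stop("unsupported wavelet for band selection: ", spec$wavelet_name)
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    coefs <- zero_other_subbands(band_decompose(rec$data[i, ], spec, h), spec)
    out[i, ] <- idwt(coefs)
  }
  eeg_recording(out, fs = rec$fs, channels = rec$channels, t0 = rec$t0)
}

#' Artifact suppression by coefficient thresholding
#'
#' Per channel, the retained-band wavelet coefficients C are computed and any
#' coefficient strictly greater than `mean(C) + k_sigma * sd(C)` (population
#' standard deviation) is set to zero; the rule is applied `n_passes` times
#' to the updated coefficient vector (zeros included in the next pass's mean
#' and sd), and the channel is reconstructed from the retained band only.
#' The default rule is one-sided on the signed coefficient values; set
#' `symmetric = TRUE` to threshold on `|C|` instead.
#'
#' Output energy never exceeds input energy (coefficients are only zeroed).
#'
#' @param rec an [eeg_recording()] (raw or already band-selected).
#' @param spec a [wavelet_band_spec()].
#' @param n_passes number of thresholding passes (default 2).
#' @param k_sigma threshold multiplier (default 2).
#' @param symmetric threshold on absolute values (default `FALSE`).
#' @return corrected [eeg_recording()], band-limited to `spec$keep_band`.
#' @export
threshold_correct <- function(rec, spec = wavelet_band_spec(rec$fs),
                              n_passes = 2L, k_sigma = 2,
                              symmetric = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "wavelet_band_spec"))
  if (n_passes < 1L) stop("n_passes must be >= 1")
  if (k_sigma <= 0) stop("k_sigma must be positive")
  h <- dmey_filter()
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    coefs <- zero_other_subbands(band_decompose(rec$data[i, ], spec, h), spec)
    C <- coefs$detail[[spec$level]]
    for (pass in seq_len(n_passes)) {
      C <- threshold_pass(C, k_sigma, symmetric)
    }
    coefs$detail[[spec$level]] <- C
    out[i, ] <- idwt(coefs)
  }
  eeg_recording(out, fs = rec$fs, channels = rec$channels, t0 = rec$t0)
}

# One pass of the outlier rule on a coefficient vector. Population sd; the
# comparison is strict, so constant vectors (sd 0) pass through unchanged.
threshold_pass <- function(C, k_sigma, symmetric) {
  m <- mean(C)
  s <- sqrt(mean((C - m)^2))
  thr <- m + k_sigma * s
  exceed <- if (symmetric) abs(C) > thr else C > thr
  C[exceed] <- 0
  C
}
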