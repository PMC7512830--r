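# Meyer-wavelet machinery: the FIR "dmey" filter, a periodised multilevel
# DWT/IDWT built on it, and a spectral continuous wavelet transform.
#
# The Meyer wavelet is defined in closed form in the frequency domain through
# the auxiliary polynomial nu(x) = x^4 (35 - 84 x + 70 x^2 - 20 x^3), which
# rises smoothly from 0 to 1 on [0, 1] with nu(x) + nu(1 - x) = 1.

meyer_nu <- function(x) {
  y <- numeric(length(x))
  y[x >= 1] <- 1
  i <- x > 0 & x < 1
  xi <- x[i]
  y[i] <- xi^4 * (35 - 84 * xi + 70 * xi^2 - 20 * xi^3)
  y
}

#' Meyer scaling function, frequency domain
#'
#' Fourier transform of the Meyer scaling function: 1 on |w| <= 2*pi/3,
#' a smooth cosine roll-off on 2*pi/3 < |w| <= 4*pi/3, 0 beyond.
#'
#' @param w angular frequency (radians per sample), any numeric vector.
#' @return values of the scaling function's Fourier transform, in [0, 1].
#' @keywords internal
meyer_phi_hat <- function(w) {
  aw <- abs(w)
  out <- numeric(length(w))
  out[aw <= 2 * pi / 3] <- 1
  i <- aw > 2 * pi / 3 & aw <= 4 * pi / 3
  out[i] <- cos(pi / 2 * meyer_nu(3 * aw[i] / (2 * pi) - 1))
  out
}

#' Meyer wavelet, frequency domain
#'
#' Zero-phase (real, even) form of the Meyer mother wavelet's Fourier
#' transform, supported on 2*pi/3 <= |w| <= 8*pi/3 with its single maximum
#' (value 1) at |w| = 4*pi/3. The corresponding time-domain wavelet is real,
#' symmetric about t = 0, and peaks there.
#'
#' @param w angular frequency (radians per sample).
#' @return values in [0, 1].
#' @export
meyer_psi_hat <- function(w) {
  aw <- abs(w)
  out <- numeric(length(w))
  i <- aw >= 2 * pi / 3 & aw <= 4 * pi / 3
  out[i] <- sin(pi / 2 * meyer_nu(3 * aw[i] / (2 * pi) - 1))
  i <- aw > 4 * pi / 3 & aw <= 8 * pi / 3
  out[i] <- cos(pi / 2 * meyer_nu(3 * aw[i] / (4 * pi) - 1))
  out
}

#' Morlet wavelet, frequency domain (real zero-phase form)
#'
#' Gaussian bump centred at the carrier frequency `omega0` (default 6),
#' applied symmetrically at +/- omega0. The admissibility correction term is
#' negligible at omega0 = 6 and omitted.
#'
#' @param w angular frequency (radians per sample).
#' @param omega0 carrier (dimensionless centre frequency), default 6.
#' @export
morlet_psi_hat <- function(w, omega0 = 6) {
  exp(-((abs(w) - omega0)^2) / 2)
}

# Resolve a wavelet name to its frequency-domain function.
wavelet_psi_hat <- function(wavelet) {
  switch(wavelet,
    dmey = ,
    meyer = meyer_psi_hat,
    morl = ,
    morlet = morlet_psi_hat,
    stop("unknown wavelet '", wavelet, "' (available: dmey, morl)")
  )
}

#' Centre frequency of a wavelet
#'
#' The peak of the wavelet's Fourier-transform modulus, in cycles per sample.
#' For the Meyer/dmey wavelet this is exactly (4*pi/3)/(2*pi) = 2/3; for the
#' Morlet it is omega0/(2*pi).
#'
#' @param wavelet wavelet name, `"dmey"` or `"morl"`.
#' @return centre frequency in cycles per sample.
#' @export
wavelet_center_frequency <- function(wavelet = "dmey") {
  switch(wavelet,
    dmey = ,
    meyer = 2 / 3,
    morl = ,
    morlet = 6 / (2 * pi),
    {
      psi <- wavelet_psi_hat(wavelet)
      w <- seq(1e-4, 3 * pi, length.out = 200000L)
      w[which.max(psi(w))] / (2 * pi)
    }
  )
}

#' Discrete Meyer ("dmey") filter
#'
#' FIR approximation of the Meyer conjugate-mirror lowpass filter, obtained by
#' sampling H(w) = sqrt(2) * phi_hat(2 w) on a fine frequency grid, inverse
#' transforming, and truncating to `n_taps` coefficients centred on the main
#' lobe. The result is renormalised so that sum(h) = sqrt(2).
#'
#' @param n_taps number of filter coefficients (default 62, the conventional
#'   dmey length).
#' @param n_grid frequency-grid size used for the construction.
#' @return numeric vector of `n_taps` lowpass coefficients.
#' @export
dmey_filter <- function(n_taps = 62L, n_grid = 8192L) {
  stopifnot(n_taps >= 8L, n_grid > 4L * n_taps)
  k <- 0:(n_grid - 1)
  w <- 2 * pi * k / n_grid
  w[w > pi] <- w[w > pi] - 2 * pi
  H <- sqrt(2) * meyer_phi_hat(2 * w)
  h <- Re(stats::fft(H, inverse = TRUE)) / n_grid
  half <- n_taps %/% 2
  idx <- c((n_grid - half + 1):n_grid, 1:(n_taps - half))
  hh <- h[idx]
  hh / sum(hh) * sqrt(2)
}

#' Quadrature mirror (highpass) filter
#'
#' Alternating-flip construction g[n] = (-1)^n h[L-1-n] for an orthogonal
#' filter bank.
#'
#' @param h lowpass filter coefficients.
#' @export
qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# Circular correlation y[k] = sum_n f[n] x[k+n] (mod N), via FFT.
circ_corr <- function(x, f) {
  N <- length(x)
  fp <- c(f, numeric(N - length(f)))
  Re(stats::fft(stats::fft(x) * Conj(stats::fft(fp)), inverse = TRUE)) / N
}

# Upsample-by-2 then circular convolution with f, output length N.
circ_conv_up <- function(coefs, f, N) {
  u <- numeric(N)
  u[seq(1, N, by = 2)] <- coefs
  fp <- c(f, numeric(N - length(f)))
  Re(stats::fft(stats::fft(u) * stats::fft(fp), inverse = TRUE)) / N
}

#' Periodised multilevel discrete wavelet transform
#'
#' Orthogonal analysis filter bank with circular boundary handling. The input
#' is zero-padded to the next multiple of `2^level`; the original length is
#' kept so [idwt()] can truncate the reconstruction.
#'
#' @param x numeric signal.
#' @param level decomposition depth.
#' @param h lowpass filter (default [dmey_filter()]).
#' @return list with `approx` (level-`level` approximation coefficients),
#'   `detail` (list of detail coefficient vectors, level 1 first), `n`
#'   (original signal length), and `filter`.
#' @export
dwt <- function(x, level, h = dmey_filter()) {
  stopifnot(level >= 1L, is.numeric(x))
  n <- length(x)
  block <- 2L^level
  if (n %% block != 0L) x <- c(x, numeric(block - n %% block))
  g <- qmf(h)
  a <- x
  detail <- vector("list", level)
  for (j in seq_len(level)) {
    N <- length(a)
    if (N < length(h)) {
      stop("signal too short for the wavelet filter at level ", j)
    }
    keep <- seq(1, N, by = 2)
    detail[[j]] <- circ_corr(a, g)[keep]
    a <- circ_corr(a, h)[keep]
  }
  list(approx = a, detail = detail, n = n, filter = h)
}

#' Inverse periodised multilevel DWT
#'
#' @param coefs a coefficient list as returned by [dwt()].
#' @return reconstructed signal, truncated to the original length.
#' @export
idwt <- function(coefs) {
  h <- coefs$filter
  g <- qmf(h)
  a <- coefs$approx
  for (j in rev(seq_along(coefs$detail))) {
    N <- 2L * length(a)
    a <- circ_conv_up(a, h, N) + circ_conv_up(coefs$detail[[j]], g, N)
  }
  a[seq_len(coefs$n)]
}

#' Spectral continuous wavelet transform
#'
#' Real-valued CWT computed scale by scale in the frequency domain: the
#' signal's FFT is multiplied by the zero-phase wavelet spectrum psi_hat(a*w)
#' (amplitude normalisation, no sqrt(a) factor) and inverse-transformed.
#' Amplitude normalisation makes the response of a pure tone peak exactly at
#' the scale whose pseudo-frequency equals the tone frequency.
#'
#' @param x numeric signal.
#' @param scales positive scales (in samples).
#' @param wavelet `"dmey"` (continuous Meyer) or `"morl"`.
#' @return real coefficient matrix, `length(scales)` rows by `length(x)`
#'   columns.
#' @export
cwt_spectral <- function(x, scales, wavelet = "dmey") {
  stopifnot(all(scales > 0), is.numeric(x))
  psi <- wavelet_psi_hat(wavelet)
  N <- length(x)
  X <- stats::fft(x)
  w <- 2 * pi * (0:(N - 1)) / N
  w[w > pi] <- w[w > pi] - 2 * pi
  out <- matrix(0, nrow = length(scales), ncol = N)
  for (i in seq_along(scales)) {
    out[i, ] <- Re(stats::fft(X * psi(scales[i] * w), inverse = TRUE)) / N
  }
  out
}
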