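# Sliding-window functional connectivity: equal-time cross-correlation
# matrices forming the FCGB (functional connectivity graph of the brain)
# sequence.

# Raw lagged cross-correlation sum CC(x, y)(tau) = sum_t x(t + tau) y(t) for
# tau >= 0, with the mirror rule CC(x, y)(-tau) = CC(y, x)(tau).
cc_lag <- function(x, y, tau = 0L) {
  n <- length(x)
  stopifnot(length(y) == n)
  tau <- as.integer(tau)
  if (tau < 0L) return(cc_lag(y, x, -tau))
  if (tau >= n) return(0)
  sum(x[(1L + tau):n] * y[1L:(n - tau)])
}

#' Pairwise connectivity weight
#'
#' Normalised absolute cross-correlation of two channel windows:
#' `|CC(x, y)(tau)| / sqrt(CC(x, x)(0) * CC(y, y)(0))`, where CC is the raw
#' (not mean-centred) lagged inner product. At the default `tau = 0` the
#' result lies in `[0, 1]` by Cauchy-Schwarz, with 1 meaning complete
#' correlation (or anti-correlation: the modulus folds the sign).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param tau integer lag (default 0, the equal-time case).
#' @param pearson if `TRUE`, remove each vector's mean first.
#' @return connectivity weight.
#' @export
crosscorr_pair <- function(x, y, tau = 0L, pearson = FALSE) {
  if (length(x) < 2L || length(y) != length(x)) {
    stop("x and y must have equal length >= 2")
  }
  if (isTRUE(pearson)) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  ex <- sum(x * x)
  ey <- sum(y * y)
  if (ex == 0 || ey == 0) stop("zero-energy signal: correlation undefined")
  abs(cc_lag(x, y, tau)) / sqrt(ex * ey)
}

#' Connectivity matrix of one window
#'
#' Builds the symmetric functional connectivity matrix of a window: entry
#' (i, j) is [crosscorr_pair()] of channels i and j at lag 0, and the
#' diagonal is forced to zero to exclude self-connections.
#'
#' @param window numeric matrix, channels in rows.
#' @param pearson mean-centre channels before correlating (default `FALSE`).
#' @return symmetric matrix with zero diagonal and off-diagonal values in
#'   `[0, 1]`.
#' @export
connectivity_matrix <- function(window, pearson = FALSE) {
  window <- as.matrix(window)
  if (ncol(window) < 2L) stop("window must contain at least 2 samples")
  if (isTRUE(pearson)) window <- window - rowMeans(window)
  cc <- tcrossprod(window)
  en <- diag(cc)
  if (any(en == 0)) {
    stop("zero-energy channel(s) in window: ",
         paste(which(en == 0), collapse = ", "))
  }
  g <- abs(cc) / sqrt(outer(en, en))
  diag(g) <- 0
  g
}

#' Build the FCGB sequence
#'
#' Slides a window of `window_mult * sl_samples` samples along the recording
#' in steps of `sl_samples` and computes one connectivity matrix per window
#' position (epoch). Epoch k covers samples `(k-1)*SL + 1 ... (k-1)*SL + L`
#' and is timestamped at its first sample, `(k-1)*SL/fs` seconds. Incomplete
#' tail windows are dropped.
#'
#' @param rec an [eeg_recording()].
#' @param cfg an [analysis_config()]; defaults to `analysis_config(rec$fs)`.
#' @return an object of class `fcgb_sequence`: a list with `values`
#'   (channels x channels x epochs array), `epoch_times` (seconds),
#'   `sl_samples`, `window_samples`, `fs`, `channels`.
#' @export
build_fcgb_sequence <- function(rec, cfg = analysis_config(rec$fs)) {
  stopifnot(inherits(rec, "eeg_recording"))
  sl <- cfg$sl_samples
  L <- cfg$window_samples
  n <- ncol(rec$data)
  if (n < L) stop("recording shorter than one analysis window (", L, " samples)")
  K <- (n - L) %/% sl + 1L
  nc <- nrow(rec$data)
  values <- array(0, dim = c(nc, nc, K))
  for (k in seq_len(K)) {
    i0 <- (k - 1L) * sl
    values[, , k] <- connectivity_matrix(rec$data[, (i0 + 1L):(i0 + L)],
                                         pearson = cfg$pearson)
  }
  structure(
    list(values = values,
         epoch_times = (seq_len(K) - 1) * sl / rec$fs,
         sl_samples = sl, window_samples = L, fs = rec$fs,
         channels = rec$channels),
    class = "fcgb_sequence"
  )
}

#' @export
print.fcgb_sequence <- function(x, ...) {
  K <- dim(x$values)[3]
  cat(sprintf(
    "<fcgb_sequence> %d epochs of %dx%d matrices, SL=%d, L=%d, fs=%g Hz (epochs %g..%g s)\n",
    K, dim(x$values)[1], dim(x$values)[2], x$sl_samples, x$window_samples,
    x$fs, x$epoch_times[1], x$epoch_times[K]
  ))
  invisible(x)
}
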