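# Network entropy: Shannon entropy (bits) of the normalised upper-triangular
# edge-weight sequence of one connectivity matrix, applied per epoch.

# Strict upper-triangular entries in row-major order: (1,2), (1,3), ...,
# (1,E), (2,3), ...  The order is irrelevant to the entropy (a symmetric
# function) but fixed so dumps are reproducible.
upper_tri_rowmajor <- function(m) {
  t(m)[lower.tri(m)]
}

#' Normalised edge-weight distribution of a connectivity matrix
#'
#' Extracts the strict upper-triangular weights (row-major) and normalises
#' them to sum to one, yielding the probability vector whose Shannon entropy
#' is the network entropy.
#'
#' @param f symmetric connectivity matrix with zero diagonal.
#' @return probability vector of length `E*(E-1)/2`.
#' @export
correlation_sequence <- function(f) {
  f <- as.matrix(f)
  g <- upper_tri_rowmajor(f)
  s <- sum(g)
  if (s <= 0) stop("degenerate graph: all upper-triangular weights are zero")
  p <- g / s
  # pin the sum to 1 exactly against accumulated rounding
  p[length(p)] <- max(0, 1 - sum(p[-length(p)]))
  p
}

#' Shannon entropy of a probability vector, in bits
#'
#' Computes `-sum(p * log2(p))` with the continuity convention
#' `0 * log2(0) = 0`. The result lies in `[0, log2(length(p))]`.
#'
#' @param p non-negative weights summing to 1 (tolerance 1e-9).
#' @return entropy in bits.
#' @export
network_entropy <- function(p) {
  if (any(p < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Network entropy series of an FCGB sequence
#'
#' Applies [correlation_sequence()] and [network_entropy()] to every epoch.
#'
#' @param seq an `fcgb_sequence` from [build_fcgb_sequence()].
#' @return an object of class `ne_series`: list with `values` (bits, one per
#'   epoch), `epoch_times` (seconds), `n_edges`, and `fs_ne` (the series'
#'   sampling rate, `fs / sl_samples` Hz).
#' @export
ne_series <- function(seq) {
  stopifnot(inherits(seq, "fcgb_sequence"))
  K <- dim(seq$values)[3]
  if (K < 1L) stop("empty FCGB sequence")
  E <- dim(seq$values)[1]
  vals <- vapply(seq_len(K), function(k) {
    p <- tryCatch(correlation_sequence(seq$values[, , k]),
                  error = function(e) stop("epoch ", k, ": ", conditionMessage(e),
                                           call. = FALSE))
    network_entropy(p)
  }, numeric(1))
  structure(
    list(values = vals, epoch_times = seq$epoch_times,
         n_edges = E * (E - 1L) / 2L, fs_ne = seq$fs / seq$sl_samples),
    class = "ne_series"
  )
}

#' @export
print.ne_series <- function(x, ...) {
  cat(sprintf(
    "<ne_series> %d epochs @ %g Hz, %d edges (max %0.4f bits), range %.4f..%.4f bits\n",
    length(x$values), x$fs_ne, x$n_edges, log2(x$n_edges),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
as.data.frame.ne_series <- function(x, ...) {
  data.frame(epoch_time_s = x$epoch_times, ne_bits = x$values)
}
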