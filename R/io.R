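# Readers/writers for EEG recordings (delimited matrix or EDF) and event
# tables, plus the container constructors used throughout the package.

#' EEG recording container
#'
#' A multichannel recording: a channels-by-samples numeric matrix (microvolts
#' by convention, though nothing depends on the unit), its sampling rate, and
#' ordered channel labels. All epoch and event times in the package are
#' seconds from the first sample (t = 0).
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel labels; defaults to the
#'   matrix rownames or `ch01, ch02, ...`.
#' @param t0 recording start offset in seconds (default 0).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = NULL, t0 = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (nrow(data) < 2L) stop("fewer than 2 channels")
  if (ncol(data) < 1L) stop("recording has no samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive number")
  if (is.null(channels)) {
    channels <- rownames(data)
    if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  channels <- as.character(channels)
  if (length(channels) != nrow(data)) stop("channels length must match the channel count")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  dimnames(data) <- list(channels, NULL)
  structure(
    list(data = data, fs = fs, channels = channels, t0 = t0),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("  channels:", paste(utils::head(x$channels, 8), collapse = ", "),
      if (length(x$channels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Read an EEG recording
#'
#' Reads either an EDF (European Data Format) file or a delimited numeric
#' matrix with channels in rows. The delimiter (comma or tab) is
#' auto-detected; a non-numeric first column is taken as channel labels.
#' Delimited files carry no sampling rate, so `fs_hint` is required for them.
#'
#' @param path file path.
#' @param fs_hint sampling rate in Hz (required for delimited input, ignored
#'   for EDF).
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path, fs_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_edf_file(path)) {
    return(read_edf(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  # row-oriented parse: recordings have few channel rows but very many
  # sample columns, which column-oriented readers handle poorly
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) stop("ragged rows in ", path)
  labels <- NULL
  first_num <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  if (anyNA(first_num)) {
    labels <- vapply(fields, `[`, "", 1L)
    fields <- lapply(fields, `[`, -1L)
  }
  m <- do.call(rbind, lapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("non-numeric cells in ", path)
    v
  }))
  if (nrow(m) < 2L) stop("fewer than 2 channels")
  if (is.null(fs_hint)) stop("fs_hint is required for delimited input")
  eeg_recording(m, fs = fs_hint, channels = labels)
}

#' Write an EEG recording as delimited text
#'
#' Channels in rows, first column the channel label. Comma-separated by
#' default; [read_eeg()] reads the result back.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_eeg_csv <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "eeg_recording"))
  lines <- vapply(seq_len(nrow(rec$data)), function(i) {
    paste(c(rec$channels[i],
            format(rec$data[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = sep)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Event table
#'
#' Timestamped events: time in seconds from the recording start, a free-text
#' label, and whether the event was self-reported (`subjective`) or observed
#' (`objective`). Rows are kept sorted by time.
#'
#' @param time_s numeric, non-negative times in seconds.
#' @param label character labels.
#' @param source `"subjective"` or `"objective"`, recycled if length 1.
#' @return a data.frame of class `event_table` with columns `time_s`,
#'   `label`, `source`.
#' @export
event_table <- function(time_s = numeric(), label = character(),
                        source = character()) {
  time_s <- as.numeric(time_s)
  label <- as.character(label)
  source <- as.character(source)
  if (length(source) == 1L && length(time_s) > 1L) {
    source <- rep(source, length(time_s))
  }
  if (length(label) != length(time_s) || length(source) != length(time_s)) {
    stop("time_s, label and source must have equal length")
  }
  if (any(is.na(time_s)) || any(time_s < 0)) stop("event times must be non-negative")
  bad <- setdiff(unique(source), c("subjective", "objective"))
  if (length(bad)) stop("unknown event source value(s): ", paste(bad, collapse = ", "))
  ord <- order(time_s)
  structure(
    data.frame(time_s = time_s[ord], label = label[ord], source = source[ord],
               stringsAsFactors = FALSE),
    class = c("event_table", "data.frame")
  )
}

#' Read an event table from TSV
#'
#' Expects a header line with columns `time_s`, `label`, `source`.
#'
#' @param path file path.
#' @return an [event_table()], sorted by time.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_s", "label", "source")
  if (!all(need %in% names(tab))) {
    stop("event file must have columns: ", paste(need, collapse = ", "))
  }
  event_table(tab$time_s, tab$label, tab$source)
}

#' Write an event table as TSV
#'
#' @param events an [event_table()].
#' @param path output path.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. The window shift SL
#' defaults to one second of samples (`fs` rounded), and the window length is
#' `window_mult * sl_samples`, i.e. ten seconds under defaults, so the
#' network-entropy series is sampled at 1 Hz.
#'
#' @param fs sampling rate of the recording in Hz (used for the SL default
#'   and for time bookkeeping).
#' @param sl_samples window shift in samples (default `round(fs)`, one
#'   second).
#' @param window_mult window length as a multiple of `sl_samples` (default
#'   10).
#' @param binarize_step initial threshold decrement for the
#'   connectedness-based binarisation (default 0.01).
#' @param binarize_min_step smallest decrement tried before giving up
#'   (default 1e-4).
#' @param wavelet_name mother wavelet for the entropy-series scalogram
#'   (default `"dmey"`).
#' @param n_scales number of CWT scales (default 1024).
#' @param band_max_hz upper edge of the analysed band of the entropy series
#'   (default 0.5 Hz, the Nyquist frequency of a 1 Hz series).
#' @param band_interest_hz frequency band used for event detection (default
#'   `c(0, 0.1)` Hz).
#' @param detect_percentile envelope percentile for high-power detection
#'   (default 95).
#' @param pearson if `TRUE`, use mean-centred (Pearson) correlations instead
#'   of the raw normalised inner product (default `FALSE`).
#' @param keep_dc if `TRUE`, skip mean removal before the CWT (default
#'   `FALSE`).
#' @param seed optional integer seed recorded in the config.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(fs,
                            sl_samples = round(fs),
                            window_mult = 10L,
                            binarize_step = 0.01,
                            binarize_min_step = 1e-4,
                            wavelet_name = "dmey",
                            n_scales = 1024L,
                            band_max_hz = 0.5,
                            band_interest_hz = c(0, 0.1),
                            detect_percentile = 95,
                            pearson = FALSE,
                            keep_dc = FALSE,
                            seed = NULL) {
  sl_samples <- as.integer(sl_samples)
  window_mult <- as.integer(window_mult)
  if (sl_samples < 1L) stop("sl_samples must be >= 1")
  if (window_mult < 1L) stop("window_mult must be >= 1")
  if (!(binarize_min_step > 0 && binarize_min_step <= binarize_step &&
        binarize_step <= 1)) {
    stop("need 0 < binarize_min_step <= binarize_step <= 1")
  }
  if (!(detect_percentile > 0 && detect_percentile < 100)) {
    stop("detect_percentile must lie in (0, 100)")
  }
  if (length(band_interest_hz) != 2L || band_interest_hz[1] > band_interest_hz[2]) {
    stop("band_interest_hz must be an increasing pair")
  }
  structure(
    list(fs = fs, sl_samples = sl_samples, window_mult = window_mult,
         window_samples = window_mult * sl_samples,
         binarize_step = binarize_step, binarize_min_step = binarize_min_step,
         wavelet_name = wavelet_name, n_scales = as.integer(n_scales),
         band_max_hz = band_max_hz, band_interest_hz = band_interest_hz,
         detect_percentile = detect_percentile,
         pearson = isTRUE(pearson), keep_dc = isTRUE(keep_dc), seed = seed),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(
    "<analysis_config> SL=%d samples, L=%d (x%d), wavelet=%s, %d scales, band of interest %g-%g Hz, detect %gth pct\n",
    x$sl_samples, x$window_samples, x$window_mult, x$wavelet_name,
    x$n_scales, x$band_interest_hz[1], x$band_interest_hz[2],
    x$detect_percentile
  ))
  invisible(x)
}
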