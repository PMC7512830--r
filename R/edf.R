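# Minimal EDF (European Data Format) support: ASCII header blocks of 256
# bytes, then per-record interleaved 16-bit little-endian integers with a
# linear digital->physical calibration per signal.

is_edf_file <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  # EDF version field: "0       " in ASCII
  length(magic) == 8L && rawToChar(magic) == "0       "
}

read_ascii <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n = n)))
}

#' Read an EDF file
#'
#' Supports continuous EDF with one common sampling rate across signals;
#' mixed per-signal rates are rejected.
#'
#' @param path file path.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8L)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  invisible(readBin(con, "raw", n = 80L + 80L + 8L + 8L))  # patient, recording, date, time
  header_bytes <- as.integer(read_ascii(con, 8L))
  invisible(readBin(con, "raw", n = 44L))                  # reserved
  n_records <- as.integer(read_ascii(con, 8L))
  record_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (ns < 1L) stop("EDF file declares no signals")
  field <- function(width) {
    vapply(seq_len(ns), function(i) read_ascii(con, width), character(1))
  }
  labels <- field(16L)
  invisible(field(80L))                                    # transducer
  invisible(field(8L))                                     # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  invisible(field(80L))                                    # prefiltering
  spr <- as.integer(field(8L))                             # samples per record
  invisible(field(32L))                                    # reserved
  if (length(unique(spr)) != 1L) {
    stop("EDF with mixed per-channel sampling rates is not supported")
  }
  fs <- spr[1L] / record_dur
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1L])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L,
                     signed = TRUE, endian = "little")
      gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (dig - dig_min[s]) * gain + phys_min[s]
    }
  }
  eeg_recording(data, fs = fs, channels = make.unique(labels))
}

#' Write an EDF file
#'
#' Writes a continuous EDF with one data record per second (or one record
#' covering everything when the duration is below a second). Values are
#' quantised to 16 bits over `phys_range`; with the default range the
#' quantisation error is at most range/65534. For a lossless round trip of
#' integer-valued data pass `phys_range = c(-32768, 32767)`.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param phys_range physical min/max used for calibration (default: data
#'   range, symmetrised).
#' @export
write_edf <- function(rec, path, phys_range = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  if (is.null(phys_range)) {
    m <- max(abs(range(rec$data)), 1e-12)
    phys_range <- c(-m, m)
  }
  dig_min <- -32768
  dig_max <- 32767
  # one-second records when possible
  spr <- if (rec$fs == round(rec$fs) && ncol(rec$data) %% rec$fs == 0) {
    as.integer(rec$fs)
  } else {
    ncol(rec$data)
  }
  record_dur <- spr / rec$fs
  n_records <- ncol(rec$data) %/% spr
  pad <- function(x, width) {
    x <- as.character(x)
    if (nchar(x) > width) x <- substr(x, 1L, width)
    formatC(x, width = width, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X", 80), pad("X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256L * (1L + ns), 8), pad("", 44),
    pad(n_records, 8), pad(format(record_dur, digits = 8), 8), pad(ns, 4)
  ), con, eos = NULL)
  wf <- function(vals, width) {
    for (v in vals) writeChar(pad(v, width), con, eos = NULL)
  }
  wf(rec$channels, 16)
  wf(rep("", ns), 80)
  wf(rep("uV", ns), 8)
  wf(rep(format(phys_range[1], digits = 8), ns), 8)
  wf(rep(format(phys_range[2], digits = 8), ns), 8)
  wf(rep(dig_min, ns), 8)
  wf(rep(dig_max, ns), 8)
  wf(rep("", ns), 80)
  wf(rep(spr, ns), 8)
  wf(rep("", ns), 32)
  gain <- (phys_range[2] - phys_range[1]) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- rec$data[s, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- round((x - phys_range[1]) / gain + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
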