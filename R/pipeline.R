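# End-to-end pipeline: (optional) preprocessing, FCGB construction, network
# entropy, scalogram, high-power region detection, event matching, optional
# classical metrics; plus result writers.

#' Run the full network-entropy analysis
#'
#' @param rec an [eeg_recording()].
#' @param events optional [event_table()] of recorded events to match
#'   against.
#' @param cfg an [analysis_config()]; defaults to `analysis_config(rec$fs)`.
#' @param preprocess apply [threshold_correct()] (band selection plus
#'   artifact thresholding) before the analysis (default `TRUE`).
#' @param metrics also compute the per-epoch classical graph metrics
#'   (default `FALSE`; the threshold search over every epoch is the slow
#'   part of the pipeline).
#' @return object of class `netent_result`: list with `ne` ([ne_series()]),
#'   `scalogram`, `regions`, `matches` (a `match_result` or `NULL`),
#'   `metrics` (data.frame or `NULL`), `cfg`.
#' @export
run_netent <- function(rec, events = NULL, cfg = analysis_config(rec$fs),
                       preprocess = TRUE, metrics = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (isTRUE(preprocess)) {
    rec <- threshold_correct(rec, wavelet_band_spec(rec$fs))
  }
  fcgb <- build_fcgb_sequence(rec, cfg)
  ne <- ne_series(fcgb)
  sc <- ne_scalogram(ne, cfg)
  regions <- detect_high_power_regions(sc, percentile = cfg$detect_percentile)
  matches <- if (!is.null(events)) match_events(regions, events) else NULL
  met <- if (isTRUE(metrics)) {
    metrics_series(fcgb, cfg$binarize_step, cfg$binarize_min_step)
  } else NULL
  structure(
    list(ne = ne, scalogram = sc, regions = regions, matches = matches,
         metrics = met, cfg = cfg),
    class = "netent_result"
  )
}

#' @export
print.netent_result <- function(x, ...) {
  cat("<netent_result>\n")
  print(x$ne)
  print(x$scalogram)
  cat(sprintf("  %d high-power regions\n", nrow(x$regions)))
  if (!is.null(x$matches)) print(x$matches)
  invisible(x)
}

#' Write analysis results to a directory
#'
#' Writes `ne_series.csv` (epoch_time_s, ne_bits), `regions.csv`,
#' `matches.csv` and `summary.json` (when events were matched),
#' `metrics.csv` (when metrics were computed), `scalogram_axes.csv`
#' (scale, freq_hz) and, optionally, the full power matrix as
#' `scalogram_power.csv` (scales in rows - this file is large).
#'
#' @param res a `netent_result`.
#' @param dir output directory, created if needed.
#' @param scalogram write the full power matrix (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir, scalogram = FALSE) {
  stopifnot(inherits(res, "netent_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(res$ne),
                   file.path(dir, "ne_series.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$regions),
                   file.path(dir, "regions.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(scale = res$scalogram$scales, freq_hz = res$scalogram$freqs_hz),
    file.path(dir, "scalogram_axes.csv"), row.names = FALSE
  )
  if (isTRUE(scalogram)) {
    utils::write.table(res$scalogram$power,
                       file.path(dir, "scalogram_power.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(res$metrics)) {
    utils::write.csv(res$metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$matches)) {
    utils::write.csv(res$matches$matches, file.path(dir, "matches.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$matches$summary,
                         file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
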