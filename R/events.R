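# Event localisation: collapse scalogram power over the band of interest to
# a temporal envelope, threshold it at a percentile, extract supra-threshold
# runs as high-power regions, and match recorded events to the nearest
# region centerline.

#' Detect high-power regions in a scalogram
#'
#' The power is averaged over the scales whose pseudo-frequency falls in the
#' band of interest, yielding a 1-D envelope e(t). Epochs where e strictly
#' exceeds its `percentile`-th percentile are marked; maximal marked runs
#' become regions, after merging runs separated by fewer than
#' `merge_gap_epochs` epochs (default: one analysis window, the method's
#' temporal resolution - each NE sample integrates a full window, so closer
#' excursions are not resolvable as distinct events). The region's
#' centerline is the power-weighted temporal centroid of its span (or the
#' geometric midpoint with `centerline = "midpoint"`).
#'
#' @param sc a `netent_scalogram`.
#' @param percentile envelope percentile in (0, 100) (default 95).
#' @param band frequency band collapsed over, Hz (default: the scalogram's
#'   band of interest; pass `c(0, Inf)` for full-band collapse).
#' @param merge_gap_epochs runs closer than this many epochs are merged
#'   (default: the scalogram's window multiple, 10 under default analysis
#'   settings).
#' @param centerline `"centroid"` (default) or `"midpoint"`.
#' @return data.frame of class `high_power_regions` with columns
#'   `region_id`, `t_start_s`, `t_end_s`, `centerline_s`, `peak_power`,
#'   `band_lo_hz`, `band_hi_hz`, sorted by time; the envelope and threshold
#'   are attached as attributes `envelope` and `threshold`.
#' @export
detect_high_power_regions <- function(sc, percentile = 95, band = NULL,
                                      merge_gap_epochs = NULL,
                                      centerline = c("centroid", "midpoint")) {
  stopifnot(inherits(sc, "netent_scalogram"))
  centerline <- match.arg(centerline)
  if (is.null(band)) band <- sc$band_interest_hz
  if (is.null(merge_gap_epochs)) {
    merge_gap_epochs <- if (!is.null(sc$window_mult)) sc$window_mult else 10L
  }
  in_band <- sc$freqs_hz >= band[1] & sc$freqs_hz <= band[2]
  if (!any(in_band)) stop("no scales fall inside the requested band")
  env <- colMeans(sc$power[in_band, , drop = FALSE])
  thr <- stats::quantile(env, percentile / 100, names = FALSE, type = 7)
  above <- env > thr
  times <- sc$times_s
  empty <- data.frame(region_id = integer(), t_start_s = numeric(),
                      t_end_s = numeric(), centerline_s = numeric(),
                      peak_power = numeric(), band_lo_hz = numeric(),
                      band_hi_hz = numeric())
  if (!any(above)) {
    return(structure(empty, class = c("high_power_regions", "data.frame"),
                     envelope = env, threshold = thr))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ss <- starts[r$values]
  ee <- ends[r$values]
  if (length(ss) > 1L) {
    ms <- ss[1L]; me <- ee[1L]; os <- integer(); oe <- integer()
    for (i in seq_along(ss)[-1L]) {
      if (ss[i] - me - 1L < merge_gap_epochs) {
        me <- ee[i]
      } else {
        os <- c(os, ms); oe <- c(oe, me)
        ms <- ss[i]; me <- ee[i]
      }
    }
    ss <- c(os, ms); ee <- c(oe, me)
  }
  ctr <- mapply(function(s, e) {
    w <- env[s:e]
    if (centerline == "midpoint") (times[s] + times[e]) / 2
    else sum(times[s:e] * w) / sum(w)
  }, ss, ee)
  out <- data.frame(
    region_id = seq_along(ss),
    t_start_s = times[ss], t_end_s = times[ee], centerline_s = ctr,
    peak_power = mapply(function(s, e) max(env[s:e]), ss, ee),
    band_lo_hz = band[1], band_hi_hz = band[2]
  )
  structure(out[order(out$t_start_s), ],
            class = c("high_power_regions", "data.frame"),
            envelope = env, threshold = thr)
}

#' Match recorded events to detected regions
#'
#' Every recorded event is paired with the region whose centerline is
#' nearest in absolute time (ties resolved to the earlier region, regions
#' may serve several events). The signed time error uses the extracted time
#' as minuend: `error_s = extracted_s - recorded_s`, so negative errors mean
#' the extraction preceded the recorded event. The summary reports the
#' Pearson correlation between recorded and extracted times (only when at
#' least 3 events were matched), the fractions of all events with
#' `|error| <= 10 s` and `<= 30 s`, and the count of negative errors.
#'
#' @param regions a `high_power_regions` data.frame.
#' @param events an [event_table()].
#' @return object of class `match_result`: list with `matches` (data.frame:
#'   `recorded_s`, `label`, `source`, `extracted_s`, `error_s`,
#'   `region_id`) and `summary` (list: `pearson_r`, `p_value`,
#'   `frac_within_10s`, `frac_within_30s`, `n_events`, `n_regions`,
#'   `n_matched`, `n_early`).
#' @export
match_events <- function(regions, events) {
  stopifnot(inherits(events, "event_table"))
  n_ev <- nrow(events)
  n_reg <- nrow(regions)
  if (n_ev == 0L) {
    matches <- data.frame(recorded_s = numeric(), label = character(),
                          source = character(), extracted_s = numeric(),
                          error_s = numeric(), region_id = integer())
  } else if (n_reg == 0L) {
    matches <- data.frame(recorded_s = events$time_s, label = events$label,
                          source = events$source, extracted_s = NA_real_,
                          error_s = NA_real_, region_id = NA_integer_)
  } else {
    idx <- vapply(events$time_s, function(t0) {
      d <- abs(regions$centerline_s - t0)
      which.min(d)  # ties -> earlier region (which.min takes the first)
    }, integer(1))
    extracted <- regions$centerline_s[idx]
    matches <- data.frame(recorded_s = events$time_s, label = events$label,
                          source = events$source, extracted_s = extracted,
                          error_s = extracted - events$time_s,
                          region_id = regions$region_id[idx])
  }
  ok <- !is.na(matches$error_s)
  n_matched <- sum(ok)
  if (n_matched >= 3L && stats::sd(matches$recorded_s[ok]) > 0 &&
      stats::sd(matches$extracted_s[ok]) > 0) {
    ct <- stats::cor.test(matches$recorded_s[ok], matches$extracted_s[ok])
    pearson_r <- unname(ct$estimate)
    p_value <- ct$p.value
  } else {
    pearson_r <- NA_real_
    p_value <- NA_real_
  }
  summary <- list(
    pearson_r = pearson_r, p_value = p_value,
    frac_within_10s = if (n_ev) sum(ok & abs(matches$error_s) <= 10) / n_ev else NA_real_,
    frac_within_30s = if (n_ev) sum(ok & abs(matches$error_s) <= 30) / n_ev else NA_real_,
    n_events = n_ev, n_regions = n_reg, n_matched = n_matched,
    n_early = sum(ok & matches$error_s < 0)
  )
  structure(list(matches = matches, summary = summary),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<match_result> %d events, %d regions, %d matched; |err|<=10s: %.1f%%, <=30s: %.1f%%, early: %d\n",
    s$n_events, s$n_regions, s$n_matched,
    100 * s$frac_within_10s, 100 * s$frac_within_30s, s$n_early
  ))
  if (!is.na(s$pearson_r)) {
    cat(sprintf("  Pearson r = %.5f (p = %.3g)\n", s$pearson_r, s$p_value))
  } else {
    cat("  correlation not computable (< 3 matched pairs)\n")
  }
  invisible(x)
}
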