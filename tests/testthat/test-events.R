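# A hand-built scalogram whose band-of-interest envelope is exactly a given
# vector: one in-band scale carrying env, one out-of-band scale of zeros.
fake_scalogram <- function(env, times = seq_along(env) - 1) {
  structure(
    list(power = rbind(env, 0), freqs_hz = c(0.05, 0.4),
         scales = c(2 / 3 / 0.05, 2 / 3 / 0.4), times_s = times,
         band_interest_hz = c(0, 0.1), fs_ne = 1, wavelet = "dmey",
         window_mult = 10L,
         coi_s = pmin(times - times[1], times[length(times)] - times)),
    class = "netent_scalogram"
  )
}

test_that("a flat-topped run yields its symmetric centre as centerline", {
  env <- numeric(400)
  env[101:111] <- 5  # times 100..110 s
  reg <- detect_high_power_regions(fake_scalogram(env), percentile = 95)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$centerline_s, 105)
  expect_equal(reg$t_start_s, 100)
  expect_equal(reg$t_end_s, 110)
  # midpoint variant agrees here by symmetry
  regm <- detect_high_power_regions(fake_scalogram(env), percentile = 95,
                                    centerline = "midpoint")
  expect_equal(regm$centerline_s, 105)
})

test_that("an all-equal envelope produces no regions", {
  reg <- detect_high_power_regions(fake_scalogram(rep(1, 100)))
  expect_equal(nrow(reg), 0L)
})

test_that("well-separated runs become ordered non-overlapping regions", {
  env <- numeric(300)
  env[51:56] <- c(1, 2, 4, 4, 2, 1)
  env[201:204] <- c(3, 6, 6, 3)
  reg <- detect_high_power_regions(fake_scalogram(env), percentile = 95)
  expect_equal(nrow(reg), 2L)
  expect_true(all(diff(reg$t_start_s) > 0))
  expect_true(reg$t_end_s[1] < reg$t_start_s[2])
  # power-weighted centroids
  expect_equal(reg$centerline_s[1],
               sum((50:55) * env[51:56]) / sum(env[51:56]))
})

test_that("runs separated by less than one analysis window merge", {
  env <- numeric(300)
  env[101:103] <- 9
  env[108:110] <- 7   # 4-epoch gap < window_mult = 10
  env[200:202] <- 8   # far away: separate region
  reg <- detect_high_power_regions(fake_scalogram(env), percentile = 97)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$t_start_s[1], 100)
  expect_equal(reg$t_end_s[1], 109)
})

test_that("band selection in detection is validated", {
  expect_error(detect_high_power_regions(fake_scalogram(rep(1, 50)),
                                         band = c(0.6, 0.9)),
               "no scales")
})

test_that("matching pairs each event with the nearest centerline", {
  env <- numeric(400)
  env[96:106] <- 5    # centerline 100
  env[296:306] <- 5   # centerline 300
  reg <- detect_high_power_regions(fake_scalogram(env), percentile = 90)
  expect_equal(reg$centerline_s, c(100, 300))
  ev <- event_table(c(95, 310), c("a", "b"), "objective")
  m <- match_events(reg, ev)
  expect_equal(m$matches$extracted_s, c(100, 300))
  expect_equal(m$matches$error_s, c(5, -10))
  # error identity: extracted = recorded + error
  expect_equal(m$matches$recorded_s + m$matches$error_s, m$matches$extracted_s)
  expect_equal(m$summary$n_early, 1L)
  expect_true(is.na(m$summary$pearson_r))  # only 2 pairs
})

test_that("no regions leaves all events unmatched", {
  reg <- detect_high_power_regions(fake_scalogram(rep(1, 50)))
  ev <- event_table(c(5, 10, 20), c("a", "b", "c"), "subjective")
  m <- match_events(reg, ev)
  expect_true(all(is.na(m$matches$error_s)))
  expect_true(is.na(m$summary$pearson_r))
  expect_equal(m$summary$frac_within_10s, 0)
})

test_that("a perfect three-event match gives r = 1 and zero errors", {
  env <- numeric(500)
  env[101] <- 5; env[201] <- 5; env[301] <- 5
  reg <- detect_high_power_regions(fake_scalogram(env), percentile = 99)
  ev <- event_table(c(100, 200, 300), c("a", "b", "c"), "objective")
  m <- match_events(reg, ev)
  expect_equal(m$matches$error_s, c(0, 0, 0))
  expect_equal(m$summary$pearson_r, 1)
  expect_lt(m$summary$p_value, 0.001)
  expect_equal(m$summary$frac_within_10s, 1)
})

test_that("translation shifts centerlines but not errors", {
  env <- numeric(300)
  env[101:111] <- c(1:6, 5:1)
  delta <- 37.5
  sc0 <- fake_scalogram(env)
  sc1 <- fake_scalogram(env, times = (seq_along(env) - 1) + delta)
  r0 <- detect_high_power_regions(sc0, percentile = 95)
  r1 <- detect_high_power_regions(sc1, percentile = 95)
  expect_equal(r1$centerline_s, r0$centerline_s + delta)
  ev0 <- event_table(c(103, 108, 120), rep("e", 3), "objective")
  ev1 <- event_table(c(103, 108, 120) + delta, rep("e", 3), "objective")
  m0 <- match_events(r0, ev0)
  m1 <- match_events(r1, ev1)
  expect_equal(m1$matches$error_s, m0$matches$error_s)
})
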