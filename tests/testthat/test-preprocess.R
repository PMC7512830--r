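test_that("band spec resolves the dyadic level and rejects non-dyadic bands", {
  spec <- wavelet_band_spec(300, c(18.75, 37.5))
  expect_equal(spec$level, 3L)  # d1 = 75-150, d2 = 37.5-75, d3 = 18.75-37.5 Hz
  expect_equal(wavelet_band_spec(300, c(37.5, 75))$level, 2L)
  expect_error(wavelet_band_spec(300, c(20, 40)), "not a dyadic detail band")
  expect_error(wavelet_band_spec(300, c(18.75, 200)), "Nyquist")
})

make_rec <- function(data, fs = 300) eeg_recording(data, fs = fs)

test_that("band selection keeps in-band energy and rejects out-of-band tones", {
  fs <- 300
  n <- 2^14
  t <- (0:(n - 1)) / fs
  set.seed(21)
  rec <- make_rec(rbind(rnorm(n), cos(2 * pi * 25 * t), cos(2 * pi * 5 * t)))
  out <- band_select(rec)
  # white noise: >= 90% of output spectral energy inside 18.75-37.5 Hz
  y <- out$data[1, ]
  P <- Mod(stats::fft(y))^2
  fr <- (0:(n - 1)) / n * fs
  inb <- (fr >= 18.75 & fr <= 37.5) | ((fs - fr) >= 18.75 & (fs - fr) <= 37.5)
  expect_gte(sum(P[inb]) / sum(P), 0.90)
  # 25 Hz tone passes (>= 80% energy), 5 Hz tone is removed (<= 5%)
  expect_gte(sum(out$data[2, ]^2) / sum(rec$data[2, ]^2), 0.80)
  expect_lte(sum(out$data[3, ]^2) / sum(rec$data[3, ]^2), 0.05)
})

test_that("band selection is linear and channel-independent", {
  set.seed(22)
  rec <- make_rec(matrix(rnorm(2 * 4096), nrow = 2))
  zero <- make_rec(matrix(0, 2, 4096) + rbind(rec$data[1, ], 0))
  expect_equal(band_select(make_rec(rbind(rep(0, 4096), rep(0, 4096))))$data,
               matrix(0, 2, 4096), ignore_attr = TRUE)
  # processing channel 1 does not depend on channel 2
  a <- band_select(rec)$data[1, ]
  b <- band_select(zero)$data[1, ]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the coefficient outlier rule matches direct arithmetic", {
  # (1,1,1,100): mean + 2 sd ~ 111.6 -> nothing zeroed
  C <- c(1, 1, 1, 100)
  expect_equal(netent:::threshold_pass(C, 2, FALSE), C)
  C <- c(0, 0, 0, 100)
  expect_equal(netent:::threshold_pass(C, 2, FALSE), C)
  # 99 ones and a 1000: threshold ~ 209.8 -> the 1000 is zeroed
  C <- c(rep(1, 99), 1000)
  out <- netent:::threshold_pass(C, 2, FALSE)
  expect_equal(out, c(rep(1, 99), 0))
  # second pass leaves the ones alone
  expect_equal(netent:::threshold_pass(out, 2, FALSE), out)
  # constant coefficients: sd = 0 and the strict ">" keeps everything
  expect_equal(netent:::threshold_pass(rep(3, 50), 2, FALSE), rep(3, 50))
})

test_that("thresholding never increases energy and is nearly idempotent", {
  sim <- small_synth(seed = 23, duration_s = 40, events = 20)
  rec <- sim$recording
  sel <- band_select(rec)
  cor2 <- threshold_correct(rec, n_passes = 2L)
  e <- function(r) sum(r$data^2)
  expect_lte(e(sel), e(rec) + 1e-6 * e(rec))
  expect_lte(e(cor2), e(sel) + 1e-6 * e(sel))
  # a third pass of the rule alters < 1% of the band coefficients
  spec <- wavelet_band_spec(300)
  h <- dmey_filter()
  for (ch in 1:3) {
    coefs <- netent:::zero_other_subbands(dwt(rec$data[ch, ], spec$level, h),
                                          spec)
    C2 <- coefs$detail[[spec$level]]
    for (p in 1:2) C2 <- netent:::threshold_pass(C2, 2, FALSE)
    C3 <- netent:::threshold_pass(C2, 2, FALSE)
    expect_lt(mean(C3 != C2), 0.01)
  }
  expect_error(threshold_correct(rec, n_passes = 0L), "n_passes")
  expect_error(threshold_correct(rec, k_sigma = 0), "k_sigma")
})

test_that("thresholding suppresses implanted high-amplitude bursts", {
  spec <- synth_spec(n_channels = 4, duration_s = 40, event_times_s = numeric(),
                     artifact_times_s = c(15, 25), seed = 24)
  rec <- generate_recording(spec)$recording
  sel <- band_select(rec)
  cor <- threshold_correct(rec)
  # the one-sided signed rule clips the positive excursions and energy ...
  expect_lt(max(cor$data), max(sel$data))
  expect_lt(sum(cor$data^2), sum(sel$data^2))
  # ... while the symmetric |C| variant suppresses both polarities
  sym <- threshold_correct(rec, symmetric = TRUE)
  expect_lt(max(abs(sym$data)), 0.8 * max(abs(sel$data)))
})
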