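test_that("algebraic connectivity matches known spectra", {
  # no edge between two nodes -> disconnected -> 0
  expect_equal(laplacian_lambda2(matrix(0, 2, 2)), 0)
  # triangle K3: Laplacian spectrum {0, 3, 3}
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(laplacian_lambda2(k3), 3, tolerance = 1e-12)
  # path P3: spectrum {0, 1, 3}
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(laplacian_lambda2(p3), 1, tolerance = 1e-12)
  expect_error(laplacian_lambda2(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("threshold search reproduces hand-stepped cases", {
  # uniform weights 0.8 on K4: strict '>' means edges appear below 0.8,
  # first connected grid point is T = 0.79, and lambda2(K4) = 4
  f <- matrix(0.8, 4, 4)
  diag(f) <- 0
  bg <- find_threshold(f)
  expect_equal(bg$threshold_T, 0.79, tolerance = 1e-9)
  expect_equal(bg$lambda2, 4, tolerance = 1e-9)
  expect_true(all(bg$adjacency == (matrix(1, 4, 4) - diag(4))))

  # weighted path 1-2 (0.9), 2-3 (0.5): connected first at T = 0.49 as P3
  f <- matrix(0, 3, 3)
  f[1, 2] <- f[2, 1] <- 0.9
  f[2, 3] <- f[3, 2] <- 0.5
  bg <- find_threshold(f)
  expect_equal(bg$threshold_T, 0.49, tolerance = 1e-9)
  expect_equal(sum(bg$adjacency), 4)  # two undirected edges
  expect_equal(laplacian_lambda2(bg$adjacency), 1, tolerance = 1e-9)

  # block-diagonal with zero cross-block weights can never connect
  f <- matrix(0, 4, 4)
  f[1, 2] <- f[2, 1] <- 0.9
  f[3, 4] <- f[4, 3] <- 0.9
  expect_error(find_threshold(f), "cannot be connected")
})

test_that("a finer step refines the threshold toward the connecting weight", {
  f <- matrix(0, 3, 3)
  f[1, 2] <- f[2, 1] <- 0.9
  f[2, 3] <- f[3, 2] <- 0.5
  coarse <- find_threshold(f, step = 0.2, min_step = 0.2)
  fine <- find_threshold(f, step = 0.01, min_step = 0.01)
  expect_equal(coarse$threshold_T, 0.4, tolerance = 1e-9)
  expect_equal(fine$threshold_T, 0.49, tolerance = 1e-9)
  expect_gte(fine$threshold_T, coarse$threshold_T)
  expect_true(oracle_bfs_connected(fine$adjacency))
})

test_that("classical metrics match closed forms on K4 and the 5-star", {
  k4 <- matrix(1, 4, 4) - diag(4)
  m <- compute_metrics(k4)
  expect_equal(m$clustering, 1)
  expect_equal(m$char_path_length, 1)
  expect_equal(m$global_efficiency, 1)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  m <- compute_metrics(star)
  expect_equal(m$clustering, 0)
  expect_equal(m$char_path_length, 1.6)   # (4*1 + 6*2)/10
  expect_equal(m$global_efficiency, 0.7)  # (4*1 + 6*0.5)/10
  expect_equal(m$vulnerability, 1)        # removing the hub isolates all leaves
  expect_error(compute_metrics(diag(0, 4)), "connected")
})

test_that("path metrics equal the BFS brute force on random connected graphs", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    a <- random_connected_adjacency(n, stats::runif(1, 0.3, 0.8))
    m <- compute_metrics(a)
    o <- oracle_path_metrics(a)
    expect_equal(m$char_path_length, o$cpl, tolerance = 1e-12)
    expect_equal(m$global_efficiency, o$eff, tolerance = 1e-12)
    expect_gte(m$clustering, 0); expect_lte(m$clustering, 1)
    expect_gte(m$vulnerability, 0); expect_lte(m$vulnerability, 1)
    expect_gte(m$char_path_length, 1)
  }
})

test_that("edge sets grow monotonically as the threshold decreases", {
  set.seed(52)
  f <- random_connectivity(8)
  prev <- matrix(0, 8, 8)
  for (T in seq(1, 0, by = -0.05)) {
    a <- netent:::binarize_at(f, T)
    expect_true(all(a >= prev))
    prev <- a
  }
})

test_that("metrics_series keeps unconnectable epochs as NA rows", {
  set.seed(53)
  rec <- eeg_recording(matrix(rnorm(4 * 400), nrow = 4), fs = 100)
  fcgb <- build_fcgb_sequence(rec, analysis_config(100, sl_samples = 100,
                                                   window_mult = 2))
  # sabotage epoch 2 into a disconnected two-block pattern
  f <- matrix(0, 4, 4)
  f[1, 2] <- f[2, 1] <- 0.9
  f[3, 4] <- f[4, 3] <- 0.9
  fcgb$values[, , 2] <- f
  expect_message(met <- metrics_series(fcgb), "unconnectable")
  expect_equal(nrow(met), 3L)
  expect_true(is.na(met$clustering[2]))
  expect_false(anyNA(met[c(1, 3), ]))
  # per-row threshold reproduces a standalone search
  bg <- find_threshold(fcgb$values[, , 1])
  expect_equal(met$threshold_T[1], bg$threshold_T)
  # identical epochs give identical rows
  fcgb$values[, , 2] <- fcgb$values[, , 1]
  fcgb$values[, , 3] <- fcgb$values[, , 1]
  met2 <- metrics_series(fcgb)
  expect_equal(met2[2, -1], met2[3, -1], ignore_attr = TRUE)
})
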