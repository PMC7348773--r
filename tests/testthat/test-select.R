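# a recording whose gyro magnitudes produce a prescribed Delta-omega vector
rec_with_dw <- function(dw) {
  n <- length(dw)
  g1 <- cbind(abs(dw) + pmax(dw, 0), 0, 0)
  g2 <- cbind(abs(dw) + pmax(-dw, 0), 0, 0)
  recording_from_channels(g1, matrix(0, n, 3), g2, matrix(0, n, 3))
}

test_that("gyro score is the windowed minimum-magnitude rate difference", {
  # stationary: all scores zero
  rec0 <- rec_with_dw(rep(0, 10))
  expect_equal(gyro_score(rec0, window = 2), rep(0, 10))

  # hand example: outliers next to a small value inherit it
  rec <- rec_with_dw(c(5, 0.1, 5, 5, 5))
  expect_equal(gyro_score(rec, window = 1), c(0.1, 0.1, 0.1, 5, 5))

  # an isolated spike surrounded by zeros scores zero
  rec2 <- rec_with_dw(c(0, 0, 8, 0, 0))
  expect_equal(gyro_score(rec2, window = 1)[3], 0)

  # sign of the minimum-magnitude element is preserved
  rec3 <- rec_with_dw(c(-0.2, 3, -4))
  expect_equal(gyro_score(rec3, window = 2), rep(-0.2, 3))
})

test_that("gyro selection keeps both ends of the sorted score list", {
  # N <= n_max: identity
  rec <- rec_with_dw(c(1, -1, 2, -2))
  expect_equal(select_gyro(rec, selection_config(n_max = 4, window = 1)),
               1:4)

  # hand case: scores (3, 2, 1, -1, -2, -3) with window 0 behaviour via
  # well-separated values and window 1 (isolated values survive windowing
  # when neighbours are larger in magnitude on both sides)
  scores <- c(3, 2, 1, -1, -2, -3)
  keep <- hingecal:::select_gyro_from_scores(scores, 4)
  expect_equal(keep, c(1, 2, 5, 6))

  # brute-force multiset oracle on random scores
  withr::with_seed(31, {
    for (i in 1:20) {
      s <- rnorm(40)
      keep <- hingecal:::select_gyro_from_scores(s, 10)
      expect_equal(length(keep), 10L)
      srt <- sort(s)
      oracle <- c(head(srt, 5), tail(srt, 5))
      expect_equal(sort(s[keep]), sort(oracle))
    }
  })
})

test_that("gyro selection balances the two sensors on sequential motion", {
  cfg <- sim_config(seed = 32)
  rec <- simulate_motion(3, cfg, 20)   # segment 1 first, then segment 2
  half <- nrow(rec) / 2
  idx <- select_gyro(rec, selection_config(n_max = 200))
  expect_equal(length(idx), 200L)
  expect_gte(sum(idx <= half), 90)     # sensor-1-dominant phase
  expect_gte(sum(idx > half), 90)      # sensor-2-dominant phase
})

test_that("angular-rate energy averages full windows and floors edges at Inf", {
  n <- 2L
  g <- cbind(rep(2, 11), 0, 0)         # constant magnitude 2
  rec <- recording_from_channels(g, matrix(0, 11, 3), matrix(0, 11, 3),
                                 matrix(0, 11, 3))
  e1 <- angular_rate_energy(rec, 1, window = n)
  expect_equal(e1[(n + 1):(11 - n)], rep(4, 11 - 2 * n))
  expect_equal(e1[1], Inf)
  expect_equal(e1[11], Inf)
  e2 <- angular_rate_energy(rec, 2, window = n)
  expect_equal(e2[(n + 1):(11 - n)], rep(0, 11 - 2 * n))
  # penalty: one stationary sensor is enough
  expect_equal(accel_penalty(rec, window = n)[(n + 1):(11 - n)],
               rep(0, 11 - 2 * n))
  expect_equal(accel_penalty(rec, window = n)[1], Inf)
})

test_that("coherence matches an independent SVD oracle", {
  # identical rows: rank one, all coherences 1
  A <- matrix(rep(c(1, 0, 2, 0, -1, 1), each = 5), 5, 6)
  expect_equal(coherence(A), rep(1, 5), tolerance = 1e-12)

  # a row orthogonal to the dominant direction scores 0
  A2 <- rbind(c(1, 0, 0, 0, 0, 0),
              c(1, 0, 0, 0, 0, 0),
              c(1, 0, 0, 0, 0, 0),
              c(0, 1, 0, 0, 0, 0))
  ck <- coherence(A2)
  expect_equal(ck[1:3], rep(1, 3), tolerance = 1e-12)
  expect_equal(ck[4], 0, tolerance = 1e-12)

  # random matrices: agree with an eigendecomposition-based w1
  withr::with_seed(33, {
    for (i in 1:10) {
      A3 <- matrix(rnorm(60), 10, 6)
      w1 <- eigen(crossprod(A3), symmetric = TRUE)$vectors[, 1]
      oracle <- abs(drop(A3 %*% w1)) / sqrt(rowSums(A3^2))
      expect_equal(coherence(A3), oracle, tolerance = 1e-9)
    }
  })
})

test_that("accelerometer selection thresholds energy then prunes redundancy", {
  cfg <- selection_config(n_max = 4, window = 1, energy_threshold = 1)

  # all penalties above threshold: nothing retained
  g_fast <- cbind(rep(5, 9), 0, 0)
  rec_fast <- recording_from_channels(g_fast, matrix(1, 9, 3), g_fast,
                                      matrix(1, 9, 3))
  expect_equal(length(select_accel(rec_fast, cfg)), 0L)

  # stationary, N small after threshold: identity on interior samples
  rec_still <- recording_from_channels(matrix(0, 6, 3), matrix(1, 6, 3),
                                       matrix(0, 6, 3), matrix(2, 6, 3))
  expect_equal(as.integer(select_accel(rec_still, cfg)), 2:5)

  # two direction clusters: removals must come from the majority cluster
  n_maj <- 12; n_min_ <- 3
  a1 <- rbind(matrix(rep(c(3, 0, 0), n_maj), ncol = 3, byrow = TRUE),
              matrix(rep(c(0, 3, 0), n_min_), ncol = 3, byrow = TRUE))
  jitter <- withr::with_seed(35,
    matrix(rnorm(3 * (n_maj + n_min_), sd = 1e-3), ncol = 3))
  rec2 <- recording_from_channels(matrix(0, n_maj + n_min_, 3), a1 + jitter,
                                  matrix(0, n_maj + n_min_, 3),
                                  matrix(0, n_maj + n_min_, 3))
  cfg2 <- selection_config(n_max = 8, window = 1, energy_threshold = 1)
  keep <- select_accel(rec2, cfg2)
  expect_true(all((n_maj + 1):(n_maj + n_min_ - 1) %in% keep))
  expect_equal(attr(keep, "fallbacks"), 0L)
})

test_that("online selection updates match batch selection", {
  cfg <- selection_config(n_max = 100, window = 5, energy_threshold = 1)
  sim <- sim_config(seed = 34)
  rec <- make_stream(c(3, 1), c(10, 5), sim, seed0 = 340)

  state <- selection_state()
  for (te in seq(1, 15)) {
    m <- sum(rec$t < te)
    state <- update_selection(state, rec[seq_len(m), ], cfg)
    expect_lte(length(state$gyro_retained), cfg$n_max)
    expect_lte(length(state$accel_retained), cfg$n_max)
  }
  # gyro: cached scores and the retained set equal the batch computation
  expect_equal(state$score, gyro_score(rec, cfg$window))
  expect_equal(state$gyro_retained, select_gyro(rec, cfg))
  # accel penalties match the batch computation
  expect_equal(state$sa, accel_penalty(rec, cfg$window))

  # empty new batch: state unchanged
  state2 <- update_selection(state, rec, cfg)
  expect_identical(state, state2)
})
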