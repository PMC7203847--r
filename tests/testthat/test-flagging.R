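test_that("windowed SD matches the direct formula", {
  # {2, 4, 6} uV -> SD exactly 2
  rec <- new_recording(matrix(c(2, 4, 6), 1), 3, "A")
  ws <- window_sd(rec, 1)
  expect_equal(unname(ws$values[1, 1]), 2)
  # constant channel -> all zero
  rec <- new_recording(rbind(rep(3, 100), rnorm(100)), 10, c("A", "B"))
  expect_true(all(window_sd(rec, 1)$values["A", ] == 0))
  # floor rule: 10.5 s at 1 s windows -> 10 windows
  rec <- noise_recording(nch = 2, n = 2625, sfreq = 250)
  expect_identical(ncol(window_sd(rec, 1)$values), 10L)
  expect_error(window_sd(noise_recording(n = 100, sfreq = 250), 1), "longer")
  # brute-force oracle on random 8 x 1000 input
  rec <- noise_recording(nch = 8, n = 1000, sfreq = 100, seed = 11)
  ws <- window_sd(rec, 1)
  for (c_i in 1:8) for (w in 1:10) {
    expect_equal(unname(ws$values[c_i, w]),
                 sd(rec$samples[c_i, ((w - 1) * 100 + 1):(w * 100)]),
                 tolerance = 1e-12)
  }
})

test_that("robust outlier mask flags exactly the anomalous cells", {
  mk <- function(v) losslessr:::new_window_stats("sd", sprintf("c%02d", seq_len(nrow(v))),
                                                 1, seq_len(ncol(v)) - 1, v)
  # zero dispersion -> all false
  m <- robust_outlier_mask(mk(matrix(4, 10, 10)), "across-rows")
  expect_false(any(m$mask))
  # one cell at 100 among 49 cells near 1 (one 50-channel window slice)
  set.seed(2)
  v <- matrix(runif(500, 0.99, 1.01), 50, 10); v[2, 4] <- 100
  m <- robust_outlier_mask(mk(v), "across-rows", k = 6)
  expect_true(m$mask[2, 4])
  expect_identical(sum(m$mask), 1L)
  # hand-computed bound for that slice
  q <- quantile(v[, 4], c(0.3, 0.5, 0.7), names = FALSE)
  expect_true(v[2, 4] > q[2] + 6 * (q[3] - q[2]))
  # permutation of the non-compared axis leaves each slice's flags intact
  perm <- sample(10)
  m2 <- robust_outlier_mask(mk(v[, perm]), "across-rows", k = 6)
  expect_identical(m2$mask, m$mask[, perm])
  # across-windows direction
  v <- matrix(runif(500, 0.99, 1.01), 50, 10); v[3, 7] <- 50
  m <- robust_outlier_mask(mk(v), "across-windows", k = 6)
  expect_true(m$mask[3, 7])
  expect_error(robust_outlier_mask(mk(matrix(1, 2, 10)), "across-rows"), ">= 3")
})

test_that("channel SD flags use a strict fraction and catch dead channels", {
  mk_mask <- function(m) structure(list(row_labels = sprintf("c%02d", seq_len(nrow(m))),
                                        onsets = seq_len(ncol(m)) - 1, window_s = 1,
                                        mask = m), class = "flag_matrix")
  expect_length(flag_channels_sd(mk_mask(matrix(FALSE, 5, 10))), 0)
  m <- matrix(FALSE, 5, 10); m[2, 1:3] <- TRUE       # 30% of windows
  expect_identical(flag_channels_sd(mk_mask(m), p_ch = 0.2), "c02")
  m <- matrix(FALSE, 5, 10); m[2, 1:2] <- TRUE       # exactly 20%: NOT flagged
  expect_length(flag_channels_sd(mk_mask(m), p_ch = 0.2), 0)
  # near-flat channel flagged via the window stats even with an empty mask
  v <- matrix(5, 4, 10); v[4, ] <- 0.01
  ws <- losslessr:::new_window_stats("sd", sprintf("c%02d", 1:4), 1, 0:9, v)
  expect_identical(flag_channels_sd(mk_mask(matrix(FALSE, 4, 10)), ws = ws), "c04")
})

test_that("time SD flags merge adjacent windows and ignore lone channels", {
  mk_mask <- function(m) structure(list(row_labels = sprintf("c%02d", seq_len(nrow(m))),
                                        onsets = seq_len(ncol(m)) - 1, window_s = 1,
                                        mask = m), class = "flag_matrix")
  # burst on 50% of channels for 3 consecutive windows -> one 3 s interval
  m <- matrix(FALSE, 64, 20); m[1:32, 5:7] <- TRUE
  tf <- flag_time_sd(mk_mask(m), p_t = 0.2)
  expect_identical(nrow(tf), 1L)
  expect_equal(tf$onset, 4)
  expect_equal(tf$duration, 3)
  expect_identical(tf$label, "ch_sd")
  # single channel on 64-channel data: 1/64 < 0.2 -> nothing
  m <- matrix(FALSE, 64, 20); m[5, ] <- TRUE
  expect_identical(nrow(flag_time_sd(mk_mask(m), p_t = 0.2)), 0L)
  expect_identical(nrow(flag_time_sd(mk_mask(matrix(FALSE, 4, 5)))), 0L)
})

test_that("neighbor correlation agrees with a brute-force oracle", {
  m <- standard_montage(32)
  rec <- noise_recording(nch = 32, n = 1000, sfreq = 250, seed = 5,
                         labels = m$labels)
  ws <- neighbor_r(rec, m, k_neighbors = 3, window_s = 1)
  nb <- losslessr:::nearest_neighbors(m, m$labels, 3)
  for (ci in c(1, 7, 32)) for (w in 1:4) {
    cols <- ((w - 1) * 250 + 1):(w * 250)
    ref <- max(vapply(nb[[ci]], function(nl)
      abs(cor(rec$samples[ci, cols], rec$samples[nl, cols])), 0))
    expect_equal(unname(ws$values[ci, w]), ref, tolerance = 1e-12)
  }
  # duplicated channel onto its nearest neighbor -> r = 1 in every window
  rec2 <- rec
  rec2$samples["E002", ] <- rec2$samples[nb[[2]][1], ]
  ws2 <- neighbor_r(rec2, m, 3, 1)
  expect_true(all(ws2$values["E002", ] > 1 - 1e-12))
  # flat channel -> 0 with a missing-data note
  rec3 <- rec
  rec3$samples["E003", ] <- 0
  ws3 <- neighbor_r(rec3, m, 3, 1)
  expect_true(all(ws3$values["E003", ] == 0))
  expect_true(all(ws3$missing[match("E003", ws3$row_labels), ]))
  # montage missing a channel errors
  expect_error(neighbor_r(noise_recording(nch = 2, labels = c("xx", "yy")),
                          m, 3, 1), "xx")
})

test_that("low_r flags decoupled channels and sensor-pop windows only", {
  m <- standard_montage(32)
  set.seed(8)
  n <- 5000
  # variance-stationary common source: uniformly high neighbor correlation
  common <- rnorm(n)
  common <- as.numeric(scale(matrix(common, 250))) # unit SD in every window
  X <- matrix(rep(common, each = 32), 32) + 0.1 * matrix(rnorm(32 * n), 32)
  rec <- new_recording(X, 250, m$labels)
  # one common source: uniformly high r, no flags
  ws <- neighbor_r(rec, m, 3, 1)
  lr <- flag_low_r(ws)
  expect_length(lr$channels, 0)
  expect_identical(nrow(lr$time), 0L)
  # one channel replaced by independent noise -> flagged low_r
  X2 <- X; X2[10, ] <- rnorm(n)
  ws2 <- neighbor_r(new_recording(X2, 250, m$labels), m, 3, 1)
  lr2 <- flag_low_r(ws2)
  expect_identical(lr2$channels, m$labels[10])
  # 2 windows where all channels decorrelate (sensor pop) -> both time-flagged
  X3 <- X
  pop <- 1001:1500  # windows 5 and 6
  X3[, pop] <- matrix(rnorm(32 * 500), 32)
  ws3 <- neighbor_r(new_recording(X3, 250, m$labels), m, 3, 1)
  lr3 <- flag_low_r(ws3)
  expect_identical(nrow(lr3$time), 1L)
  expect_equal(lr3$time$onset, 4)
  expect_equal(lr3$time$duration, 2)
  expect_identical(lr3$time$label, "low_r")
})

test_that("bridging needs extreme and stable correlation", {
  m <- standard_montage(32)
  nb <- losslessr:::nearest_neighbors(m, m$labels, 1)
  set.seed(4)
  n <- 5000
  common <- rnorm(n)
  X <- matrix(rep(common, each = 32), 32) * runif(32, 0.5, 1.5) +
    0.4 * matrix(rnorm(32 * n), 32)
  lb <- m$labels
  i <- match("E011", lb); j <- match(nb[[i]], lb)
  # duplicated pair + 1% relative noise -> both flagged
  X2 <- X
  X2[j, ] <- X2[i, ] + 0.01 * sd(X2[i, ]) * rnorm(n)
  ws <- neighbor_r(new_recording(X2, 250, lb), m, 3, 1)
  expect_setequal(flag_bridge(ws), lb[c(i, j)])
  # independent-ish montage: no bridges
  ws0 <- neighbor_r(new_recording(X, 250, lb), m, 3, 1)
  expect_length(flag_bridge(ws0), 0)
  # strong common source at r ~ 0.9 stays below the 0.98 bar
  X3 <- X
  X3[j, ] <- X3[i, ] + 0.5 * sd(X3[i, ]) * rnorm(n)
  pr <- abs(cor(X3[i, ], X3[j, ]))
  expect_lt(pr, 0.98)
  ws3 <- neighbor_r(new_recording(X3, 250, lb), m, 3, 1)
  expect_length(flag_bridge(ws3), 0)
})

test_that("gap marking flags uncovered spans longer than the threshold", {
  rec <- noise_recording(nch = 2, n = 40 * 250, sfreq = 250)
  # events at 10 and 30 s with zero duration, 40 s recording
  ev <- event_table(c(10, 30), c(0, 0), c("a", "b"))
  gaps <- mark_gaps(ev, rec, max_gap_s = 5)
  expect_identical(nrow(gaps), 3L)
  expect_equal(gaps$onset, c(0, 10, 30))
  expect_equal(gaps$duration, c(10, 20, 10))
  expect_true(all(gaps$label == "gap"))
  # events covering the whole recording -> nothing
  ev2 <- event_table(0, 40, "block")
  expect_identical(nrow(mark_gaps(ev2, rec, 5)), 0L)
  # resting convention: empty table -> no gap flags
  expect_identical(nrow(mark_gaps(event_table(), rec, 5)), 0L)
  # short inter-event spans are tolerated
  ev3 <- event_table(seq(0, 38, by = 2), rep(1, 20), rep("s", 20))
  expect_identical(nrow(mark_gaps(ev3, rec, 5)), 0L)
})

test_that("channel criteria are invariant to channel ordering", {
  sim <- defect_sim(duration_s = 60, seed = 3, movement_bursts = 0)
  rec <- sim$recording
  m <- sim$montage
  perm <- sample(length(rec$labels))
  rec_p <- new_recording(rec$samples[perm, ], rec$sfreq, rec$labels[perm],
                         events = rec$events)
  ws <- neighbor_r(rec, m, 3, 1)
  ws_p <- neighbor_r(rec_p, m, 3, 1)
  expect_setequal(flag_bridge(ws), flag_bridge(ws_p))
  lr <- flag_low_r(ws); lr_p <- flag_low_r(ws_p)
  expect_setequal(lr$channels, lr_p$channels)
})
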