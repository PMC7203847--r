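test_that("mains removal suppresses the line tone and only the line tone", {
  t <- seq(1 / 250, 20, by = 1 / 250)
  tone <- function(f) new_recording(matrix(sin(2 * pi * f * t), 1), 250, "A")
  # >= 30 dB at the line frequency
  out <- notch_filter(tone(60), 60)
  expect_lt(sd(out$samples) / sd(tone(60)$samples), 0.032)
  # passband within 1 dB outside +/- 2 Hz of the notch
  for (f in c(58, 62, 55, 10)) {
    out <- notch_filter(tone(f), 60)
    expect_gt(sd(out$samples) / sd(tone(f)$samples), 0.891)
  }
  # DC is in the passband
  dc <- new_recording(matrix(rep(5, 5000), 1), 250, "A")
  expect_lt(max(abs(notch_filter(dc, 60)$samples - 5)), 1e-9)
  # above Nyquist is rejected
  expect_error(notch_filter(tone(10), 130), "Nyquist")
  # input untouched, provenance appended
  rec <- tone(60)
  out <- notch_filter(rec, 60)
  expect_equal(rec$provenance, character(0))
  expect_match(out$provenance[1], "notch_filter")
  expect_false(identical(rec$samples, out$samples))
})

test_that("harmonic notches remove multiples of the line frequency", {
  t <- seq(1 / 500, 10, by = 1 / 500)
  x <- sin(2 * pi * 60 * t) + 0.5 * sin(2 * pi * 120 * t) + sin(2 * pi * 17 * t)
  rec <- new_recording(matrix(x, 1), 500, "A")
  out <- notch_filter(rec, 60, harmonics = 3)  # 180 Hz skipped at 500 Hz? no: < 250, kept
  p <- welch_psd(out$samples[1, ], 500)
  at <- function(f) p$power[which.min(abs(p$freq - f))]
  expect_lt(at(60) / at(17), 1e-3)
  expect_lt(at(120) / at(17), 1e-3)
})

test_that("average reference zeroes the included mean and drops rank by one", {
  rec <- noise_recording(nch = 32, n = 2000, seed = 3)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$samples))), 1e-9)
  sv <- svd(out$samples)$d
  expect_identical(sum(sv > 1e-7 * sv[1]), 31L)       # numerical rank 31
  # excluded channels are re-expressed against the same reference
  out2 <- rereference_average(rec, exclude = "ch01")
  incl <- setdiff(rec$labels, "ch01")
  expect_lt(max(abs(colMeans(out2$samples[incl, ]))), 1e-9)
  ref <- colMeans(rec$samples[incl, ])
  expect_equal(out2$samples["ch01", ], rec$samples["ch01", ] - ref)
  expect_error(rereference_average(noise_recording(nch = 2),
                                   exclude = "ch01"), ">= 2")
})

test_that("study envelope matches a direct quantile computation", {
  # zero dispersion: bounds collapse onto the common value
  ws_const <- losslessr:::new_window_stats("sd", letters[1:4], 1, 0:9,
                                          matrix(7, 4, 10))
  env <- estimate_study_envelope(list(ws_const))
  expect_equal(env$lower, 7)
  expect_equal(env$upper, 7)
  # pooled 1..100 against the brute-force quantile oracle
  vals <- matrix(1:100, 10, 10)
  ws <- losslessr:::new_window_stats("sd", letters[1:10], 1, 0:9, vals)
  env <- estimate_study_envelope(list(ws), pL = 0.3, pU = 0.7, k = 3)
  q <- quantile(1:100, c(0.3, 0.5, 0.7), names = FALSE)
  expect_equal(env$lower, q[2] - 3 * (q[2] - q[1]))
  expect_equal(env$upper, q[2] + 3 * (q[3] - q[2]))
  # pooling two identical recordings changes nothing
  env2 <- estimate_study_envelope(list(ws, ws), pL = 0.3, pU = 0.7, k = 3)
  expect_equal(env2$lower, env$lower)
  expect_equal(env2$upper, env$upper)
  expect_error(estimate_study_envelope(list()), "empty")
  ws_other <- losslessr:::new_window_stats("neighbor_r", letters[1:10], 1, 0:9, vals)
  expect_error(estimate_study_envelope(list(ws, ws_other)), "mixed")
})

test_that("staging flags follow the envelope and fraction rules", {
  env <- structure(list(statistic = "sd", lower = 0, upper = 10, q50 = 5,
                        k = 6, n_recordings = 1), class = "study_envelope")
  mk <- function(v) losslessr:::new_window_stats("sd", sprintf("c%02d", 1:10),
                                                 1, 0:19, v)
  # everything inside: no flags
  st <- flag_staging(mk(matrix(5, 10, 20)), env)
  expect_length(st$channels, 0)
  expect_identical(nrow(st$time), 0L)
  # one channel always 10x above: channel flagged, no time flags remain
  v <- matrix(5, 10, 20); v[3, ] <- 100
  st <- flag_staging(mk(v), env)
  expect_identical(st$channels, "c03")
  expect_identical(nrow(st$time), 0L)
  # 5-window burst on 80% of channels: one merged interval over those windows
  v <- matrix(5, 10, 20); v[1:8, 6:10] <- 50
  st <- flag_staging(mk(v), env, p_ch = 0.3, p_t = 0.2)
  expect_length(st$channels, 0)
  expect_identical(nrow(st$time), 1L)
  expect_equal(st$time$onset, 5)
  expect_equal(st$time$duration, 5)
  expect_identical(st$time$label, "ch_s_sd")
  # statistic id mismatch is refused
  ws_r <- losslessr:::new_window_stats("neighbor_r", "a", 1, 0, matrix(1))
  expect_error(flag_staging(ws_r, env), "statistic")
})

test_that("growing k never shrinks the envelope (flag monotonicity)", {
  set.seed(9)
  vals <- matrix(rexp(500), 25, 20)
  ws <- losslessr:::new_window_stats("sd", sprintf("c%02d", 1:25), 1, 0:19, vals)
  flagged_cells <- function(k) {
    env <- estimate_study_envelope(list(ws), k = k)
    sum(ws$values < env$lower | ws$values > env$upper)
  }
  ks <- c(1, 2, 4, 6, 10)
  counts <- vapply(ks, flagged_cells, 0)
  expect_true(all(diff(counts) <= 0))
})
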