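toy_sources <- function(n = 5000, seed = 1) {
  set.seed(seed)
  S <- rbind(sign(rnorm(n)) * rexp(n), sign(rnorm(n)) * rexp(n))
  A <- matrix(c(1, 0.5, 0.4, 1), 2, 2)
  list(S = S, A = A, X = A %*% S)
}

test_that("ICA input preparation drops flags and excises intervals", {
  rec <- rereference_average(noise_recording(nch = 32, n = 300 * 250, seed = 6))
  # no flags, average referenced -> rank 31
  prep <- prepare_ica_input(rec, annotations())
  expect_identical(prep$effective_rank, 31L)
  expect_length(prep$included_channels, 32)
  # 2 channels flagged -> 30 rows
  ann <- annotations(channel_flags = list(ch01 = "ch_sd", ch05 = "low_r"))
  prep <- prepare_ica_input(rec, ann)
  expect_identical(nrow(prep$data), 30L)
  # 60 s flagged of 300 -> (300 - 60) * 250 samples retained
  ann <- annotations(time_flags = losslessr:::make_intervals(
    c(0, 200), c(30, 30), c("ch_s_sd", "ic_sd1")))
  prep <- prepare_ica_input(rec, ann)
  expect_identical(ncol(prep$data), (300L - 60L) * 250L)
  # too few channels errors
  heavy <- annotations(channel_flags = stats::setNames(
    rep(list("ch_sd"), 20), sprintf("ch%02d", 1:20)))
  expect_error(prepare_ica_input(rec, heavy), "16")
  # too few samples errors with measured values
  short <- rereference_average(noise_recording(nch = 32, n = 5000, seed = 7))
  expect_error(prepare_ica_input(short, annotations()), "retained samples")
})

test_that("infomax recovers super-Gaussian sources and is seed-deterministic", {
  toy <- toy_sources()
  dec <- run_ica(toy$X, seed = 3, effective_rank = 2)
  cc <- abs(cor(t(dec$activations), t(toy$S)))
  matched <- min(apply(cc, 1, max))
  expect_gte(matched, 0.95)
  # same inputs + seed -> identical matrices
  dec2 <- run_ica(toy$X, seed = 3, effective_rank = 2)
  expect_identical(dec$mixing, dec2$mixing)
  expect_identical(dec$unmixing, dec2$unmixing)
  # unmixing . mixing ~ identity on the retained subspace
  expect_lt(max(abs(dec$unmixing %*% dec$mixing - diag(2))), 1e-6)
  # components ordered by descending back-projected variance
  expect_true(all(diff(dec$bp_variance) <= 1e-9))
})

test_that("fastica engine also separates the toy mix", {
  toy <- toy_sources(seed = 2)
  dec <- run_ica(toy$X, method = "fastica", seed = 4, effective_rank = 2)
  cc <- abs(cor(t(dec$activations), t(toy$S)))
  expect_gte(min(apply(cc, 1, max)), 0.95)
  dec2 <- run_ica(toy$X, method = "fastica", seed = 4, effective_rank = 2)
  expect_identical(dec$mixing, dec2$mixing)
})

test_that("rank-deficient input yields exactly rank-many components", {
  toy <- toy_sources()
  X3 <- rbind(toy$X, toy$X[1, ] + toy$X[2, ])   # 3 channels, rank 2
  dec <- run_ica(X3, seed = 5)
  expect_identical(dec$effective_rank, 2L)
  expect_identical(nrow(dec$activations), 2L)
  expect_identical(dim(dec$mixing), c(3L, 2L))
})

test_that("external AMICA adapter refuses to run without a binary", {
  expect_error(run_ica(toy_sources()$X, method = "amica_external", seed = 1,
                       effective_rank = 2), "binary")
})

test_that("component activation SD aligns windows to recording time", {
  # synthetic decomposition: 3 ICs, contiguous samples
  n <- 1000
  act <- rbind(rep(2, n), rnorm(n), rnorm(n))
  dec <- structure(list(activations = act, sample_index = 0:(n - 1),
                        effective_rank = 3L), class = "ica_decomposition")
  ws <- ic_activation_sd(dec, 1, sfreq = 100, total_s = 10)
  expect_identical(nrow(ws$values), 3L)          # rows = rank
  expect_true(all(ws$values[1, ] == 0))          # constant activation
  # one 10x burst window stands out against the row median
  act2 <- rbind(rnorm(n), rnorm(n), rnorm(n))
  act2[2, 301:400] <- act2[2, 301:400] * 10
  dec2 <- structure(list(activations = act2, sample_index = 0:(n - 1),
                         effective_rank = 3L), class = "ica_decomposition")
  ws2 <- ic_activation_sd(dec2, 1, 100, 10)
  expect_gt(ws2$values[2, 4], 8 * median(ws2$values[2, ]))
  # excised middle: sparse windows are marked missing
  keep <- c(0:249, 750:999)
  dec3 <- structure(list(activations = act[, keep + 1], sample_index = keep,
                         effective_rank = 3L), class = "ica_decomposition")
  ws3 <- ic_activation_sd(dec3, 1, 100, 10)
  expect_true(all(ws3$missing[, 4]))             # fully excised window
  expect_false(any(ws3$missing[, 1]))
})

test_that("IC time flags follow the stage label and fraction rule", {
  set.seed(3)
  v <- matrix(rnorm(200, 10, 0.5), 10, 20)
  ws <- losslessr:::new_window_stats("ic_sd", sprintf("IC%03d", 1:10), 1, 0:19, v)
  expect_identical(nrow(flag_ic_time(ws, 1)), 0L)    # stationary -> empty
  # 2-window burst on 40% of ICs -> one interval of 2 windows
  v2 <- v; v2[1:4, 11:12] <- 100
  ws2 <- losslessr:::new_window_stats("ic_sd", sprintf("IC%03d", 1:10), 1, 0:19, v2)
  tf <- flag_ic_time(ws2, 1, p_t = 0.2)
  expect_identical(nrow(tf), 1L)
  expect_equal(tf$onset, 10)
  expect_equal(tf$duration, 2)
  expect_identical(tf$label, "ic_sd1")
  expect_identical(flag_ic_time(ws2, 2, p_t = 0.2)$label, "ic_sd2")
})

test_that("back-projection reconstructs, zeroes, and partitions variance", {
  sim <- clean_sim(duration_s = 40, seed = 5)
  rec <- rereference_average(sim$recording)
  dec <- run_ica(rec$samples, seed = 2, effective_rank = 31)
  # nothing flagged: reconstruction equals the centered input
  proj <- backproject_retained(dec, integer(0), add_center = TRUE)
  relerr <- max(abs(proj$samples - rec$samples)) / max(abs(rec$samples))
  expect_lt(relerr, 1e-6)
  # everything flagged: zeros + warning
  expect_warning(pz <- backproject_retained(dec, seq_len(31)), "all")
  expect_true(all(pz$samples == 0))
  # per-channel variance partition: var(x) = var(kept) + var(cut) + 2 cov
  flags <- c(3L, 8L)
  kept <- backproject_retained(dec, flags)$samples
  cut <- backproject_retained(dec, setdiff(1:31, flags))$samples
  for (ci in c(1, 16, 32)) {
    vx <- var(rec$samples[ci, ])
    resid <- vx - var(kept[ci, ]) - var(cut[ci, ]) -
      2 * cov(kept[ci, ], cut[ci, ])
    expect_lt(abs(resid) / vx, 1e-6)
  }
})

test_that("heuristic labels find the planted blink and spare the brain source", {
  sim <- simulate_recording(sim_config(
    n_channels = 32, duration_s = 120, sfreq = 250, seed = 21,
    emg_rate_min = 0, line_amp_uv = 0))
  rec <- rereference_average(sim$recording)
  dec <- run_ica(rec$samples, seed = 9, effective_rank = 31)
  labels <- heuristic_ic_flags(dec, rec, sim$montage, line_freq = 60)
  # the component matching the planted blink topography carries "blink"
  bt <- sim$truth$blink_topography - mean(sim$truth$blink_topography)
  cc <- apply(dec$mixing, 2, function(a) abs(cor(a, bt)))
  blink_ic <- which.max(cc)
  expect_true("blink" %in% labels[[as.character(blink_ic)]])
  # the component matching the strongest alpha source gets no artifact label
  st <- sim$truth$source_topographies
  st <- sweep(st, 2, colMeans(st))
  brain_ic <- which.max(apply(dec$mixing, 2, function(a)
    max(abs(cor(a, st)))))
  brain_labels <- setdiff(labels[[as.character(brain_ic)]], "low_power")
  expect_length(brain_labels, 0)
})

test_that("variance-share floor labels negligible components", {
  toy <- toy_sources()
  X <- rbind(toy$X, 1e-4 * rnorm(5000))
  m <- new_montage(c("a", "b", "c"),
                   rbind(c(0, 0.08, 0.02), c(0.05, 0, 0.06), c(0, -0.07, 0.03)))
  rec <- new_recording(X, 250, c("a", "b", "c"))
  dec <- run_ica(rec$samples, seed = 2, effective_rank = 3)
  labels <- heuristic_ic_flags(dec, rec, m, line_freq = 60,
                               low_power_share = 0.001)
  shares <- dec$bp_variance / sum(dec$bp_variance)
  expect_true(all(which(shares < 0.001) %in%
                    as.integer(names(labels)[vapply(labels, function(l)
                      "low_power" %in% l, TRUE)])))
})
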