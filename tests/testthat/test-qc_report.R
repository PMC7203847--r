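test_that("exclusive time accounting follows precedence and conserves time", {
  rec <- noise_recording(nch = 2, n = 100 * 10, sfreq = 10)  # 100 s
  # empty annotations: all retained
  ts <- time_summary(annotations(), rec)
  expect_setequal(ts$category, c("gap", "ch_s_sd", "ch_sd", "low_r",
                                 "ic_sd1", "ic_sd2", "manual", "retained"))
  expect_equal(ts$seconds[ts$category == "retained"], 100)
  expect_equal(ts$proportion[ts$category == "retained"], 1)
  # overlapping ch_sd [10,20) and low_r [15,25): precedence splits 10 / 5
  ann <- annotations(time_flags = losslessr:::make_intervals(
    c(10, 15), c(10, 10), c("ch_sd", "low_r")))
  ts <- time_summary(ann, rec)
  expect_equal(ts$seconds[ts$category == "ch_sd"], 10)
  expect_equal(ts$seconds[ts$category == "low_r"], 5)
  expect_equal(sum(ts$seconds), 100)
})

test_that("time and channel categories conserve totals on random annotations", {
  set.seed(77)
  rec <- noise_recording(nch = 16, n = 50 * 20, sfreq = 20)  # 50 s
  for (i in 1:100) {
    k <- sample(0:6, 1)
    tf <- if (k > 0) losslessr:::make_intervals(
      onset = runif(k, 0, 45),
      duration = runif(k, 0.1, 5),
      label = sample(losslessr:::TIME_FLAG_LABELS, k, replace = TRUE))
    else losslessr:::empty_intervals()
    nch_f <- sample(0:8, 1)
    cf <- if (nch_f > 0) stats::setNames(
      lapply(seq_len(nch_f), function(j)
        sample(losslessr:::CHANNEL_FLAG_LABELS, sample(1:2, 1))),
      sample(rec$labels, nch_f)) else list()
    ann <- annotations(channel_flags = cf, time_flags = tf)
    ts <- time_summary(ann, rec)
    expect_identical(sum(ts$samples), 50L * 20L)    # exact conservation
    expect_lt(abs(sum(ts$proportion) - 1), 1e-9)
    cs <- channel_summary(ann, 16)
    expect_identical(sum(cs$count), 16L)
    expect_lt(abs(sum(cs$proportion) - 1), 1e-9)
  }
})

test_that("channel accounting applies precedence and exact proportions", {
  # 13 of 65 flagged -> retention 0.8
  cf <- stats::setNames(rep(list("ch_sd"), 13), sprintf("E%03d", 1:13))
  cs <- channel_summary(annotations(channel_flags = cf), 65)
  expect_equal(cs$proportion[cs$category == "retained"], 0.8)
  # both ch_sd and bridge: counted once, under ch_sd
  ann <- annotations(channel_flags = list(E001 = c("bridge", "ch_sd")))
  cs <- channel_summary(ann, 65)
  expect_identical(cs$count[cs$category == "ch_sd"], 1L)
  expect_identical(cs$count[cs$category == "bridge"], 0L)
  cs0 <- channel_summary(annotations(), 65)
  expect_equal(cs0$proportion[cs0$category == "retained"], 1)
})

test_that("spatial variance is the cross-channel SD at each sample", {
  rec <- new_recording(rbind(c(1, 2, 5), c(3, 2, 5)), 1, c("a", "b"))
  sv <- spatial_variance(rec)
  expect_equal(sv$per_sample, c(sqrt(2), 0, 0))
  # homogeneity: scaling samples x2 scales the SD x2
  rec2 <- rec; rec2$samples <- rec2$samples * 2
  expect_equal(spatial_variance(rec2)$per_sample, 2 * sv$per_sample)
  expect_error(spatial_variance(new_recording(matrix(1, 1, 3), 1, "a")), ">= 2")
  # annotations restrict the time average to retained samples
  rec3 <- noise_recording(nch = 4, n = 100, sfreq = 10)
  ann <- annotations(time_flags = losslessr:::make_intervals(0, 5, "ch_sd"))
  sv3 <- spatial_variance(rec3, ann)
  expect_equal(sv3$mean, mean(sv3$per_sample[51:100]))
})

test_that("component variance shares are normalized and reflect the split", {
  toy_n <- 5000
  set.seed(12)
  # two separable sources with known amplitude ratio
  S <- rbind(3 * sign(rnorm(toy_n)) * rexp(toy_n), sign(rnorm(toy_n)) * rexp(toy_n))
  A <- matrix(c(1, 0.2, -0.3, 1), 2, 2)
  dec <- run_ica(A %*% S, seed = 6, effective_rank = 2)
  icv0 <- ic_variance_summary(dec, integer(0))
  expect_equal(icv0$retained_share, 1)
  icv <- ic_variance_summary(dec, 1L)
  expect_lt(abs(icv$retained_share + icv$flagged_share - 1), 1e-6)
  expect_lt(icv$retained_share, 0.5)   # the dominant component was flagged
})

test_that("spectral profile resolves a tone and stays flat on white noise", {
  t <- seq(1 / 250, 60, by = 1 / 250)
  rec <- new_recording(rbind(sin(2 * pi * 10 * t), rnorm(length(t))),
                       250, c("Cz", "E002"))
  p <- psd_profile(rec, "Cz")
  expect_true(all(p$freq >= 1 & p$freq <= 30))
  peak <- p$freq[which.max(p$power)]
  expect_lt(abs(peak - 10), 0.5)
  expect_gt(max(p$power), 20 * median(p$power[abs(p$freq - 10) > 2]))
  # white noise: bounded ripple under segment averaging at 300 s
  rec2 <- noise_recording(nch = 2, n = 300 * 250, sfreq = 250,
                          labels = c("Cz", "E002"))
  p2 <- psd_profile(rec2, "Cz")
  expect_lt(max(p2$power) / min(p2$power), 3)
  # missing channel resolved via nearest montage position
  m <- standard_montage(32)
  rec3 <- noise_recording(nch = 32, n = 2500, sfreq = 250, labels = m$labels)
  rec3$labels[1] <- "VTX"; rownames(rec3$samples)[1] <- "VTX"
  rec3$montage <- new_montage(rec3$labels, m$positions)
  p3 <- psd_profile(rec3, "Cz")
  expect_identical(unique(p3$channel), "VTX")
  expect_error(psd_profile(noise_recording(n = 2500), "Cz"), "not found")
})

test_that("QC report round-trips summaries and writes one block per recording", {
  sim <- clean_sim(duration_s = 30, seed = 9)
  rec <- rereference_average(sim$recording)
  ann <- annotations(
    channel_flags = list(E002 = "ch_sd"),
    time_flags = losslessr:::make_intervals(c(0, 20), c(3, 4), c("gap", "ch_sd")))
  s <- qc_summary(rec, ann, id = "rec01")
  out <- withr::local_tempdir()
  paths <- render_report(list(s), out)
  js <- jsonlite::read_json(file.path(out, "qc_summary.json"))
  expect_identical(js$n_recordings, 1L)
  expect_length(js$recordings, 1)
  blk <- js$recordings[[1]]
  expect_identical(blk$id, "rec01")
  expect_equal(blk$spatial_sd_uv, s$spatial_sd_uv, tolerance = 1e-12)
  got_ts <- vapply(blk$time, function(r) r$seconds, 0)
  expect_equal(got_ts, s$time$seconds, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(file.exists(file.path(out, "qc_summary.tsv")))
  expect_error(render_report(list(), out), "empty")
})
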