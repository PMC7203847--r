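# Shared fixtures, built in code at test time.

# small white-noise recording
noise_recording <- function(nch = 8, n = 1000, sfreq = 250, seed = 42,
                            labels = sprintf("ch%02d", seq_len(nch))) {
  set.seed(seed)
  new_recording(matrix(rnorm(nch * n), nch), sfreq, labels)
}

# the planted-defect study fixture: 2 bad channels (x10 gain), 1 flat,
# 1 bridged neighbor pair, 1 decoupled channel, movement bursts
defect_sim <- function(duration_s = 300, seed = 1, movement_bursts = 4) {
  m <- standard_montage(32)
  nb <- losslessr:::nearest_neighbors(m, m$labels, 1)
  mate <- nb[[match("E011", m$labels)]]
  cfg <- sim_config(n_channels = 32, duration_s = duration_s, sfreq = 250,
                    seed = seed, movement_bursts = movement_bursts,
                    bad_channels = c("E005", "E017"),
                    flat_channels = "E009",
                    bridged_pairs = list(c("E011", mate)),
                    decoupled_channels = "E020")
  simulate_recording(cfg)
}

# artifact-free: no blinks, EMG, movement, mains or planted defects
clean_sim <- function(duration_s = 300, seed = 2) {
  simulate_recording(sim_config(n_channels = 32, duration_s = duration_s,
                                sfreq = 250, seed = seed,
                                blink_rate_min = 0, emg_rate_min = 0,
                                line_amp_uv = 0))
}

# run the non-ICA part of the pipeline on one simulated recording, pooling
# the study envelope from the recording itself
annotate_no_ica <- function(sim, seed = 5) {
  cfg <- validate_config(list(stages = list(ica = FALSE)))
  rec <- notch_filter(sim$recording, 60)
  env <- estimate_study_envelope(list(window_sd(rec)))
  cfg$notch_harmonics <- 0
  suppressWarnings(
    annotate_recording(rec, env, cfg, montage = sim$montage, seed = seed))
}

# precision/recall of predicted channel labels against truth, with the
# study-level and subject-level voltage-variance flags counted as one
# criterion family
channel_pr <- function(truth_channels, channel_flags, criterion) {
  fam <- function(x) if (criterion == "ch_sd") x %in% c("ch_sd", "ch_s_sd") else criterion %in% x
  truth_set <- names(truth_channels)[vapply(truth_channels, function(l)
    criterion %in% l, TRUE)]
  pred_set <- names(channel_flags)[vapply(channel_flags, fam, TRUE)]
  tp <- length(intersect(truth_set, pred_set))
  list(recall = if (length(truth_set)) tp / length(truth_set) else NA_real_,
       precision = if (length(pred_set)) tp / length(pred_set) else NA_real_,
       truth = truth_set, pred = pred_set)
}

# fraction of truth intervals covered >= min overlap by predicted intervals
interval_recall <- function(truth_iv, pred_iv, min_overlap = 0.5) {
  if (!nrow(truth_iv)) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth_iv)), function(i)
    losslessr:::interval_overlap_fraction(truth_iv$onset[i], truth_iv$duration[i],
                                          pred_iv) >= min_overlap, TRUE)
  mean(hit)
}
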