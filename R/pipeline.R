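# Batch orchestration of the full annotation flow, and the purge utility
# that applies reviewed annotations for post-processing.

log_msg <- function(level, cfg_level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[cfg_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

# fraction of each window covered by intervals (for excluding already-flagged
# windows from later comparison populations)
windows_covered <- function(onsets, window_s, iv, min_frac = 0.5) {
  if (!nrow(iv)) return(rep(FALSE, length(onsets)))
  vapply(onsets, function(o)
    interval_overlap_fraction(o, window_s, iv) >= min_frac, TRUE)
}

#' Annotate a single recording
#'
#' The per-recording core of the pipeline: staging flags from the pooled
#' study envelope, average re-reference excluding staging-flagged channels,
#' subject-level voltage-variance and neighbor-correlation criteria, gap
#' marking, then two ICA stages with component-variance time flagging and
#' heuristic component labels. Returns annotations plus the staged recording
#' and the stage-2 decomposition; the input recording is never modified.
#'
#' @param rec an `eeg_recording` (montage attached or supplied).
#' @param env pooled [estimate_study_envelope()]; NULL skips staging flags.
#' @param cfg a [validate_config()] result.
#' @param montage montage (defaults to the recording's own).
#' @param seed per-recording seed (defaults to `cfg$seed`).
#' @return list: `ann`, `rec` (staged), `dec` (stage-2 or NULL),
#'   `staged_sd` windowed statistic.
#' @export
annotate_recording <- function(rec, env, cfg = validate_config(list()),
                               montage = rec$montage, seed = cfg$seed) {
  if (is.null(montage)) stopf("annotate_recording: no montage available")
  ann <- annotations()
  win <- cfg$window_s

  rec <- notch_filter(rec, cfg$line_freq, cfg$notch_harmonics)

  # study-level staging (on raw-referenced data, so catastrophic channels
  # cannot poison the average reference)
  if (!is.null(env) && isTRUE(cfg$stages$staging)) {
    ws0 <- window_sd(rec, win)
    st <- flag_staging(ws0, env, cfg$fractions$p_ch, cfg$fractions$p_t)
    ann <- add_channel_flags(ann, st$channels, "ch_s_sd")
    ann <- add_time_flags(ann, st$time)
  }

  # dead electrodes must be caught on raw-referenced data: the average
  # reference would re-inject the common signal into a flat channel
  if (isTRUE(cfg$stages$flagging)) {
    ws_raw <- window_sd(rec, win, rows = setdiff(rec$labels, flagged_channels(ann)))
    med_all <- stats::median(ws_raw$values)
    row_med <- apply(ws_raw$values, 1, stats::median)
    flat <- ws_raw$row_labels[row_med <= 0.05 * med_all]
    ann <- add_channel_flags(ann, flat, "ch_sd")
  }

  rec <- rereference_average(rec, exclude = flagged_channels(ann))

  if (isTRUE(cfg$stages$flagging)) {
    prior_ch <- flagged_channels(ann)
    rows <- setdiff(rec$labels, prior_ch)
    ws <- window_sd(rec, win, rows = rows)
    mask <- robust_outlier_mask(ws, "across-rows", cfg$envelope$pL,
                                cfg$envelope$pU, cfg$envelope$k)
    covered <- windows_covered(ws$onsets, win, ann$time_flags)
    mask$mask[, covered] <- FALSE
    ch_sd <- flag_channels_sd(mask, cfg$fractions$p_ch, ws = ws)
    ann <- add_channel_flags(ann, ch_sd, "ch_sd")
    ann <- add_time_flags(ann, flag_time_sd(mask, cfg$fractions$p_t,
                                            exclude = ch_sd, label = "ch_sd"))

    rows2 <- setdiff(rows, ch_sd)
    nr <- neighbor_r(rec, montage, cfg$k_neighbors, win, rows = rows2)
    bridged <- flag_bridge(nr, cfg$bridge$r_median_min, cfg$bridge$r_dispersion_max)
    ann <- add_channel_flags(ann, bridged, "bridge")
    covered2 <- windows_covered(nr$onsets, win, ann$time_flags)
    nr2 <- nr
    nr2$values <- nr$values[, !covered2, drop = FALSE]
    nr2$missing <- nr$missing[, !covered2, drop = FALSE]
    nr2$onsets <- nr$onsets[!covered2]
    lr <- flag_low_r(nr2, cfg$low_r$pL, cfg$low_r$pU, cfg$low_r$k,
                     cfg$low_r$p_ch, cfg$low_r$p_t, exclude = bridged)
    ann <- add_channel_flags(ann, lr$channels, "low_r")
    ann <- add_time_flags(ann, lr$time)
  }

  ann <- add_time_flags(ann, mark_gaps(rec$events, rec, cfg$max_gap_s))

  dec2 <- NULL
  if (isTRUE(cfg$stages$ica)) {
    excl <- TIME_FLAG_LABELS
    if (!isTRUE(cfg$ica$exclude_gap)) excl <- setdiff(excl, "gap")
    dur <- recording_duration(rec)
    run_stage <- function(stage, ann) {
      prep <- prepare_ica_input(rec, ann, exclude_time_labels = excl)
      dec <- run_ica(prep, method = cfg$ica$method, seed = seed + stage,
                     stage = stage, max_steps = cfg$ica$max_steps,
                     amica_binary = cfg$ica$amica_binary)
      ws <- ic_activation_sd(dec, win, rec$sfreq, dur)
      flags <- flag_ic_time(ws, stage, cfg$ica$envelope$pL, cfg$ica$envelope$pU,
                            cfg$ica$envelope$k, cfg$ica$p_t)
      list(dec = dec, flags = flags)
    }
    s1 <- run_stage(1, ann)
    ann <- add_time_flags(ann, s1$flags)
    s2 <- run_stage(2, ann)
    ann <- add_time_flags(ann, s2$flags)
    dec2 <- s2$dec
    icf <- heuristic_ic_flags(dec2, rec, montage, line_freq = cfg$line_freq,
                              low_power_share = cfg$ica$low_power_share)
    for (k in names(icf)) ann <- add_ic_flags(ann, k, icf[[k]])
  }

  list(ann = ann, rec = rec, dec = dec2)
}

#' Run the pipeline over a BIDS dataset
#'
#' Scans the dataset, pools windowed voltage variance across all recordings
#' into the study envelope, annotates each recording
#' (staging flags, channel/time criteria, two ICA stages, component labels),
#' writes a lossless derivative per recording and a QC report, and returns a
#' run manifest. Failures are isolated per recording: one corrupt file is
#' logged and the rest continue.
#'
#' @param cfg a [validate_config()] result (needs `dataset_root`; output
#'   defaults to the dataset root).
#' @return list (class `pipeline_run`): `status` (`"ok"`, `"partial"` or
#'   `"failed"`), `manifest` data.frame (one row per recording, ok/failed +
#'   message), `summaries`, `derivative_root`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  if (is.null(cfg$dataset_root)) stopf("run_pipeline: dataset_root not set")
  out_root <- cfg$output_root %||% cfg$dataset_root
  man <- scan_dataset(cfg$dataset_root)
  if (!is.null(cfg$subjects)) man <- man[man$subject %in% cfg$subjects, , drop = FALSE]
  if (!nrow(man)) stopf("run_pipeline: no recordings selected")
  log_msg("info", cfg$log_level, "run_pipeline: %d recording(s)", nrow(man))

  recs <- vector("list", nrow(man))
  stats <- list()
  status <- character(nrow(man)); msg <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    recs[i] <- list(tryCatch({
      r <- read_recording(man[i, ])
      r <- notch_filter(r, cfg$line_freq, cfg$notch_harmonics)
      stats[[length(stats) + 1L]] <- window_sd(r, cfg$window_s)
      r
    }, error = function(e) { msg[i] <<- conditionMessage(e); NULL }))
  }
  ok_read <- !vapply(recs, is.null, TRUE)
  if (!any(ok_read)) stopf("run_pipeline: every recording failed to load")
  env <- if (isTRUE(cfg$stages$staging))
    estimate_study_envelope(stats, cfg$envelope$pL, cfg$envelope$pU, cfg$envelope$k)
  else NULL

  summaries <- list()
  for (i in seq_len(nrow(man))) {
    if (!ok_read[i]) { status[i] <- "failed"; next }
    id <- paste0("sub-", man$subject[i],
                 ifelse(is.na(man$task[i]), "", paste0("_task-", man$task[i])))
    res <- tryCatch({
      rec <- recs[[i]]
      # the staging notch is already applied during the pooling pass
      cfg_i <- cfg; cfg_i$notch_harmonics <- 0
      out <- annotate_recording(rec, env, cfg_i, montage = rec$montage,
                                seed = cfg$seed + i)
      base <- write_derivative(rec, out$ann, out_root, overwrite = cfg$overwrite,
                               extra = list(config = unclass(cfg),
                                            pipeline_version = as.character(
                                              utils::packageVersion("losslessr"))))
      summaries[[id]] <- qc_summary(out$rec, out$ann, out$dec, id = id)
      "ok"
    }, error = function(e) { msg[i] <<- conditionMessage(e); "failed" })
    status[i] <- res
    log_msg(if (res == "ok") "info" else "warn", cfg$log_level,
            "%s: %s%s", id, status[i], ifelse(msg[i] == "", "", paste0(" (", msg[i], ")")))
  }
  manifest <- data.frame(subject = man$subject, task = man$task, path = man$path,
                         status = status, message = msg, stringsAsFactors = FALSE)
  run_status <- if (all(status == "ok")) "ok" else if (any(status == "ok")) "partial" else "failed"
  deriv <- file.path(out_root, "derivatives", "lossless")
  jsonlite::write_json(list(status = run_status, manifest = manifest,
                            seed = cfg$seed),
                       file.path(deriv, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  if (length(summaries))
    render_report(summaries, file.path(deriv, "qc"))
  structure(list(status = run_status, manifest = manifest,
                 summaries = summaries, envelope = env,
                 derivative_root = deriv),
            class = "pipeline_run")
}

#' Apply annotations to produce a reduced recording (purge)
#'
#' Downstream application of the quality annotations: drops flagged
#' channels, removes flagged components (replacing the signal by the
#' retained back-projection), and excises flagged time, in that order. The
#' original recording is untouched. Purging refuses unreviewed annotations
#' unless `allow_unreviewed` is set, encoding the review gate of the manual
#' QC step.
#'
#' @param rec an `eeg_recording`.
#' @param ann an [annotations()] object.
#' @param dec stage-2 `ica_decomposition` (required when `"ics"` is
#'   requested and components are flagged).
#' @param what subset of `c("channels", "ics", "time")`.
#' @param allow_unreviewed bypass the review gate.
#' @return the reduced recording, with the reduction logged in provenance.
#' @export
purge_recording <- function(rec, ann, dec = NULL,
                            what = c("channels", "ics", "time"),
                            allow_unreviewed = FALSE) {
  what <- match.arg(what, several.ok = TRUE)
  if (ann$review_state != "reviewed" && !allow_unreviewed)
    stopf("purge: annotations are unreviewed (review them or set allow_unreviewed)")
  validate_annotations(ann, rec)
  out <- rec
  if ("channels" %in% what) {
    keep <- setdiff(out$labels, flagged_channels(ann))
    if (!length(keep)) stopf("purge: no channels retained")
    out$samples <- out$samples[keep, , drop = FALSE]
    out$labels <- keep
    out <- with_provenance(out, sprintf("purge_channels(%d dropped)",
                                        n_channels(rec) - length(keep)))
  }
  if ("ics" %in% what && length(ann$ic_flags)) {
    if (is.null(dec)) stopf("purge: components are flagged but no decomposition given")
    proj <- backproject_retained(dec, ann$ic_flags, add_center = TRUE)
    rows <- intersect(out$labels, proj$labels)
    cols <- proj$sample_index + 1L
    out$samples[rows, cols] <- proj$samples[rows, , drop = FALSE]
    out <- with_provenance(out, sprintf("purge_ics(%d removed)", length(ann$ic_flags)))
  }
  if ("time" %in% what) {
    mask <- intervals_to_mask(ann$time_flags, n_samples(out), out$sfreq)
    if (all(mask)) stopf("purge: no time retained")
    if (any(mask)) {
      keep_idx <- which(!mask)
      # remap event onsets onto the purged timeline; drop events in cut time
      if (nrow(out$events)) {
        ev <- out$events
        smp <- as.integer(floor(ev$onset * out$sfreq)) + 1L
        kept <- !mask[pmin(smp, length(mask))]
        newpos <- cumsum(!mask)
        ev <- ev[kept, , drop = FALSE]
        ev$onset <- (newpos[smp[kept]] - 1L) / out$sfreq
        ev$duration <- pmin(ev$duration, (sum(!mask) / out$sfreq) - ev$onset)
        out$events <- ev
      }
      out$samples <- out$samples[, keep_idx, drop = FALSE]
      out <- with_provenance(out, sprintf("purge_time(%.3f s removed)",
                                          sum(mask) / rec$sfreq))
    }
  }
  out
}
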