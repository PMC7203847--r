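# QC diagnostics: exclusive time/channel/component accounting, spatial
# variance, and pre/post power-spectrum profiles.

TIME_PRECEDENCE <- c("gap", "ch_s_sd", "ch_sd", "low_r", "ic_sd1", "ic_sd2", "manual")
CHANNEL_PRECEDENCE <- c("ch_s_sd", "ch_sd", "bridge", "low_r", "manual")

#' Exclusive time accounting per flag category
#'
#' Assigns every sample to exactly one category by precedence
#' `gap > ch_s_sd > ch_sd > low_r > ic_sd1 > ic_sd2 > manual > retained`
#' (pipeline order: a sample flagged by an early coarse criterion is counted
#' there even if later criteria flagged it too). Seconds are sample counts
#' divided by the sampling rate, so the categories sum to the recording
#' duration exactly.
#'
#' @param ann an [annotations()] object.
#' @param rec the recording.
#' @return data.frame with category, seconds, proportion.
#' @export
time_summary <- function(ann, rec) {
  n <- n_samples(rec)
  assigned <- rep(NA_character_, n)
  for (lab in TIME_PRECEDENCE) {
    m <- intervals_to_mask(time_flags_of(ann, lab), n, rec$sfreq)
    assigned[is.na(assigned) & m] <- lab
  }
  assigned[is.na(assigned)] <- "retained"
  cats <- c(TIME_PRECEDENCE, "retained")
  cnt <- vapply(cats, function(cg) sum(assigned == cg), 0L)
  # conservation is exact at the sample level; seconds are counts / sfreq
  data.frame(category = cats, samples = cnt,
             seconds = as.numeric(cnt) / rec$sfreq,
             proportion = as.numeric(cnt) / n,
             stringsAsFactors = FALSE)
}

#' Exclusive channel accounting per flag category
#'
#' Counts each channel once, under its highest-precedence flag
#' (`ch_s_sd > ch_sd > bridge > low_r > manual`), with unflagged channels
#' counted as retained; proportions are over the full channel count.
#'
#' @param ann an [annotations()] object.
#' @param n_channels total channel count of the recording.
#' @return data.frame with category, count, proportion.
#' @export
channel_summary <- function(ann, n_channels) {
  assigned <- vapply(ann$channel_flags, function(flags) {
    hit <- CHANNEL_PRECEDENCE[CHANNEL_PRECEDENCE %in% flags]
    if (length(hit)) hit[1] else NA_character_
  }, "")
  cats <- c(CHANNEL_PRECEDENCE, "retained")
  cnt <- vapply(CHANNEL_PRECEDENCE, function(cg) sum(assigned == cg, na.rm = TRUE), 0L)
  cnt <- c(cnt, retained = n_channels - sum(cnt))
  data.frame(category = cats, count = as.integer(cnt),
             proportion = as.integer(cnt) / n_channels,
             stringsAsFactors = FALSE)
}

#' Spatial variance: SD across channels at each time point
#'
#' The signal-magnitude diagnostic used for component accounting: the sample
#' standard deviation over channel values at every sample, and its time
#' average (restricted to retained time when annotations are supplied).
#'
#' @param rec an `eeg_recording`, or any channels x time matrix.
#' @param ann optional [annotations()]; flagged time is excluded from the
#'   time average.
#' @return list with `per_sample` (uV) and `mean` (uV).
#' @export
spatial_variance <- function(rec, ann = NULL) {
  X <- if (inherits(rec, "eeg_recording")) rec$samples else as.matrix(rec)
  if (nrow(X) < 2) stopf("spatial_variance: need >= 2 channels")
  mu <- colMeans(X)
  ss <- sqrt(pmax(0, (colSums(X^2) - nrow(X) * mu^2) / (nrow(X) - 1)))
  keep <- rep(TRUE, length(ss))
  if (!is.null(ann) && inherits(rec, "eeg_recording")) {
    mask <- intervals_to_mask(time_flags_of(ann, TIME_PRECEDENCE),
                              n_samples(rec), rec$sfreq)
    keep <- !mask
  }
  list(per_sample = ss, mean = mean(ss[keep]))
}

#' Retained vs flagged component variance shares
#'
#' Shares of scalp signal accounted for by retained vs flagged components,
#' computed from the time-averaged spatial SD of the two back-projections
#' and normalized to sum to one.
#'
#' @param dec a stage-2 `ica_decomposition`.
#' @param ic_flags flagged component indices (or annotation `ic_flags` list).
#' @return list with `retained_share`, `flagged_share`, `retained_spatial_sd`
#'   and `flagged_spatial_sd` (uV).
#' @export
ic_variance_summary <- function(dec, ic_flags = integer(0)) {
  if (is.list(ic_flags)) ic_flags <- as.integer(names(ic_flags))
  proj_r <- backproject_retained(dec, ic_flags)
  r <- nrow(dec$activations)
  flagged <- intersect(seq_len(r), ic_flags)
  sd_r <- if (nrow(proj_r$samples) >= 2) spatial_variance(proj_r$samples)$mean else 0
  sd_f <- if (length(flagged)) {
    pf <- suppressWarnings(backproject_retained(dec, setdiff(seq_len(r), flagged)))
    if (nrow(pf$samples) >= 2) spatial_variance(pf$samples)$mean else 0
  } else 0
  tot <- sd_r + sd_f
  if (tot == 0) tot <- 1
  list(retained_share = sd_r / tot, flagged_share = sd_f / tot,
       retained_spatial_sd = sd_r, flagged_spatial_sd = sd_f)
}

#' Power-spectrum profile of one channel
#'
#' Averaged-periodogram estimate (2 s Hann segments, 50% overlap) restricted
#' to `[fmin, fmax]`. The channel is resolved by label, with a
#' nearest-position fallback (e.g. the vertex) for layouts lacking it.
#'
#' @param rec an `eeg_recording`.
#' @param channel channel label (default `"Cz"`).
#' @param fmin,fmax frequency band in Hz (defaults 1 and 30).
#' @param montage optional montage for the nearest-position fallback.
#' @param fallback_position 3D position used when the label is absent.
#' @return data.frame with freq (Hz) and power (uV^2/Hz).
#' @export
psd_profile <- function(rec, channel = "Cz", fmin = 1, fmax = 30,
                        montage = rec$montage, fallback_position = c(0, 0, 0.09)) {
  if (recording_duration(rec) < 4)
    stopf("psd_profile: recording shorter than 4 s")
  if (!channel %in% rec$labels) {
    if (is.null(montage)) stopf("psd_profile: channel '%s' not found", channel)
    shared <- intersect(rec$labels, montage$labels)
    if (!length(shared)) stopf("psd_profile: channel '%s' not found", channel)
    d <- sqrt(rowSums(sweep(montage$positions[shared, , drop = FALSE], 2,
                            fallback_position, `-`)^2))
    channel <- shared[which.min(d)]
  }
  p <- welch_psd(rec$samples[channel, ], rec$sfreq, seg_s = 2, overlap = 0.5)
  keep <- p$freq >= fmin & p$freq <= fmax
  data.frame(freq = p$freq[keep], power = p$power[keep], channel = channel,
             stringsAsFactors = FALSE)
}

#' Per-recording QC summary
#'
#' Bundles the diagnostic surfaces for one recording: exclusive time and
#' channel accounting, spatial-SD time average, component variance shares
#' and the pre/post-QC power spectrum at the vertex. Post-QC means flagged
#' time excised and flagged components removed before estimation.
#'
#' @param rec the recording (after staging, e.g. average-referenced).
#' @param ann final [annotations()].
#' @param dec optional stage-2 `ica_decomposition`.
#' @param id recording identifier string.
#' @param channel PSD channel label.
#' @return a `qc_summary` list.
#' @export
qc_summary <- function(rec, ann, dec = NULL, id = "recording", channel = "Cz") {
  ts <- time_summary(ann, rec)
  cs <- channel_summary(ann, n_channels(rec))
  sv <- spatial_variance(rec, ann)
  icv <- if (!is.null(dec)) ic_variance_summary(dec, ann$ic_flags) else NULL
  pre <- tryCatch(psd_profile(rec, channel), error = function(e) NULL)
  post <- NULL
  if (!is.null(pre)) {
    post_rec <- tryCatch(
      purge_recording(rec, mark_reviewed(ann), dec = dec,
                      what = c("channels", "ics", "time")),
      error = function(e) NULL)
    if (!is.null(post_rec) && recording_duration(post_rec) >= 4)
      post <- tryCatch(psd_profile(post_rec, channel), error = function(e) NULL)
  }
  structure(list(id = id, total_s = recording_duration(rec),
                 time = ts, channels = cs,
                 spatial_sd_uv = sv$mean,
                 ic_variance = icv, psd_pre = pre, psd_post = post),
            class = "qc_summary")
}

#' Write a QC report
#'
#' Emits one JSON block per recording plus an aggregate, a flat tab-separated
#' table of all summary numbers (for cross-site aggregation), and diagnostic
#' plots: time/channel accounting pies, spatial-SD histogram, and the
#' pre/post spectral profile with per-frequency median and 2.5/97.5%
#' quantiles across recordings.
#'
#' @param summaries non-empty list of [qc_summary()] objects.
#' @param out_dir output directory (created if needed).
#' @param plots write PNG figures (default TRUE).
#' @return invisibly, the paths written.
#' @export
render_report <- function(summaries, out_dir, plots = TRUE) {
  if (!length(summaries)) stopf("render_report: empty summary list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- lapply(summaries, function(s) {
    list(id = s$id, total_s = s$total_s,
         time = s$time, channels = s$channels,
         spatial_sd_uv = s$spatial_sd_uv,
         ic_retained_share = s$ic_variance$retained_share %||% NA)
  })
  json_path <- file.path(out_dir, "qc_summary.json")
  jsonlite::write_json(list(n_recordings = length(summaries), recordings = blocks),
                       json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  flat <- do.call(rbind, lapply(summaries, function(s) {
    tm <- stats::setNames(s$time$proportion, paste0("time_", s$time$category))
    ch <- stats::setNames(s$channels$proportion, paste0("ch_", s$channels$category))
    data.frame(id = s$id, total_s = s$total_s, t(tm), t(ch),
               spatial_sd_uv = s$spatial_sd_uv,
               ic_retained_share = s$ic_variance$retained_share %||% NA,
               stringsAsFactors = FALSE)
  }))
  tsv_path <- file.path(out_dir, "qc_summary.tsv")
  write_tsv(flat, tsv_path)
  paths <- c(json_path, tsv_path)
  if (plots) paths <- c(paths, render_report_plots(summaries, out_dir))
  invisible(paths)
}

render_report_plots <- function(summaries, out_dir) {
  paths <- character(0)
  mean_prop <- function(get) {
    m <- Reduce(`+`, lapply(summaries, get)) / length(summaries)
    m
  }
  pal <- c(gap = "grey70", ch_s_sd = "darkred", ch_sd = "steelblue",
           low_r = "red", ic_sd1 = "magenta", ic_sd2 = "purple",
           bridge = "forestgreen", manual = "orange", retained = "darkblue")
  p1 <- file.path(out_dir, "time_accounting.png")
  grDevices::png(p1, 900, 450)
  graphics::par(mfrow = c(1, 2))
  tp <- mean_prop(function(s) stats::setNames(s$time$proportion, s$time$category))
  graphics::pie(tp[tp > 0], col = pal[names(tp[tp > 0])],
                main = "Time accounting (mean proportion)")
  graphics::hist(vapply(summaries, function(s)
    s$time$proportion[s$time$category == "retained"], 0),
    main = "Retained time per recording", xlab = "proportion", col = "steelblue")
  grDevices::dev.off()
  p2 <- file.path(out_dir, "channel_accounting.png")
  grDevices::png(p2, 900, 450)
  graphics::par(mfrow = c(1, 2))
  cp <- mean_prop(function(s) stats::setNames(s$channels$proportion, s$channels$category))
  graphics::pie(cp[cp > 0], col = pal[names(cp[cp > 0])],
                main = "Channel accounting (mean proportion)")
  graphics::hist(vapply(summaries, function(s) s$spatial_sd_uv, 0),
                 main = "Spatial SD", xlab = "uV", col = "darkblue")
  grDevices::dev.off()
  paths <- c(p1, p2)
  pres <- Filter(Negate(is.null), lapply(summaries, `[[`, "psd_pre"))
  if (length(pres)) {
    p3 <- file.path(out_dir, "psd_profile.png")
    grDevices::png(p3, 900, 450)
    f <- pres[[1]]$freq
    mat <- vapply(pres, function(p) p$power[seq_along(f)], f)
    med <- apply(mat, 1, stats::median)
    qs <- apply(mat, 1, stats::quantile, c(0.025, 0.975))
    graphics::matplot(f, log10(mat), type = "l", lty = 1, col = "grey80",
                      xlab = "Hz", ylab = "log10 power",
                      main = "Spectral profile (pre grey/black, post blue)")
    graphics::lines(f, log10(med), lwd = 2)
    graphics::lines(f, log10(qs[1, ]), col = "red")
    graphics::lines(f, log10(qs[2, ]), col = "red")
    posts <- Filter(Negate(is.null), lapply(summaries, `[[`, "psd_post"))
    if (length(posts)) {
      pmat <- vapply(posts, function(p) stats::approx(p$freq, p$power, f, rule = 2)$y, f)
      graphics::lines(f, log10(apply(pmat, 1, stats::median)), col = "blue", lwd = 2)
    }
    grDevices::dev.off()
    paths <- c(paths, p3)
  }
  paths
}
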