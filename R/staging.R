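# Staging: harmonize recordings into a comparable state (common head
# surface, mains removal, average reference) and apply the pooled
# study-level voltage-variance criterion (flag label ch_s_sd).

#' Remove mains interference (regression notch)
#'
#' Estimates the line-frequency sinusoid (and its harmonics) by weighted
#' least squares in overlapping Hann-weighted windows and subtracts the
#' fitted component, channel by channel. Unlike a convolutional notch this
#' has no edge transient and leaves the passband untouched: only a band of
#' roughly +/- 1/window width around each harmonic is affected, far inside
#' the +/- 2 Hz tolerance, while a stationary tone at the line frequency is
#' suppressed to numerical precision (>> 30 dB). Windowing lets the fit
#' track slow drifts of line amplitude and phase.
#'
#' @param rec an `eeg_recording`.
#' @param line_freq mains frequency in Hz (must be below Nyquist).
#' @param harmonics number of harmonics fitted (fundamental counts as the
#'   first); harmonics at or above Nyquist are skipped.
#' @param win_s fitting-window length in seconds (default 4).
#' @return a new recording with provenance appended; the input is untouched.
#' @export
notch_filter <- function(rec, line_freq, harmonics = 1, win_s = 4) {
  nyq <- rec$sfreq / 2
  if (line_freq >= nyq)
    stopf("notch_filter: line_freq %g Hz is at/above Nyquist (%g Hz)", line_freq, nyq)
  if (harmonics < 1) return(with_provenance(rec, "notch_filter(skipped)"))
  X <- rec$samples
  n <- ncol(X)
  freqs <- line_freq * seq_len(harmonics)
  freqs <- freqs[freqs < nyq]
  win <- min(n, as.integer(round(win_s * rec$sfreq)))
  hop <- max(1L, win %/% 2L)
  starts <- unique(c(seq(1L, max(1L, n - win + 1L), by = hop), n - win + 1L))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 0.5) / win)
  tt <- seq_len(n) / rec$sfreq
  fit <- matrix(0, nrow(X), n)
  wsum <- numeric(n)
  for (s in starts) {
    idx <- s:(s + win - 1L)
    D <- do.call(cbind, lapply(freqs, function(f)
      cbind(sin(2 * pi * f * tt[idx]), cos(2 * pi * f * tt[idx]))))
    Dw <- D * w
    beta <- solve(crossprod(Dw, D), crossprod(Dw, t(X[, idx, drop = FALSE])))
    fit[, idx] <- fit[, idx] + t(D %*% beta) * rep(w, each = nrow(X))
    wsum[idx] <- wsum[idx] + w
  }
  X <- X - fit / rep(pmax(wsum, 1e-12), each = nrow(X))
  out <- rec
  out$samples <- X
  rownames(out$samples) <- rec$labels
  with_provenance(out, sprintf("notch_filter(%g Hz x%d)", line_freq, harmonics))
}

#' Re-reference to the average of the scalp channels
#'
#' Subtracts, at every sample, the mean over the non-excluded channels from
#' every channel (excluded channels are re-expressed against the same
#' reference). Reduces the effective rank of the included set by exactly one.
#'
#' @param rec an `eeg_recording`.
#' @param exclude channel labels left out of the reference (e.g. channels
#'   already flagged `ch_s_sd`).
#' @return a new recording; the input is untouched.
#' @export
rereference_average <- function(rec, exclude = character(0)) {
  keep <- setdiff(rec$labels, exclude)
  if (length(keep) < 2)
    stopf("rereference_average: need >= 2 non-excluded channels (have %d)", length(keep))
  ref <- colMeans(rec$samples[keep, , drop = FALSE])
  out <- rec
  out$samples <- sweep(rec$samples, 2, ref, `-`)
  with_provenance(out, sprintf("rereference_average(n=%d)", length(keep)))
}

#' Pool windowed statistics into a study-level envelope
#'
#' Pools every channel-window value across recordings and derives the robust
#' envelope `[q50 - k (q50 - qL), q50 + k (qU - q50)]` from the pooled
#' distribution. The envelope is what makes `ch_s_sd` a *study-level*
#' criterion: one recording is judged against the whole cohort.
#'
#' @param stats_list list of [window_sd()] results (same statistic id).
#' @param pL,pU pooled quantile probabilities (defaults 0.3 / 0.7).
#' @param k dispersion multiplier (default 6).
#' @return a `study_envelope` (statistic, lower, upper, q50, k, n_recordings).
#' @export
estimate_study_envelope <- function(stats_list, pL = 0.3, pU = 0.7, k = 6) {
  if (!length(stats_list)) stopf("estimate_study_envelope: empty stats list")
  ids <- unique(vapply(stats_list, function(s) s$statistic, ""))
  if (length(ids) != 1)
    stopf("estimate_study_envelope: mixed statistic ids: %s", paste(ids, collapse = ", "))
  pooled <- unlist(lapply(stats_list, function(s) as.numeric(s$values)), use.names = FALSE)
  b <- robust_bounds(pooled, pL, pU, k)
  lo <- if (is.finite(b$lower)) b$lower else b$q50
  hi <- if (is.finite(b$upper)) b$upper else b$q50
  structure(list(statistic = ids, lower = lo, upper = hi, q50 = b$q50,
                 pL = pL, pU = pU, k = k, n_recordings = length(stats_list)),
            class = "study_envelope")
}

#' @export
print.study_envelope <- function(x, ...) {
  cat(sprintf("<study_envelope> %s in [%.4g, %.4g] (q50 %.4g, k=%g, %d recordings)\n",
              x$statistic, x$lower, x$upper, x$q50, x$k, x$n_recordings))
  invisible(x)
}

#' Study-level staging flags (ch_s_sd)
#'
#' Marks each channel-window cell whose value falls outside the pooled study
#' envelope, then flags channels whose outlier fraction over windows exceeds
#' `p_ch` and (after excluding those channels) windows whose outlier fraction
#' over channels exceeds `p_t`. Adjacent flagged windows are merged into
#' maximal intervals. All flags carry the label `ch_s_sd`.
#'
#' @param ws a [window_sd()] result for one recording.
#' @param env the pooled [estimate_study_envelope()].
#' @param p_ch,p_t strict fraction thresholds (defaults 0.2).
#' @return list with `channels` (labels) and `time` (interval data.frame).
#' @export
flag_staging <- function(ws, env, p_ch = 0.2, p_t = 0.2) {
  if (!identical(ws$statistic, env$statistic))
    stopf("flag_staging: statistic id '%s' does not match envelope '%s'",
          ws$statistic, env$statistic)
  out <- ws$values < env$lower | ws$values > env$upper
  out[is.na(out)] <- FALSE
  ch_frac <- rowMeans(out)
  chans <- ws$row_labels[ch_frac > p_ch]
  keep <- !(ws$row_labels %in% chans)
  time <- empty_intervals()
  if (any(keep)) {
    t_frac <- colMeans(out[keep, , drop = FALSE])
    time <- windows_to_intervals(t_frac > p_t, ws$onsets, ws$window_s, "ch_s_sd")
  }
  list(channels = chans, time = time)
}
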