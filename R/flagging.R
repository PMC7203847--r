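# Subject-level windowed statistics and the ch_sd, low_r, bridge and gap
# annotation criteria. The pipeline progresses from coarse voltage-variance
# outliers to fine-grained neighbor-correlation measures, each criterion
# excluding channels already flagged by earlier ones from its comparison
# population.

#' Windowed standard deviation per channel
#'
#' Sample SD (n-1 denominator) of each channel within consecutive
#' non-overlapping windows; a trailing partial window is dropped.
#'
#' @param rec an `eeg_recording`.
#' @param window_s window length in seconds (default 1).
#' @param rows optional channel subset (labels).
#' @return a `window_stats` object (statistic id `"sd"`, values in uV).
#' @export
window_sd <- function(rec, window_s = 1, rows = rec$labels) {
  npw <- as.integer(round(window_s * rec$sfreq))
  n <- n_samples(rec)
  if (npw > n) stopf("window_sd: window (%g s) longer than recording (%g s)",
                     window_s, recording_duration(rec))
  nwin <- n %/% npw
  X <- rec$samples[rows, seq_len(nwin * npw), drop = FALSE]
  vals <- t(apply(X, 1, function(x) {
    m <- matrix(x, nrow = npw)
    mu <- colMeans(m)
    sqrt(pmax(0, (colSums(m^2) - npw * mu^2) / (npw - 1)))
  }))
  new_window_stats("sd", rows, window_s, (seq_len(nwin) - 1) * window_s, vals)
}

new_window_stats <- function(statistic, row_labels, window_s, onsets, values,
                             missing = NULL, pair_r = NULL) {
  values <- matrix(values, nrow = length(row_labels),
                   dimnames = list(row_labels, NULL))
  structure(list(statistic = statistic, row_labels = as.character(row_labels),
                 window_s = window_s, onsets = onsets, values = values,
                 missing = missing, pair_r = pair_r),
            class = "window_stats")
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf("<window_stats> %s: %d rows x %d windows of %g s\n",
              x$statistic, nrow(x$values), ncol(x$values), x$window_s))
  invisible(x)
}

#' Robust outlier mask over a windowed-statistic matrix
#'
#' For each slice along the chosen axis (each window when comparing across
#' rows; each row when comparing across windows) computes the asymmetric
#' envelope `q50 +/- k * (one-sided inter-quantile distance)` from that slice
#' and marks cells outside it. Slices with zero dispersion on a side produce
#' no flags on that side. With `side = "low"` only the lower bound is
#' applied (used by the neighbor-correlation criterion, where only
#' *decoupled* channels are anomalous).
#'
#' @param ws a `window_stats`.
#' @param axis `"across-rows"` or `"across-windows"`.
#' @param pL,pU,k envelope parameters (defaults 0.3, 0.7, 6).
#' @param side `"both"` (default), `"low"` or `"high"`.
#' @return a `flag_matrix` (row labels, window onsets, logical mask).
#' @export
robust_outlier_mask <- function(ws, axis = c("across-rows", "across-windows"),
                                pL = 0.3, pU = 0.7, k = 6,
                                side = c("both", "low", "high")) {
  axis <- match.arg(axis)
  side <- match.arg(side)
  v <- ws$values
  slice_len <- if (axis == "across-rows") nrow(v) else ncol(v)
  if (slice_len < 3)
    stopf("robust_outlier_mask: need >= 3 entries along the comparison axis (have %d)",
          slice_len)
  mask <- matrix(FALSE, nrow(v), ncol(v))
  flag_slice <- function(x) {
    b <- robust_bounds(x, pL, pU, k)
    lo <- if (side == "high") -Inf else b$lower
    hi <- if (side == "low") Inf else b$upper
    out <- x < lo | x > hi
    out[is.na(out)] <- FALSE
    out
  }
  if (axis == "across-rows") {
    for (w in seq_len(ncol(v))) mask[, w] <- flag_slice(v[, w])
  } else {
    for (r in seq_len(nrow(v))) mask[r, ] <- flag_slice(v[r, ])
  }
  if (!is.null(ws$missing)) mask[ws$missing] <- FALSE
  structure(list(row_labels = ws$row_labels, onsets = ws$onsets,
                 window_s = ws$window_s, mask = mask),
            class = "flag_matrix")
}

#' Channel flags from a voltage-variance outlier mask (ch_sd)
#'
#' A channel is flagged when it is an outlier in strictly more than `p_ch`
#' of the windows. Channels that are (near-)flat over the whole recording —
#' median window SD below `flat_frac` of the montage-wide median — are
#' always flagged on the low side: dead electrodes must not survive even
#' when the asymmetric envelope cannot see them.
#'
#' @param mask a [robust_outlier_mask()] over an SD statistic, across rows.
#' @param p_ch strict fraction threshold (default 0.2).
#' @param ws the `window_stats` the mask came from (needed for the flat rule;
#'   optional).
#' @param flat_frac near-flat threshold relative to the montage median
#'   window SD (default 0.05).
#' @return character vector of flagged channel labels.
#' @export
flag_channels_sd <- function(mask, p_ch = 0.2, ws = NULL, flat_frac = 0.05) {
  frac <- rowMeans(mask$mask)
  flagged <- mask$row_labels[frac > p_ch]
  if (!is.null(ws)) {
    med_all <- stats::median(ws$values)
    row_med <- apply(ws$values, 1, stats::median)
    flat <- ws$row_labels[row_med <= flat_frac * med_all]
    flagged <- union(flagged, flat)
  }
  flagged
}

#' Time flags from a voltage-variance outlier mask (ch_sd)
#'
#' A window is flagged when strictly more than `p_t` of the (unflagged)
#' channels are outliers in it; adjacent flagged windows merge into one
#' interval.
#'
#' @param mask a [robust_outlier_mask()], rows restricted to unflagged
#'   channels (or use `exclude`).
#' @param p_t strict fraction threshold (default 0.2).
#' @param exclude channel labels dropped from the column fractions.
#' @param label interval label (default `"ch_sd"`).
#' @return interval data.frame (onset, duration, label).
#' @export
flag_time_sd <- function(mask, p_t = 0.2, exclude = character(0), label = "ch_sd") {
  keep <- !(mask$row_labels %in% exclude)
  if (!any(keep)) return(empty_intervals())
  frac <- colMeans(mask$mask[keep, , drop = FALSE])
  windows_to_intervals(frac > p_t, mask$onsets, mask$window_s, label)
}

#' Windowed neighbor correlation per channel
#'
#' For every channel and window, the maximum absolute Pearson correlation
#' with the channel's `k_neighbors` nearest electrodes (3D Euclidean
#' distance on the montage). Channels with zero variance in a window get
#' value 0 with a missing-data note. The per-pair correlations are retained
#' for the bridging criterion.
#'
#' @param rec an `eeg_recording`.
#' @param m montage covering all channels of `rec`.
#' @param k_neighbors neighbors per channel (default 3).
#' @param window_s window length in seconds (default 1).
#' @param rows optional channel subset.
#' @return a `window_stats` (statistic id `"neighbor_r"`, values in `[0, 1]`;
#'   `$pair_r` holds the per-pair correlation matrix).
#' @export
neighbor_r <- function(rec, m, k_neighbors = 3, window_s = 1, rows = rec$labels) {
  stopifnot(k_neighbors >= 1)
  nb <- nearest_neighbors(m, rows, k_neighbors)
  npw <- as.integer(round(window_s * rec$sfreq))
  n <- n_samples(rec)
  if (npw > n) stopf("neighbor_r: window longer than recording")
  nwin <- n %/% npw
  X <- rec$samples[rows, , drop = FALSE]
  # unique neighbor pairs
  pair_key <- unique(unlist(lapply(seq_along(rows), function(i)
    vapply(nb[[i]], function(j) paste(sort(c(rows[i], j)), collapse = "\r"), "")),
    use.names = FALSE))
  pairs <- do.call(rbind, strsplit(pair_key, "\r", fixed = TRUE))
  pr <- matrix(NA_real_, nrow(pairs), nwin)
  vals <- matrix(0, length(rows), nwin)
  miss <- matrix(FALSE, length(rows), nwin)
  idx <- match(rows, rows)
  for (w in seq_len(nwin)) {
    cols <- ((w - 1) * npw + 1):(w * npw)
    Xi <- X[, cols, drop = FALSE]
    sds <- apply(Xi, 1, stats::sd)
    cc <- suppressWarnings(stats::cor(t(Xi)))
    cc[!is.finite(cc)] <- 0
    pr[, w] <- cc[cbind(match(pairs[, 1], rows), match(pairs[, 2], rows))]
    for (i in seq_along(rows)) {
      if (sds[i] == 0) { vals[i, w] <- 0; miss[i, w] <- TRUE; next }
      vals[i, w] <- max(abs(cc[i, match(nb[[i]], rows)]))
    }
  }
  ws <- new_window_stats("neighbor_r", rows, window_s,
                         (seq_len(nwin) - 1) * window_s, vals, missing = miss,
                         pair_r = list(pairs = pairs, r = pr))
  ws
}

#' Low neighbor-correlation flags (low_r)
#'
#' Low-side-only outlier detection on the neighbor-correlation statistic.
#' Channel flags compare across channels within each window: a channel
#' electrically decoupled from its neighborhood sits below the cohort of
#' well-attached channels. Time flags compare each remaining channel against
#' its own correlation history across windows: a global decorrelation (e.g.
#' a sensor pop) drops every channel at once and is invisible to the
#' within-window comparison, but is a low outlier in every channel's
#' history. Both use the strict fraction rules of the voltage-variance
#' criterion.
#'
#' @param ws a [neighbor_r()] result.
#' @param pL,pU,k envelope parameters.
#' @param p_ch,p_t strict fraction thresholds.
#' @param exclude channels already flagged by earlier criteria (removed from
#'   the comparison population).
#' @return list with `channels` and `time` (label `low_r`).
#' @export
flag_low_r <- function(ws, pL = 0.3, pU = 0.7, k = 6, p_ch = 0.2, p_t = 0.2,
                       exclude = character(0)) {
  if (!identical(ws$statistic, "neighbor_r"))
    stopf("flag_low_r: expected a neighbor_r statistic, got '%s'", ws$statistic)
  keep <- !(ws$row_labels %in% exclude)
  sub <- new_window_stats(ws$statistic, ws$row_labels[keep], ws$window_s,
                          ws$onsets, ws$values[keep, , drop = FALSE],
                          missing = ws$missing[keep, , drop = FALSE])
  mask <- robust_outlier_mask(sub, "across-rows", pL, pU, k, side = "low")
  chans <- mask$row_labels[rowMeans(mask$mask) > p_ch]
  keep2 <- !(sub$row_labels %in% chans)
  sub2 <- new_window_stats(sub$statistic, sub$row_labels[keep2], sub$window_s,
                           sub$onsets, sub$values[keep2, , drop = FALSE],
                           missing = sub$missing[keep2, , drop = FALSE])
  mask2 <- robust_outlier_mask(sub2, "across-windows", pL, pU, k, side = "low")
  time <- flag_time_sd(mask2, p_t, label = "low_r")
  list(channels = chans, time = time)
}

#' Bridged-electrode flags (bridge)
#'
#' A neighbor pair is bridged (electrical short, e.g. saline spread) when
#' its absolute correlation is both extremely high and extremely stable
#' across windows: median |r| > `r_median_min` and inter-quartile distance
#' of |r| < `r_dispersion_max`. Both members of a bridged pair are flagged.
#'
#' @param ws a [neighbor_r()] result (carries per-pair correlations).
#' @param r_median_min median |r| threshold (default 0.98).
#' @param r_dispersion_max inter-quartile |r| dispersion threshold
#'   (default 0.01).
#' @return character vector of bridged channel labels.
#' @export
flag_bridge <- function(ws, r_median_min = 0.98, r_dispersion_max = 0.01) {
  if (is.null(ws$pair_r)) stopf("flag_bridge: per-pair correlations not retained")
  pr <- abs(ws$pair_r$r)
  flagged <- character(0)
  for (p in seq_len(nrow(pr))) {
    r <- pr[p, ]
    r <- r[is.finite(r)]
    if (!length(r)) next
    med <- stats::median(r)
    disp <- diff(stats::quantile(r, c(0.25, 0.75), names = FALSE))
    if (med > r_median_min && disp < r_dispersion_max)
      flagged <- union(flagged, ws$pair_r$pairs[p, ])
  }
  sort(flagged)
}

#' Mark non-task time as gaps
#'
#' Flags the lead-in before the first event, the lead-out after the last
#' event (onset + duration), and every span between consecutive events, when
#' longer than `max_gap_s`. An empty event table produces no gap flags
#' (resting-state convention: all time is task time).
#'
#' @param ev an [event_table()].
#' @param rec the recording the events belong to.
#' @param max_gap_s minimum span length to flag (default 5 s).
#' @return interval data.frame labeled `gap`.
#' @export
mark_gaps <- function(ev, rec, max_gap_s = 5) {
  if (!nrow(ev)) return(empty_intervals())
  dur <- recording_duration(rec)
  # spans not covered by [onset, onset+duration) of any event
  cover <- cbind(ev$onset, ev$onset + ev$duration)
  cover <- cover[order(cover[, 1]), , drop = FALSE]
  merged <- list()
  lo <- cover[1, 1]; hi <- cover[1, 2]
  for (i in seq_len(nrow(cover))[-1]) {
    if (cover[i, 1] <= hi) hi <- max(hi, cover[i, 2])
    else { merged[[length(merged) + 1L]] <- c(lo, hi); lo <- cover[i, 1]; hi <- cover[i, 2] }
  }
  merged[[length(merged) + 1L]] <- c(lo, hi)
  mg <- do.call(rbind, merged)
  span_lo <- c(0, mg[, 2])
  span_hi <- c(mg[, 1], dur)
  len <- span_hi - span_lo
  keep <- len > max_gap_s
  if (!any(keep)) return(empty_intervals())
  make_intervals(span_lo[keep], len[keep], "gap")
}
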