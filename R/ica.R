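# Two-stage ICA orchestration: prepare cleaned input from the current
# annotation state, decompose (extended infomax by default), flag
# non-stationary time from component-activation variance (ic_sd1 / ic_sd2),
# apply heuristic component labels, and back-project retained components.

#' Assemble the data matrix for an ICA stage
#'
#' Drops every flagged channel, excises every flagged time interval
#' (including `gap` by default; task-comparability errs toward modeling task
#' time only) and concatenates the remaining segments. The decomposition
#' dimensionality is the numerical rank of the retained matrix, which is one
#' less than the channel count on average-referenced data.
#'
#' @param rec an `eeg_recording`.
#' @param ann current [annotations()].
#' @param exclude_time_labels time-flag labels to excise (default: all).
#' @param min_channels hard floor on included channels (default 16).
#' @return list with `data` (channels x samples), `included_channels`,
#'   `included_intervals`, `sample_index` (0-based original indices) and
#'   `effective_rank`.
#' @export
prepare_ica_input <- function(rec, ann, exclude_time_labels = TIME_FLAG_LABELS,
                              min_channels = 16) {
  drop_ch <- flagged_channels(ann)
  keep_ch <- setdiff(rec$labels, drop_ch)
  nch <- length(keep_ch)
  if (nch < min_channels)
    stopf("prepare_ica_input: only %d channels retained (< %d)", nch, min_channels)
  mask <- intervals_to_mask(time_flags_of(ann, exclude_time_labels),
                            n_samples(rec), rec$sfreq)
  keep_idx <- which(!mask)
  need_err <- 10 * nch^2
  need_warn <- 30 * nch^2
  if (length(keep_idx) < need_err)
    stopf("prepare_ica_input: %d retained samples < 10 * %d^2 = %d",
          length(keep_idx), nch, need_err)
  if (length(keep_idx) < need_warn)
    warnf("prepare_ica_input: %d retained samples < 30 * %d^2 = %d; decomposition may be unstable",
          length(keep_idx), nch, need_warn)
  X <- rec$samples[keep_ch, keep_idx, drop = FALSE]
  rank <- numerical_rank(X)
  iv <- windows_to_intervals(!mask, (seq_len(n_samples(rec)) - 1) / rec$sfreq,
                             1 / rec$sfreq, "included")
  list(data = X, included_channels = keep_ch, included_intervals = iv,
       sample_index = keep_idx - 1L, effective_rank = rank)
}

numerical_rank <- function(X, tol = 1e-7) {
  cx <- X - rowMeans(X)
  sv <- svd(tcrossprod(cx) / (ncol(X) - 1), nu = 0, nv = 0)$d
  sum(sv > tol * sv[1])
}

#' Run an ICA decomposition
#'
#' Centers and PCA-whitens the input down to `effective_rank` dimensions,
#' then unmixes with the chosen engine. Components are ordered by descending
#' back-projected variance and sign-normalized (largest scalp weight
#' positive), so identical inputs, method and seed give identical results.
#'
#' `"extended_infomax"` (default) and `"fastica"` are built in;
#' `"amica_external"` is an adapter that hands the problem to a separately
#' installed AMICA binary (see [amica_adapter()]).
#'
#' @param data channels x samples matrix, or a [prepare_ica_input()] result.
#' @param method decomposition engine.
#' @param seed integer seed controlling the engine's stochastic elements.
#' @param stage 1 or 2 (recorded in the result).
#' @param effective_rank dimensionality; defaults to the numerical rank.
#' @param max_steps,lrate,tol engine tuning (extended infomax).
#' @param amica_binary path to an external AMICA executable.
#' @return an `ica_decomposition`: mixing (channels x ICs), unmixing
#'   (ICs x channels), activations, effective rank, method tag and seed.
#' @export
run_ica <- function(data, method = c("extended_infomax", "fastica", "amica_external"),
                    seed = 1, stage = 1, effective_rank = NULL,
                    max_steps = 512, lrate = NULL, tol = 1e-6,
                    amica_binary = NULL) {
  method <- match.arg(method)
  prep <- NULL
  if (is.list(data) && !is.null(data$data)) { prep <- data; data <- prep$data }
  X <- as.matrix(data)
  labels <- rownames(X) %||% sprintf("ch%02d", seq_len(nrow(X)))
  r <- effective_rank %||% prep$effective_rank %||% numerical_rank(X)
  if (r < 2) stopf("run_ica: effective rank %d is too low", r)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(r)], .Machine$double.eps)
  wh <- diag(1 / sqrt(ev), r) %*% t(eg$vectors[, seq_len(r), drop = FALSE])
  dewh <- eg$vectors[, seq_len(r), drop = FALSE] %*% diag(sqrt(ev), r)
  Xw <- wh %*% Xc

  W <- seeded(seed, switch(method,
    extended_infomax = {
      lr <- lrate %||% 0.001
      blk <- max(8L, as.integer(floor(sqrt(ncol(Xw) / 3))))
      res <- infomax_core(Xw, max_steps, lr, blk, tol, TRUE,
                          6000L, 60, 0.98, 1e9, 0.8)
      if (!res$converged && res$wchange > 1e-3)
        stopf("run_ica: extended infomax failed to converge (wchange %.3g after %d steps, lrate %.2g)",
              res$wchange, res$steps, res$lrate)
      res$weights
    },
    fastica = fastica_core(Xw, max_iter = max_steps, tol = 1e-8),
    amica_external = amica_adapter(Xw, amica_binary)))

  unmix <- W %*% wh                       # ICs x channels
  mix <- dewh %*% solve(W)                # channels x ICs
  S <- unmix %*% Xc                       # activations
  # order by back-projected variance, normalize signs
  bp_var <- colSums(mix^2) * apply(S, 1, stats::var)
  ord <- order(bp_var, decreasing = TRUE)
  mix <- mix[, ord, drop = FALSE]
  unmix <- unmix[ord, , drop = FALSE]
  S <- S[ord, , drop = FALSE]
  for (i in seq_len(nrow(S))) {
    if (mix[which.max(abs(mix[, i])), i] < 0) {
      mix[, i] <- -mix[, i]; unmix[i, ] <- -unmix[i, ]; S[i, ] <- -S[i, ]
    }
  }
  rownames(mix) <- labels; colnames(unmix) <- labels
  structure(list(stage = stage, mixing = mix, unmixing = unmix,
                 activations = S, center = ctr,
                 included_channels = prep$included_channels %||% labels,
                 included_intervals = prep$included_intervals,
                 sample_index = prep$sample_index %||% (seq_len(ncol(X)) - 1L),
                 effective_rank = r, method = method, seed = seed,
                 bp_variance = sort(bp_var, decreasing = TRUE)),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> stage %d: %d ICs over %d channels (%s, seed %d)\n",
              x$stage, x$effective_rank, ncol(x$unmixing), x$method, x$seed))
  invisible(x)
}

# symmetric FastICA (tanh contrast) on whitened data; deterministic given
# the R RNG state
fastica_core <- function(Xw, max_iter = 200, tol = 1e-8) {
  r <- nrow(Xw); N <- ncol(Xw)
  W <- matrix(stats::rnorm(r * r), r, r)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    U <- W %*% Xw
    G <- tanh(U)
    Gp <- 1 - G^2
    W1 <- (G %*% t(Xw)) / N - diag(rowMeans(Gp), r) %*% W
    W1 <- sym_decor(W1)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
  }
  W
}

#' External AMICA adapter
#'
#' Contract for plugging in a separately installed AMICA executable: the
#' whitened data matrix is written as a little-endian float stream next to a
#' parameter text file, the binary is invoked, and the resulting unmixing
#' matrix (`W.bin`, row-major floats) is read back.
#'
#' @param Xw whitened data (rank x samples).
#' @param binary path to the AMICA executable; an informative error is
#'   raised when unset.
#' @return unmixing matrix in whitened space.
#' @export
amica_adapter <- function(Xw, binary = NULL) {
  if (is.null(binary) || !nzchar(binary) || !file.exists(binary))
    stopf("amica_external: no AMICA binary configured; %s",
          "set ica$amica_binary to a built amica executable or use extended_infomax")
  dir <- tempfile("amica")
  dir.create(dir)
  datf <- file.path(dir, "input.fdt")
  con <- file(datf, "wb")
  writeBin(as.numeric(Xw), con, size = 4, endian = "little")
  close(con)
  writeLines(c(sprintf("files %s", datf),
               sprintf("data_dim %d", nrow(Xw)),
               sprintf("field_dim %d", ncol(Xw)),
               sprintf("outdir %s", dir),
               "num_models 1", "max_iter 2000"),
             file.path(dir, "amica.param"))
  status <- system2(binary, file.path(dir, "amica.param"))
  if (status != 0) stopf("amica_external: binary exited with status %d", status)
  wf <- file.path(dir, "W.bin")
  if (!file.exists(wf)) stopf("amica_external: no W.bin produced")
  w <- readBin(wf, "numeric", n = nrow(Xw)^2, size = 4, endian = "little")
  matrix(w, nrow(Xw), nrow(Xw), byrow = TRUE)
}

#' Windowed SD of component activations
#'
#' Per-component standard deviation of the activation time course in
#' windows aligned to the original recording grid (the decomposition's
#' sample index maps concatenated samples back to recording time). Windows
#' with less than `min_frac` of their samples retained are marked missing:
#' an SD estimated from a sliver of a window at the edge of an excised
#' interval is not comparable to full-window values.
#'
#' @param dec an `ica_decomposition`.
#' @param window_s window length in seconds (default 1).
#' @param sfreq sampling rate of the original recording.
#' @param total_s duration of the original recording in seconds.
#' @param min_frac minimum retained fraction of a window (default 0.5).
#' @return a `window_stats` with one row per component.
#' @export
ic_activation_sd <- function(dec, window_s = 1, sfreq, total_s, min_frac = 0.5) {
  npw <- as.integer(round(window_s * sfreq))
  nwin <- as.integer(floor(total_s * sfreq)) %/% npw
  win_of <- dec$sample_index %/% npw + 1L
  r <- nrow(dec$activations)
  vals <- matrix(NA_real_, r, nwin)
  miss <- matrix(TRUE, r, nwin)
  for (w in seq_len(nwin)) {
    cols <- which(win_of == w)
    if (length(cols) < max(2, min_frac * npw)) next
    A <- dec$activations[, cols, drop = FALSE]
    mu <- rowMeans(A)
    vals[, w] <- sqrt(pmax(0, (rowSums(A^2) - length(cols) * mu^2) / (length(cols) - 1)))
    miss[, w] <- FALSE
  }
  vals[miss] <- 0
  new_window_stats("ic_sd", sprintf("IC%03d", seq_len(r)), window_s,
                   (seq_len(nwin) - 1) * window_s, vals, missing = miss)
}

#' Time flags from component-activation variance (ic_sd1 / ic_sd2)
#'
#' Outlier mask across windows per component (a component's own activation
#' history is its comparison population), then a window is flagged when
#' strictly more than `p_t` of the components are outliers in it. Merged
#' intervals carry the stage label.
#'
#' @param ws an [ic_activation_sd()] result.
#' @param stage 1 or 2 (selects label `ic_sd1` or `ic_sd2`).
#' @param pL,pU,k envelope parameters.
#' @param p_t strict fraction threshold.
#' @return interval data.frame.
#' @export
flag_ic_time <- function(ws, stage, pL = 0.3, pU = 0.7, k = 6, p_t = 0.2) {
  stopifnot(stage %in% c(1, 2))
  mask <- robust_outlier_mask(ws, "across-windows", pL, pU, k)
  frac <- colMeans(mask$mask)
  windows_to_intervals(frac > p_t, ws$onsets, ws$window_s,
                       sprintf("ic_sd%d", stage))
}

#' Heuristic artifact labels for components
#'
#' Advisory labels from topography and spectrum: `blink` (frontal-dominant
#' topography with low-frequency-dominated activations), `lateral_eye`
#' (frontal bipolar left/right topography), `emg` (positive spectral slope
#' above 20 Hz with focal edge topography), `line` (>= 10x spectral peak at
#' the mains frequency), `low_power` (back-projected variance share below
#' `low_power_share`). Labels are advisory: the final component disposition
#' is whatever the (editable) annotation file says after review.
#'
#' @param dec a stage-2 `ica_decomposition`.
#' @param rec the recording (for the sampling rate).
#' @param m montage covering the included channels.
#' @param line_freq mains frequency in Hz.
#' @param low_power_share variance-share floor (default 0.001 = 0.1%).
#' @return named list: component index (character) -> character vector of
#'   labels; components with no label are absent.
#' @export
heuristic_ic_flags <- function(dec, rec, m, line_freq = 60,
                               low_power_share = 0.001) {
  pos <- m$positions[dec$included_channels, , drop = FALSE]
  radius <- max(sqrt(rowSums(pos^2)))
  frontal <- pos[, 2] > 0.5 * radius
  edge <- pos[, 3] < 0.35 * radius
  r <- nrow(dec$activations)
  shares <- dec$bp_variance / sum(dec$bp_variance)
  out <- list()
  nyq <- rec$sfreq / 2
  for (i in seq_len(r)) {
    labels <- character(0)
    topo <- dec$mixing[, i]
    atopo <- abs(topo)
    act <- dec$activations[i, ]
    psd <- welch_psd(act, rec$sfreq, seg_s = min(2, floor(length(act) / rec$sfreq / 2)))
    pw <- psd$power; fr <- psd$freq
    frontal_ratio <- if (any(frontal)) mean(atopo[frontal]) / mean(atopo) else 0
    lowfrac <- sum(pw[fr > 0 & fr < 5]) / sum(pw[fr > 0])
    z <- (act - mean(act)) / stats::sd(act)
    kurt <- mean(z^4) - 3
    skew <- mean(z^3)
    # blinks: frontal field plus either low-frequency-dominated or sparse
    # skewed transients (sparse blinks leave mostly background in between,
    # diluting the spectral fraction but not the kurtosis)
    if (frontal_ratio > 1.8 && (lowfrac > 0.5 || (kurt > 5 && abs(skew) > 0.5)))
      labels <- c(labels, "blink")
    if (any(frontal & pos[, 1] < 0) && any(frontal & pos[, 1] > 0)) {
      lf <- mean(topo[frontal & pos[, 1] < 0])
      rf <- mean(topo[frontal & pos[, 1] > 0])
      if (frontal_ratio > 1.5 && lf * rf < 0 &&
          min(abs(lf), abs(rf)) > 0.2 * max(atopo))
        labels <- c(labels, "lateral_eye")
    }
    hi <- fr >= 20 & fr <= nyq - 5
    if (sum(hi) > 4) {
      slope <- stats::coef(stats::lm(log(pw[hi] + 1e-30) ~ log(fr[hi])))[2]
      focal <- max(atopo)^2 / sum(atopo^2)
      if (slope > 0 && any(edge) && edge[which.max(atopo)] && focal > 0.1)
        labels <- c(labels, "emg")
    }
    band <- fr >= line_freq - 1 & fr <= line_freq + 1
    if (any(band)) {
      rest <- pw[fr >= 1 & !band]
      if (length(rest) && max(pw[band]) >= 10 * stats::median(rest))
        labels <- c(labels, "line")
    }
    if (shares[i] < low_power_share) labels <- c(labels, "low_power")
    if (length(labels)) out[[as.character(i)]] <- labels
  }
  out
}

#' Back-project retained components to the scalp
#'
#' Reconstructs the scalp signal from the non-flagged components only:
#' `mixing[, retained] %*% activations[retained, ]`, over the included
#' channels and intervals. The input recording is untouched. Flagging every
#' component yields an all-zero projection with a warning.
#'
#' @param dec an `ica_decomposition`.
#' @param ic_flags flagged component indices (integer vector), or the
#'   `ic_flags` list of an annotation set.
#' @param add_center add the channel means back (default FALSE: projections
#'   are analyzed as zero-mean signals).
#' @return list (class `ica_projection`): `samples`, `labels`,
#'   `sample_index`, `retained` component indices.
#' @export
backproject_retained <- function(dec, ic_flags = integer(0), add_center = FALSE) {
  if (is.list(ic_flags)) ic_flags <- as.integer(names(ic_flags))
  r <- nrow(dec$activations)
  retained <- setdiff(seq_len(r), ic_flags)
  if (!length(retained)) {
    warnf("backproject_retained: all %d components flagged; returning zero signal", r)
    Y <- matrix(0, nrow(dec$mixing), ncol(dec$activations))
  } else {
    Y <- dec$mixing[, retained, drop = FALSE] %*%
      dec$activations[retained, , drop = FALSE]
  }
  if (add_center) Y <- Y + dec$center
  rownames(Y) <- dec$included_channels
  structure(list(samples = Y, labels = dec$included_channels,
                 sample_index = dec$sample_index, retained = retained),
            class = "ica_projection")
}
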