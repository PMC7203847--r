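#' @useDynLib losslessr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile median sd cor fft rnorm runif approx mvfft
#' @importFrom utils read.delim write.table head tail
NULL

# Internal conventions: samples are channels x time in microvolts; time in
# seconds; sample indices 0-based; intervals half-open [onset, onset+duration).

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Robust one-sided quantile bounds
#'
#' Computes the asymmetric outlier envelope used throughout the pipeline:
#' `[q50 - k * (q50 - qL), q50 + k * (qU - q50)]`. A side whose one-sided
#' inter-quantile distance is zero is treated as dispersion-free and produces
#' no flags on that side (the bound is pushed to +/-Inf).
#'
#' @param x numeric vector (NAs dropped).
#' @param pL,pU lower/upper quantile probabilities (defaults 0.3 and 0.7).
#' @param k dispersion multiplier (default 6).
#' @return list with `lower`, `upper`, `q50`.
#' @export
robust_bounds <- function(x, pL = 0.3, pU = 0.7, k = 6) {
  x <- x[is.finite(x)]
  if (!length(x)) return(list(lower = -Inf, upper = Inf, q50 = NA_real_))
  q <- unname(stats::quantile(x, c(pL, 0.5, pU), names = FALSE, type = 7))
  dlo <- q[2] - q[1]
  dhi <- q[3] - q[2]
  list(
    lower = if (dlo > 0) q[2] - k * dlo else -Inf,
    upper = if (dhi > 0) q[2] + k * dhi else Inf,
    q50 = q[2]
  )
}

# --- half-open interval helpers (onset/duration data frames, seconds) -------

empty_intervals <- function(label = character(0)) {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = as.character(label)[0], stringsAsFactors = FALSE)
}

make_intervals <- function(onset, duration, label) {
  data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
             label = as.character(label), stringsAsFactors = FALSE)
}

# merge runs of consecutive flagged windows into maximal intervals
windows_to_intervals <- function(flagged, onsets, window_s, label) {
  if (!any(flagged)) return(empty_intervals())
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  make_intervals(onsets[starts[keep]],
                 onsets[ends[keep]] + window_s - onsets[starts[keep]],
                 rep(label, length(keep)))
}

# logical per-sample mask (length n) covered by intervals, sfreq Hz
intervals_to_mask <- function(iv, n, sfreq) {
  mask <- logical(n)
  if (is.null(iv) || !nrow(iv)) return(mask)
  for (i in seq_len(nrow(iv))) {
    a <- max(0L, as.integer(floor(iv$onset[i] * sfreq)))
    b <- min(n, as.integer(ceiling((iv$onset[i] + iv$duration[i]) * sfreq)))
    if (b > a) mask[(a + 1L):b] <- TRUE
  }
  mask
}

# fraction of interval [on, on+dur) covered by any interval in iv
interval_overlap_fraction <- function(onset, duration, iv) {
  if (!nrow(iv) || duration <= 0) return(0)
  a <- onset; b <- onset + duration
  lo <- pmax(a, iv$onset)
  hi <- pmin(b, iv$onset + iv$duration)
  # clip then merge overlapping covered pieces before summing
  seg <- cbind(lo, hi)[hi > lo, , drop = FALSE]
  if (!nrow(seg)) return(0)
  seg <- seg[order(seg[, 1]), , drop = FALSE]
  covered <- 0; cur_lo <- seg[1, 1]; cur_hi <- seg[1, 2]
  for (i in seq_len(nrow(seg))[-1]) {
    if (seg[i, 1] <= cur_hi) cur_hi <- max(cur_hi, seg[i, 2])
    else { covered <- covered + (cur_hi - cur_lo); cur_lo <- seg[i, 1]; cur_hi <- seg[i, 2] }
  }
  covered <- covered + (cur_hi - cur_lo)
  covered / duration
}

# --- Welch power spectral density -------------------------------------------

#' Averaged-periodogram (Welch) power spectral density
#'
#' Hann-tapered segments with 50% overlap; density normalized so that the
#' integral over frequency approximates the signal variance.
#'
#' @param x numeric vector (one channel).
#' @param sfreq sampling frequency in Hz.
#' @param seg_s segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `power` (uV^2/Hz).
#' @export
welch_psd <- function(x, sfreq, seg_s = 2, overlap = 0.5) {
  nper <- as.integer(round(seg_s * sfreq))
  if (nper < 8) stopf("welch_psd: segment of %d samples is too short", nper)
  if (length(x) < nper) stopf("welch_psd: signal shorter than one segment")
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann taper
  u <- sum(w^2)
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  pow <- acc / (length(starts) * u * sfreq)
  # one-sided: double all bins except DC and (for even nper) Nyquist
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1) * sfreq / nper, power = pow * dbl)
}

seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
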