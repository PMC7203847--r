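# Ground-truthed synthetic EEG. Emulates the structure of dense-net infant
# recordings: dipolar-like brain sources over 1/f background, heavy artifact
# contamination (blinks, EMG, movement), planted channel defects (noisy, flat,
# bridged, decoupled), mains interference, and a task/gap event schedule.

#' Simulation configuration
#'
#' Defines a synthetic recording: montage size, duration, sampling rate,
#' brain-source model, artifact rates and planted channel defects. Every
#' stochastic element is driven by `seed`, so identical configs reproduce
#' identical sample matrices.
#'
#' Amplitudes are the standard deviations (in microvolts) of the source time
#' courses at their strongest electrode; artifact rates are events per minute.
#'
#' @param n_channels 32, 65 or 129 (standard cap layouts).
#' @param duration_s recording length in seconds.
#' @param sfreq sampling rate in Hz.
#' @param seed integer seed (mandatory).
#' @param n_sources number of focal brain sources; the default gives a
#'   dense overlapping source field so that no electrode sits in a
#'   coverage hole.
#' @param source_scale_m spatial scale (m) of the focal source topographies;
#'   the default reflects the strong spatial smoothing of scalp potentials.
#' @param n_diffuse number of diffuse background sources (very broad
#'   topographies). Real scalp EEG shares a globally volume-conducted
#'   background, so no electrode is ever isolated from its neighbors.
#' @param diffuse_scale_m spatial scale of the diffuse topographies.
#' @param source_band oscillation band in Hz (default alpha, 8-12).
#' @param source_amp_uv brain-source amplitude (SD, microvolts).
#' @param noise_amp_uv per-channel sensor-noise amplitude.
#' @param blink_rate_min,emg_rate_min blink / EMG-burst rates per minute.
#' @param blink_amp_uv,emg_amp_uv blink / EMG amplitudes.
#' @param movement_bursts number of broadband movement bursts.
#' @param movement_duration_s duration of each movement burst.
#' @param movement_gain amplitude multiplier of movement bursts relative to
#'   the background.
#' @param bad_channels labels of channels given `bad_gain` x extra noise.
#' @param bad_gain noise gain for bad channels.
#' @param flat_channels labels of dead (near-zero) channels.
#' @param bridged_pairs list of 2-element character vectors; the second
#'   member of each pair is replaced by the first plus 1% relative noise.
#' @param decoupled_channels labels replaced by independent noise
#'   (electrically decoupled from the head).
#' @param line_freq,line_amp_uv mains frequency and amplitude (0 disables).
#' @param event_blocks data.frame(start, end, code, spacing_s) of task blocks
#'   (events every `spacing_s` within `[start, end)`), or NULL for a
#'   resting-state recording with no events.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_channels = 32, duration_s = 300, sfreq = 250, seed,
                       n_sources = 20, source_scale_m = 0.08,
                       n_diffuse = 0, diffuse_scale_m = 0.18,
                       source_band = c(8, 12),
                       source_amp_uv = 8, noise_amp_uv = 2,
                       blink_rate_min = 4, blink_amp_uv = 80,
                       emg_rate_min = 2, emg_amp_uv = 15,
                       movement_bursts = 0, movement_duration_s = 5,
                       movement_gain = 10,
                       bad_channels = character(0), bad_gain = 10,
                       flat_channels = character(0),
                       bridged_pairs = list(),
                       decoupled_channels = character(0),
                       line_freq = 60, line_amp_uv = 2,
                       event_blocks = default_event_blocks(duration_s)) {
  if (missing(seed)) stopf("sim_config: seed is mandatory")
  cfg <- list(n_channels = n_channels, duration_s = duration_s, sfreq = sfreq,
              seed = as.integer(seed), n_sources = n_sources,
              source_scale_m = source_scale_m,
              n_diffuse = n_diffuse, diffuse_scale_m = diffuse_scale_m,
              source_band = source_band, source_amp_uv = source_amp_uv,
              noise_amp_uv = noise_amp_uv,
              blink_rate_min = blink_rate_min, blink_amp_uv = blink_amp_uv,
              emg_rate_min = emg_rate_min, emg_amp_uv = emg_amp_uv,
              movement_bursts = movement_bursts,
              movement_duration_s = movement_duration_s,
              movement_gain = movement_gain,
              bad_channels = bad_channels, bad_gain = bad_gain,
              flat_channels = flat_channels, bridged_pairs = bridged_pairs,
              decoupled_channels = decoupled_channels,
              line_freq = line_freq, line_amp_uv = line_amp_uv,
              event_blocks = event_blocks)
  m <- standard_montage(n_channels)
  planted <- c(cfg$bad_channels, cfg$flat_channels, cfg$decoupled_channels,
               unlist(cfg$bridged_pairs))
  bad <- setdiff(planted, m$labels)
  if (length(bad))
    stopf("sim_config: planted label(s) not in the %d-channel layout: %s",
          n_channels, paste(bad, collapse = ", "))
  stopifnot(blink_rate_min >= 0, emg_rate_min >= 0, movement_bursts >= 0)
  structure(cfg, class = "sim_config")
}

#' Default task-block schedule for a synthetic recording
#'
#' Two stimulus blocks separated by a break, with lead-in and lead-out time,
#' scaled to the recording duration. Recordings shorter than 60 s get no
#' events (resting convention).
#'
#' @param duration_s recording length in seconds.
#' @export
default_event_blocks <- function(duration_s) {
  if (duration_s < 60) return(NULL)
  lead <- max(5, duration_s / 15)
  brk <- max(8, duration_s / 15)
  span <- (duration_s - 2 * lead - brk) / 2
  data.frame(start = c(lead, lead + span + brk),
             end = c(lead + span, duration_s - lead),
             code = c("stm+", "stm+"),
             spacing_s = 2)
}

# power-law (1/f^alpha) noise via spectral shaping, unit SD
noise_one_over_f <- function(n, alpha = 1) {
  nf <- n %/% 2L + 1L
  f <- seq_len(nf) - 1
  amp <- c(0, f[-1]^(-alpha / 2))
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1L)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  as.numeric(scale(x))
}

# white noise high-passed above cutoff Hz (FFT mask), unit SD
noise_highpass <- function(n, sfreq, cutoff = 20) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  f <- c(seq(0, n %/% 2), seq.int(-((n - 1) %/% 2), -1)) * sfreq / n
  sp[abs(f) < cutoff] <- 0
  as.numeric(scale(Re(stats::fft(sp, inverse = TRUE) / n)))
}

# Gaussian radial-basis topography centred on a scalp point, peak 1
rbf_topography <- function(positions, center, scale_m = 0.05) {
  d <- sqrt(rowSums(sweep(positions, 2, center, `-`)^2))
  exp(-(d / scale_m)^2)
}

# signed dipolar-like topography: opposite RBF lobes around a scalp point
# along a random tangential axis, peak |1|. Signed fields keep the montage
# common mode small, as real source projections do.
dipole_topography <- function(positions, center, scale_m, sep_m = 0.035) {
  radius <- sqrt(sum(center^2))
  axis <- stats::rnorm(3)
  axis <- axis - sum(axis * center) * center / radius^2  # tangential
  axis <- axis / sqrt(sum(axis^2))
  c1 <- center + sep_m * axis
  c2 <- center - sep_m * axis
  c1 <- c1 * radius / sqrt(sum(c1^2))
  c2 <- c2 * radius / sqrt(sum(c2^2))
  tp <- rbf_topography(positions, c1, scale_m) -
    rbf_topography(positions, c2, scale_m)
  tp / max(abs(tp))
}

# ~300 ms biphasic blink pulse sampled at sfreq, peak 1
blink_pulse <- function(sfreq, width_s = 0.3) {
  t <- seq(0, width_s, by = 1 / sfreq)
  p <- sin(2 * pi * t / width_s) * exp(-((t - width_s / 3) / (width_s / 2))^2)
  p / max(abs(p))
}

poisson_onsets <- function(rate_min, duration_s, refractory_s = 1) {
  n <- stats::rpois(1, rate_min * duration_s / 60)
  if (n == 0) return(numeric(0))
  on <- sort(stats::runif(n, 0, max(0, duration_s - refractory_s)))
  on[c(TRUE, diff(on) > refractory_s)]
}

#' Simulate a ground-truthed EEG recording
#'
#' Builds the scalp signal as a sum of smooth dipolar-like topographies times
#' 1/f-plus-oscillation source time courses, adds the configured artifacts and
#' channel defects, and returns the recording together with its montage and a
#' ground-truth object mirroring the configuration (expected channel labels,
#' artifact intervals, source topographies and variances).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `recording`, `montage`, `truth`.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeded(cfg$seed, {
    m <- standard_montage(cfg$n_channels)
    nch <- cfg$n_channels
    n <- as.integer(round(cfg$duration_s * cfg$sfreq))
    pos <- m$positions
    radius <- max(sqrt(rowSums(pos^2)))

    # brain sources: RBF topographies x (1/f + band-limited oscillation);
    # the last n_diffuse sources are very broad, supplying the globally
    # shared background every real scalp recording has
    n_src <- cfg$n_sources + cfg$n_diffuse
    topo <- matrix(0, nch, n_src)
    src_var <- numeric(n_src)
    X <- matrix(0, nch, n)
    for (s in seq_len(n_src)) {
      diffuse <- s > cfg$n_sources
      az <- stats::runif(1, 0, 2 * pi)
      el <- stats::runif(1, if (diffuse) 0.6 else 0.15, 1.2)
      center <- radius * c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
      tp <- dipole_topography(pos, center, scale_m = if (diffuse)
        cfg$diffuse_scale_m else cfg$source_scale_m)
      f0 <- stats::runif(1, cfg$source_band[1], cfg$source_band[2])
      osc <- sin(2 * pi * f0 * seq_len(n) / cfg$sfreq + stats::runif(1, 0, 2 * pi))
      sig <- 0.6 * noise_one_over_f(n) + 0.8 * osc
      sig <- sig / stats::sd(sig) * cfg$source_amp_uv
      topo[, s] <- tp
      src_var[s] <- stats::var(sig)
      X <- X + tp %o% sig
    }
    # homogenize per-channel brain amplitude (scalp amplitude varies far
    # less than a raw RBF mixture suggests); row scaling preserves all
    # between-channel correlation structure
    row_sd <- apply(X, 1, stats::sd)
    X <- X * (cfg$source_amp_uv / pmax(row_sd, 1e-12))

    truth_time <- empty_intervals()
    blink_topo <- NULL

    # blinks: frontal-weighted topography, biphasic pulses
    if (cfg$blink_rate_min > 0) {
      front <- radius * c(0, 0.95, 0.25)
      blink_topo <- rbf_topography(pos, front, scale_m = 0.055)
      pulse <- blink_pulse(cfg$sfreq)
      on <- poisson_onsets(cfg$blink_rate_min, cfg$duration_s)
      act <- numeric(n)
      for (o in on) {
        i0 <- as.integer(round(o * cfg$sfreq))
        idx <- i0 + seq_along(pulse)
        idx <- idx[idx <= n]
        act[idx] <- act[idx] + cfg$blink_amp_uv * pulse[seq_along(idx)] *
          stats::runif(1, 0.8, 1.2)
      }
      X <- X + blink_topo %o% act
      if (length(on))
        truth_time <- rbind(truth_time, make_intervals(on, 0.3, "blink"))
    }

    # EMG bursts: high-passed noise on outer-ring electrodes
    edge <- which(pos[, 3] < 0.35 * radius)
    if (cfg$emg_rate_min > 0 && length(edge)) {
      on <- poisson_onsets(cfg$emg_rate_min, cfg$duration_s, refractory_s = 2)
      for (o in on) {
        dur <- stats::runif(1, 0.8, 1.5)
        i0 <- as.integer(round(o * cfg$sfreq))
        len <- min(n - i0, as.integer(round(dur * cfg$sfreq)))
        if (len < cfg$sfreq / 5) next
        idx <- i0 + seq_len(len)
        for (e in edge) {
          w <- stats::runif(1, 0.2, 1)
          X[e, idx] <- X[e, idx] + cfg$emg_amp_uv * w * noise_highpass(len, cfg$sfreq)
        }
        truth_time <- rbind(truth_time, make_intervals(o, len / cfg$sfreq, "emg"))
      }
    }

    # movement bursts: broadband, x10 background, on > 50% of channels
    if (cfg$movement_bursts > 0) {
      bg_sd <- stats::sd(as.numeric(X[, seq_len(min(n, 5000))]))
      slots <- seq(0.1, 0.9, length.out = cfg$movement_bursts) * cfg$duration_s
      for (o in slots) {
        len <- as.integer(round(cfg$movement_duration_s * cfg$sfreq))
        i0 <- as.integer(round(o * cfg$sfreq))
        len <- min(len, n - i0)
        idx <- i0 + seq_len(len)
        hit <- sort(sample.int(nch, size = ceiling(0.6 * nch)))
        env <- sin(pi * seq_len(len) / len)  # taper the burst edges
        for (e in hit)
          X[e, idx] <- X[e, idx] + cfg$movement_gain * bg_sd * env *
            noise_one_over_f(len, alpha = 0.5)
        truth_time <- rbind(truth_time,
                            make_intervals(o, len / cfg$sfreq, "movement"))
      }
    }

    # mains interference with a mild spatial gradient
    if (cfg$line_amp_uv > 0 && cfg$line_freq < cfg$sfreq / 2) {
      gains <- stats::runif(nch, 0.8, 1.2)
      line <- sqrt(2) * cfg$line_amp_uv *
        sin(2 * pi * cfg$line_freq * seq_len(n) / cfg$sfreq)
      X <- X + gains %o% line
    }

    # sensor noise
    X <- X + matrix(stats::rnorm(nch * n, sd = cfg$noise_amp_uv), nch, n)

    # planted channel defects (after signal composition)
    truth_ch <- list()
    # typical channel amplitude outside movement bursts, raw and as the
    # median 1 s window SD in the analysis frame (average reference) — the
    # statistic the variance criteria actually compare
    clean_cols <- which(!intervals_to_mask(
      truth_time[truth_time$label == "movement", , drop = FALSE], n, cfg$sfreq))
    if (length(clean_cols) > 50000) clean_cols <- clean_cols[seq_len(50000)]
    typ_sd <- stats::median(apply(X[, clean_cols, drop = FALSE], 1, stats::sd))
    win_sd <- function(v, npw) {
      nw <- length(v) %/% npw
      apply(matrix(v[seq_len(nw * npw)], npw), 2, stats::sd)
    }
    npw <- as.integer(cfg$sfreq)
    ref_sig <- colMeans(X[, clean_cols, drop = FALSE])
    Xr_clean <- sweep(X[, clean_cols, drop = FALSE], 2, ref_sig)
    typ_win_sd_ref <- stats::median(apply(Xr_clean, 1, win_sd, npw = npw))
    # a decoupled channel is independent of the average reference, so
    # re-referencing ADDS the reference variance to it; aim its raw
    # amplitude below the referenced target accordingly
    ref_win_var <- stats::median(win_sd(ref_sig, npw))^2
    typ_decoupled_raw <- sqrt(max(typ_win_sd_ref^2 - ref_win_var,
                                  (0.3 * typ_win_sd_ref)^2))
    for (lb in cfg$decoupled_channels) {
      # independent signal with the same spectral makeup, (referenced)
      # amplitude AND windowed-variance statistics as a typical channel — a
      # mixture of several independent components, like the multi-source mix
      # a real channel carries. Invisible to the variance criteria, caught
      # only by the neighbor-correlation criterion.
      i <- match(lb, m$labels)
      dcp <- numeric(n)
      for (cpt in seq_len(max(3, cfg$n_sources %/% 2))) {
        f0 <- stats::runif(1, cfg$source_band[1], cfg$source_band[2])
        osc <- sin(2 * pi * f0 * seq_len(n) / cfg$sfreq + stats::runif(1, 0, 2 * pi))
        dcp <- dcp + 0.6 * noise_one_over_f(n) + 0.8 * osc
      }
      dcp <- dcp + stats::rnorm(n, sd = cfg$noise_amp_uv / cfg$source_amp_uv)
      X[i, ] <- dcp * typ_decoupled_raw /
        stats::median(win_sd(dcp[clean_cols], npw))
      truth_ch[[lb]] <- unique(c(truth_ch[[lb]], "low_r"))
    }
    for (lb in cfg$bad_channels) {
      i <- match(lb, m$labels)
      X[i, ] <- X[i, ] + stats::rnorm(n, sd = cfg$bad_gain * typ_sd)
      truth_ch[[lb]] <- unique(c(truth_ch[[lb]], "ch_sd"))
    }
    for (lb in cfg$flat_channels) {
      i <- match(lb, m$labels)
      X[i, ] <- stats::rnorm(n, sd = 0.02 * cfg$noise_amp_uv)
      truth_ch[[lb]] <- unique(c(truth_ch[[lb]], "ch_sd"))
    }
    for (pr in cfg$bridged_pairs) {
      i <- match(pr[1], m$labels); j <- match(pr[2], m$labels)
      X[j, ] <- X[i, ] + stats::rnorm(n, sd = 0.01 * stats::sd(X[i, ]))
      truth_ch[[pr[1]]] <- unique(c(truth_ch[[pr[1]]], "bridge"))
      truth_ch[[pr[2]]] <- unique(c(truth_ch[[pr[2]]], "bridge"))
    }

    ev <- schedule_events(cfg$event_blocks, cfg$duration_s)
    rec <- new_recording(X, cfg$sfreq, m$labels, events = ev, montage = m,
                         provenance = sprintf("simulate_recording(seed=%d)", cfg$seed))
    truth <- structure(
      list(channels = truth_ch,
           time = truth_time[order(truth_time$onset), , drop = FALSE],
           source_topographies = `rownames<-`(topo, m$labels),
           source_variance = src_var,
           blink_topography = blink_topo,
           config = cfg),
      class = "sim_truth")
    list(recording = rec, montage = m, truth = truth)
  })
}

schedule_events <- function(blocks, duration_s) {
  if (is.null(blocks) || !nrow(blocks)) return(event_table())
  on <- numeric(0); code <- character(0)
  for (b in seq_len(nrow(blocks))) {
    t <- seq(blocks$start[b], blocks$end[b] - 1e-9, by = blocks$spacing_s[b])
    on <- c(on, t); code <- c(code, rep(blocks$code[b], length(t)))
  }
  o <- order(on)
  event_table(onset = on[o], duration = rep(1, length(on)), code = code[o])
}
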