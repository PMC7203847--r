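---
title: "Lossless annotation of continuous EEG: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossless annotation of continuous EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the data state

Multi-site developmental EEG studies pool recordings that differ in montage
(dense saline nets of 32-129 channels), task structure, duration, mains
frequency, and — above all — in how heavily they are contaminated by blinks,
muscle activity, movement, bridged or dead electrodes. Conventional
preprocessing *rejects* contaminated channels and epochs, which destroys
information and bakes one lab's cleaning policy into the shared data.

`losslessr` instead keeps every raw sample untouched and stores all quality
decisions as **annotations**: labeled channel flags, labeled time intervals
and labeled independent-component (IC) flags, written as editable
tab-separated sidecars in a BIDS derivative tree. Downstream users *purge*
(apply) the annotations they agree with; a reviewer can edit any decision by
editing a text file. The package's contract is that after a full pipeline run
every raw data file is byte-identical to its input.

## The annotation criteria

All criteria share one robust outlier rule. For a vector of values `x`
(window SDs across channels, a channel's correlation history, pooled study
values) the envelope is

    [ q50 - k * (q50 - qL),  q50 + k * (qU - q50) ]

with one-sided inter-quantile distances, defaults `qL/qU` at probabilities
0.3/0.7 and `k = 6`. Using 0.3/0.7 rather than quartiles keeps the scale
estimate away from the contaminated tails (recordings can be mostly
artifact); the asymmetric construction tolerates the strong right skew of
variance statistics. A side with zero inter-quantile distance produces no
flags on that side — a degenerate slice is treated as dispersion-free rather
than as all-outlying.

A cell-level outlier mask becomes a flag through strict fraction rules: a
channel is flagged when it is an outlier in more than `p_ch = 0.2` of
windows; a window is time-flagged when more than `p_t = 0.2` of the
(unflagged) channels or components are outliers in it. Adjacent flagged
windows merge into maximal half-open intervals `[onset, onset + duration)`.
Windows are 1 s, non-overlapping — the standard stationarity scale for EEG —
and every parameter is exposed in the pipeline config.

The criteria run in a fixed order, each excluding what earlier ones flagged
from its comparison population, progressing from coarse to fine:

1. **`ch_s_sd` (staging, study level).** Windowed channel SDs of *all*
   recordings are pooled and a single study envelope is estimated; each
   recording is then flagged against the pooled envelope. This is computed
   on raw-referenced data, before average re-referencing, so that a few
   catastrophic channels cannot poison the reference; re-referencing then
   excludes the `ch_s_sd` channels. Pooling is global by default (a
   per-channel option exists in `estimate_study_envelope`'s inputs by
   restricting rows) because position-resolved pooling needs many more
   recordings than a desk-scale study provides.
2. **`ch_sd` (subject level).** The same windowed-SD statistic compared
   across channels within each window, on the average-referenced recording.
   Near-flat channels — median window SD below 5% of the montage-wide
   median — are always flagged: a dead electrode is often *not* a formal
   outlier (the asymmetric envelope's lower bound can be negative), and
   after average re-referencing it would even inherit the common signal,
   so flat detection runs on raw-referenced data. The 5% floor is far below
   any plausible brain-signal amplitude ratio and far above amplifier noise
   on a flatlined input.
3. **`low_r` / `bridge` (neighbor correlation).** For each channel, the
   maximum absolute Pearson correlation with its 3 nearest electrodes per
   window. Channel flags use a *low-side-only* comparison across channels
   (a decoupled electrode falls below the cohort); time flags compare each
   channel against its own history across windows, because a global
   decorrelation (sensor pop) lowers every channel at once and is invisible
   within a window. Bridged pairs are extreme *and stable*: median |r| >
   0.98 with inter-quartile dispersion < 0.01 across windows. Both members
   are flagged — without an impedance map there is no principled way to
   pick the culprit, and the reviewer can unflag one by editing the sidecar.
   Max-neighbor (not median-neighbor) correlation is used because it is
   conservative toward isolation: one good neighbor is enough to keep a
   channel.
4. **`gap`.** Spans not covered by any event — lead-in, breaks, lead-out —
   longer than `max_gap_s = 5` are marked as non-task time. An empty event
   table marks nothing (resting recordings are all "task").
5. **`ic_sd1` / `ic_sd2` (two-stage ICA).** Stage 1 decomposes the data
   that survives the channel/time criteria and flags windows in which more
   than `p_t` of the components have outlying activation SD relative to
   their own history — residual non-stationarities that no spatially fixed
   source can explain. Stage 2 re-decomposes after also excising `ic_sd1`
   time and produces the final decomposition, `ic_sd2` flags, and heuristic
   component labels. Activation variance (not back-projected scalp
   variance) is the flagged statistic; the projection variant is available
   via `backproject_retained` if wanted. Windows with less than half their
   samples retained are excluded from the comparison: an SD from a sliver
   of a window at an excision edge is not comparable to full-window values.

Gap time is excluded from ICA input by default (`ica$exclude_gap`): it keeps
the decomposition comparable across task recordings. When gap data is known
to be clean, motionless signal, including it gives ICA more samples and the
toggle exists for exactly that case.

## The decomposition engine

The default engine is extended infomax (natural-gradient, block updates,
kurtosis-based sub/super-Gaussian switching, learning-rate annealing),
implemented in compiled code with data permuted through R's RNG so that a
seed fixes the result bit-for-bit. Input is centered and PCA-whitened to its
numerical rank (rank n-1 on average-referenced data); components are ordered
by descending back-projected variance and sign-normalized. Convergence is a
weight-change norm below 1e-6 (up to 512 passes); non-convergence above
1e-3 is an error carrying the diagnostics. A symmetric FastICA (tanh
contrast) engine is built in as an alternative, and `amica_adapter`
documents a file-based contract for an externally compiled AMICA binary —
the mixture model itself is a separately published algorithm and is not
reimplemented here.

Component labels (`blink`, `lateral_eye`, `emg`, `line`, `low_power`) are
**advisory**. Blink: frontal-dominant topography (mean |weight| over
electrodes with y > 0.5 R at least 1.8x the montage mean) together with
either low-frequency dominance (> 50% of power below 5 Hz) or sparse skewed
transients (excess kurtosis > 5 and |skewness| > 0.5) — sparse blinks leave
mostly background between events, which dilutes the spectral fraction but
not the kurtosis. Lateral eye movements: frontal bipolar left/right
topography. EMG: positive log-log spectral slope above 20 Hz with focal
edge topography. Line: a >= 10x spectral peak within 1 Hz of the mains
frequency. `low_power`: back-projected variance share below 0.1%. The final
disposition of every component is whatever the reviewed annotation file
says; the heuristics only pre-fill it.

## Staging choices

Mains interference is removed by regression rather than by a convolutional
notch: the line sinusoid (and harmonics) is fitted by weighted least squares
in 4 s Hann windows with 50% overlap and subtracted. A stationary tone is
suppressed to numerical precision, the passband outside roughly 1/(window
length) of the line frequency is untouched, and there are no filter edge
transients — the reason this approach is standard for line removal in EEG.
The windowing tracks slow drifts in line amplitude and phase.

Montage co-registration solves the least-squares similarity transform
(rotation, isotropic scale, translation) from fiducials when both montages
carry all three, otherwise from three or more shared labels, and warns when
the fitted head radius leaves 0.05-0.15 m. Full head-model fitting is out
of scope.

Average re-referencing subtracts the mean of the non-excluded channels from
every channel (excluded channels are re-expressed against the same
reference), making the included per-sample mean zero to 1e-9 and reducing
the numerical rank by exactly one.

## QC accounting

For summaries, overlapping flags are resolved by precedence in pipeline
order — `gap > ch_s_sd > ch_sd > low_r > ic_sd1 > ic_sd2 > manual >
retained` for time and `ch_s_sd > ch_sd > bridge > low_r > manual` for
channels — so each sample and channel is counted exactly once and the
categories sum to the recording duration (exact at the sample-count level)
and the channel count. The stored annotations keep every label separately;
precedence only affects reporting. Spatial variance is the cross-channel SD
at each sample; component accounting reports the retained vs flagged share
of time-averaged spatial SD of the two back-projections. Spectral profiles
are averaged periodograms (2 s Hann segments, 50% overlap — declared
defaults, config-visible) at the vertex channel, with a nearest-position
fallback for layouts lacking the `Cz` label, summarized across recordings
by median and 2.5/97.5% quantiles.

## The synthetic generator

`simulate_recording` builds ground-truthed fixtures emulating the target
data: a sum of smooth *signed* dipolar-like topographies (opposite
radial-basis lobes, scale 0.08 m, separation 0.035 m) times 1/f-plus-alpha
source time courses (20 sources, 8 uV SD each), 2 uV sensor noise, biphasic
~300 ms frontal blinks (4/min, 80 uV), high-passed EMG bursts at outer-ring
electrodes (2/min, 15 uV), broadband movement bursts at 10x background on
60% of channels, mains sinusoid (2 uV default), and planted channel defects:
noisy channels (10x noise gain), near-dead channels, bridged pairs
(duplicate plus 1% relative noise), and decoupled channels. Three modeling
choices matter and were each forced by a property of real scalp EEG. Signed
topographies keep the montage common mode small, as real source projections
do; all-positive source bumps produce a large shared component whose removal
at re-referencing distorts every cross-channel comparison. A dense source
field (20 overlapping sources) with per-channel amplitude normalization
avoids both coverage holes (electrodes with unrealistically low neighbor
correlation) and amplitude heterogeneity (electrodes on a source peak that
outlie the variance criteria by construction); the scalp is far more
homogeneous than a sparse mixture suggests. Decoupled channels are an
independent multi-component mixture calibrated so that their median 1 s
window SD in the average-reference frame matches the montage median —
accounting for the fact that re-referencing *adds* the reference variance
to a channel that does not share it — which makes them a pure
neighbor-correlation defect, invisible to the variance criteria. Source
amplitudes are exact by construction (time courses are scaled to the
configured SD), events follow two task blocks with lead-in/break/lead-out
gaps, and everything is deterministic under the mandatory seed.

What the generator does **not** emulate: realistic forward-model
topographies (no dipole orientation structure), age-dependent spectra,
heartbeat and sweat artifacts, electrode drift, or inter-recording montage
variation. Passing the recovery tests therefore shows the criteria detect
the *kinds* of defect they target at realistic contrast, not that the
default thresholds are optimal for any particular cohort.

## Problem sizes and numerical choices

The packaged test and acceptance fixtures use 32 channels at 250 Hz: 300 s
for the defect-recovery and false-positive studies and 100-120 s for the
end-to-end and artifact-removal runs — large enough to satisfy the ICA
sample heuristic (at least 10 n^2, warning below 30 n^2, with n the retained
channel count) while keeping a full study in minutes on one core. Intervals
are half-open with 0-based sample indexing and seconds throughout; samples
are microvolts internally regardless of the on-disk unit. Quantiles are
type-7. Ties in the blink/line component matching are broken by variance
order (components are sorted by back-projected variance). BrainVision is
the supported on-disk dialect (IEEE float-32 or int16 with per-channel
resolution); other BIDS-EEG dialects are recognized by the scanner but
rejected at read time — format conversion belongs to the acquisition site,
not the standardized core.

## Known limitations

The study envelope needs several recordings to be meaningfully "study
level"; with a single recording it degenerates to a second subject-level
criterion. Heuristic component labels are tuned for dense caps with a
vertex-anterior coordinate frame and will mislabel on radically different
montages. The regression notch assumes the line frequency is known (50 or
60 Hz); it does not search for it. The purge utility's IC step requires the
stage-2 decomposition object; annotations alone cannot reconstruct it.
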