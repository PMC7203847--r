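# losslessr

Annotation-over-rejection quality control for continuous EEG.

Pooled multi-site EEG studies — dense-net infant recordings especially —
arrive with wildly different montages, tasks, durations and contamination
levels. The usual remedy, rejecting bad channels and epochs per lab, throws
away signal and hard-codes one cleaning policy into shared data. `losslessr`
implements the *lossless* alternative: raw recordings are never modified;
instead a staged pipeline detects and **annotates** bad channels, bad time
and artifactual independent components, writing every decision as an
editable sidecar table in a BIDS derivative tree. Analysts later *purge*
(apply) whichever annotations they accept.

## The method

Every criterion is built from one robust statistic: windowed quantities
(1 s windows) compared against the asymmetric envelope

```
[ q50 − k·(q50 − q30),  q50 + k·(q70 − q50) ],   k = 6
```

with strict fraction rules (a channel is flagged when outlying in > 20% of
windows; a window when > 20% of channels/components outlie in it). The
criteria run coarse-to-fine, each excluding what earlier ones caught:

| flag | level | statistic |
|---|---|---|
| `ch_s_sd` | study | windowed channel SD vs the envelope pooled over **all** recordings |
| `ch_sd` | subject | windowed channel SD across channels per window (+ dead-channel floor) |
| `low_r` | subject | max neighbor correlation, low side (decoupled electrodes; sensor pops) |
| `bridge` | subject | neighbor pairs with median \|r\| > 0.98 and IQ dispersion < 0.01 |
| `gap` | subject | non-task spans > 5 s between events |
| `ic_sd1`, `ic_sd2` | subject | component-activation SD outliers from two-stage ICA |

Staging harmonizes recordings first: similarity co-registration of the
electrode montage to a packaged standard cap (32/65/129), regression-based
mains removal, and average re-referencing that excludes `ch_s_sd` channels.
The ICA engine is a seeded extended-infomax implementation (compiled inner
loop), with FastICA and an external-AMICA adapter as alternatives;
components get advisory labels (`blink`, `lateral_eye`, `emg`, `line`,
`low_power`) that a reviewer can edit in the sidecar before purging.

A ground-truthed synthetic generator (`simulate_recording`) reproduces the
target data characteristics — 1/f + alpha sources on smooth topographies,
blinks, EMG, movement bursts, bridged/flat/noisy/decoupled channels, mains —
so the whole pipeline is testable without any data download.

## Worked example

```r
library(losslessr)

# a 3-recording synthetic study written as a BIDS tree
root <- tempfile("study")
sims <- lapply(1:3, function(i)
  simulate_recording(sim_config(n_channels = 32, duration_s = 100,
                                sfreq = 250, seed = i)))
write_bids_fixture(sims, root)

res <- run_pipeline(validate_config(list(dataset_root = root, seed = 1)))
res$status
#> [1] "ok"
res$summaries[[1]]$time[, c("category", "seconds", "proportion")]
#>          category seconds proportion
#> gap           gap  22.004    0.22004
#> ch_s_sd   ch_s_sd   2.000    0.02000
#> ch_sd       ch_sd   0.000    0.00000
#> low_r       low_r   2.000    0.02000
#> ic_sd1     ic_sd1   1.000    0.01000
#> ic_sd2     ic_sd2   0.000    0.00000
#> manual     manual   0.000    0.00000
#> retained retained  72.996    0.72996
```

The run writes, per recording, a byte-identical copy of the raw data plus
`*_desc-annotations.tsv` (time flags), a channels table whose
`status`/`status_description` columns carry the channel flags,
`*_desc-icflags.tsv` (component labels) and a JSON sidecar with the review
state and the full serialized config, under `derivatives/lossless/`, along
with a QC report (`qc_summary.json`, `qc_summary.tsv`, accounting and
spectrum plots). In the example above the pipeline marks the scheduled
task gaps (22 s), time-flags 5 s in which the generator's blink/EMG
artifacts drive the voltage-variance, neighbor-correlation and
component-variance criteria, and retains the rest; no channels are flagged
on this defect-free recording.

After review (edit the sidecars, set the state to `reviewed`):

```r
man <- scan_dataset(root)
rec <- read_recording(man[1, ])
ann <- mark_reviewed(read_annotations(file.path(root, "derivatives", "lossless",
         "sub-001", "eeg", "sub-001_task-task")))
clean <- purge_recording(rec, ann, what = c("channels", "time"))
```

A thin command-line front-end covers batch use:

```sh
inst/cli/lossless simulate --out study/ --n-recordings 3 --seed 1
inst/cli/lossless run --dataset study/ --seed 1
inst/cli/lossless scan --dataset study/ --emit-commands   # one line per recording, for array jobs
```

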