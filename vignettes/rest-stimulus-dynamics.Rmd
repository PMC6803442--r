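---
title: "Temporal dynamics of rest and stimulus-evoked EEG with eegdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal dynamics of rest and stimulus-evoked EEG with eegdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdyn)
```

## The scientific problem

A recurring question in clinical electrophysiology is whether differences
seen in the brain's *resting* activity carry over into how it responds to
*stimuli*. `eegdyn` implements a family of time-domain dynamics measures
that make this rest-stimulus interaction quantifiable in ordinary
multichannel EEG recorded during an eyes-closed rest period and a
three-stimulus auditory oddball task (frequent *standard* tones, rare
task-relevant *deviant* tones that require a button press, and rare
task-irrelevant *novel* sounds):

* **Resting state.** Peak frequency (PF) of the theta (4-8 Hz, read at Fz)
  and alpha (rest: 8-13 Hz, read at Pz) bands, its coefficient of
  variation CV = sigma/mu (a unit-free index of peak stability), and band
  power.
* **Task epochs.** Trial-to-trial variability (TTV), Lempel-Ziv (LZ76)
  complexity change around stimulus onset, and frequency/power "sliding"
  (FS/PS) — the percent change of band-limited instantaneous frequency and
  power after the stimulus.
* **Inference.** Two-sample Kolmogorov-Smirnov comparisons between groups
  (distribution-level, robust at n < 30 per group), pooled two-tailed
  Spearman correlations between measures, and Benjamini-Hochberg FDR
  control.

Because clinical EEG of this kind is rarely shareable, the package ships a
first-class synthetic cohort generator whose parameters map one-to-one
onto the quantities the analysis estimates. Every downstream stage is
therefore testable end to end without any data download.

## Time-domain peak frequency

PF is estimated in the time domain rather than by picking a Fourier peak.
The channel is band-passed with a zero-phase windowed (Hamming) FIR filter
whose design places transition zones of 15% of the band width at each band
edge; the kernel order is the larger of three cycles of the low cut-off
and the length needed to actually realize that transition width
(~3.3 fs / transition bandwidth), rounded to an even order so the kernel
is symmetric with integer group delay. Forward-backward application is
implemented as a single convolution with the kernel's autocorrelation,
which is algebraically the same operation (response |B(f)|^2, zero phase)
and avoids latency bias in the onset-locked windows.

The analytic signal of the filtered series then yields

* instantaneous frequency: `fs / 2pi` times the first difference of the
  unwrapped analytic phase (first value replicated to preserve length),
  cleaned by a sliding median of order 10 (an 11-sample centered window
  with reflected edges — the order is a convention of this estimator; a
  single pass is applied). Values are *not* clipped to the band; clipping
  is available as an off-by-default option.
* instantaneous power: the squared modulus of the analytic signal.

The resting summary takes the time mean of PF (mu), the CV as sample
(n-1) SD over mean — the sample SD is the statistical default and is the
only dispersion convention used anywhere in the package — and band power
as the time-mean squared envelope on the same filtered signal. One filter
order of samples at each edge is excluded from all summary means to keep
filter and Hilbert edge transients out. When a recording is longer than
85,000 samples (170 s at 500 Hz) it is truncated to exactly that length
first, so all subjects contribute equal data.

Two alpha conventions coexist deliberately: resting alpha is 8-13 Hz
while task alpha is 7-13 Hz, and both are plain configuration values
(`analysis_config(rest_bands =, task_bands =)`). Note that CV = sigma/mu
is a *coefficient of variation*; the related Fano factor (sigma^2/mu) is a
different quantity and is not what this package computes.

## Trial-to-trial variability

With trials x samples data for one electrode, the cross-trial sample SD
sigma(t) is taken at every onset-relative timepoint and expressed as
percent change from its value at onset:

TTV(t) = (sigma(t) - sigma(0)) / sigma(0) x 100.

TTV is zero at onset by construction, invariant to adding any common
(trial-invariant) evoked waveform and to global amplitude scaling, and is
summarized by the *signed* trapezoidal AUC over 0-500 ms. A negative AUC
indicates post-onset variability quenching, a positive one enhancement;
an absolute-value mode exists but signed is the default because the
percent-change curve is naturally signed. Epochs span -500 to +800 ms
around onset (enough for the 300 ms pre-stimulus complexity window and
the 0-500 ms AUC windows with margin), are cut *after* filtering the
continuous data (so filter transients never sit at epoch edges), use the
half-open convention [tmin, tmax), and assign the onset sample to the
post-stimulus side. No baseline correction is applied anywhere.

Because deviants are only 10% of an oddball stream, the standards are
randomly subsampled (seeded, without replacement, original order kept) to
the deviant count before any trial-count-sensitive measure is computed.

## Lempel-Ziv complexity

Each 300-ms window (150 samples at 500 Hz) is binarized at its *own*
median — the window is the measured time series, so the threshold is
per-window, with ties mapping to 1 — and parsed left to right counting
LZ76 productions: a new word is counted whenever the running word cannot
be copied from the prior history, where the history includes the growing
word's own prefix (overlapping copies allowed), and a pending final word
counts once. The count c(n) is normalized as C(n) = c(n) / (n / log2 n),
which calibrates to ~1 for fair-coin sequences and decays to 0 for
constant ones. The production search is implemented as a binary search
for the longest copyable prefix using fixed-string matching; an
independent pointer-walk parser in the test suite verifies equality on
every binary sequence up to length 12.

Complexity is computed per trial and averaged within condition (computing
it on the trial-averaged signal instead is available via `per_trial =
FALSE`; per-trial is the default because it preserves single-trial
structure). The reported quantity is `diff = post - pre` over the two
windows [-300, 0) and [0, 300) ms.

## Frequency and power sliding

For each trial of narrow-band epochs, instantaneous frequency
(median-filtered) and power are computed, averaged across trials at every
timepoint, and each mean curve converted to percent change from onset —
mean first, then percent change, following the convention that the
trial-mean curve is the object of interest (the per-trial-percent-change
alternative is exposed as an option). The onset power is guarded by an
epsilon of 1e-12 (squared-signal units) against pathological inputs.
AUCs are read out in fixed 100-ms windows: alpha FS 376-476 ms, alpha PS
150-250 ms, theta FS 400-500 ms, theta PS 166-266 ms. These windows are
treated as constants of the analysis, not re-derived. A second readout
integrates the *raw* mean curves (Hz x ms, uV^2 x ms) to probe absolute
rather than relative differences.

## Statistics

Group comparisons use the two-sample KS statistic
D = sup |ECDF_a - ECDF_b| with a two-sided p-value, exact when
n1 x n2 <= 10,000 (always true at these group sizes) and asymptotic
otherwise. Spearman correlations are Pearson correlations of average-tie
ranks with the two-sided t approximation, always pooled across both
groups. BH adjustment is applied per "figure family" (rest comparisons;
TTV; LZC; FS/PS percent; FS/PS absolute; task-task correlations;
rest-task correlations); a single global family is one switch away
(`bh_mode = "global"`). Per-family is the default because each family is
reported as one block of results; the family label travels with every
result row so the correction is always auditable.

## The synthetic cohort generator

Each subject's EEG is

* two band-limited oscillators (theta, alpha) whose instantaneous
  frequency performs a mean-reverting Ornstein-Uhlenbeck drift with
  configurable stationary SD (`pf_wander_sd` — the generative counterpart
  of the resting CV), clipped to the band, with amplitude setting band
  power; the oscillators project onto channels Fz and Pz with fixed
  weights (own channel 1.0, other channel 0.3);
* 1/f^beta background noise (spectrally shaped white noise, beta = 1 by
  default), independent per channel;
* during the task, per-trial post-onset modulations: the noise SD is
  scaled by `1 + quench[condition]` along a ramp rising over 0-100 ms,
  sustained to 500 ms and released by 600 ms (matching the TTV AUC
  window); oscillator frequency and power are scaled by Gaussian bumps
  (SD 50 ms) centered inside the corresponding FS/PS AUC windows; and a
  common damped evoked oscillation (10 Hz carrier, 100 ms latency, 200 ms
  decay) is added to every trial, with novel trials receiving a per-trial
  randomized latency (the audio content of novels is irrelevant
  downstream, only the label matters);
* deviant-trial reaction times
  `rt = rt_base - rt_coupling x |quench[deviant]| + noise`, so stronger
  variability modulation produces faster responses.

Default session constants are the standard paradigm: 500 Hz sampling,
3-min rest, 800 tones at 80/10/10 standard/deviant/novel with 336-ms
tones and a 1-s inter-stimulus interval. Cohorts draw subjects from group
templates with 5% relative between-subject jitter on all continuous
parameters; an optional shared latent factor (`rest_task_coupling`) links
theta frequency wander to the deviant quench magnitude, which is the
generative model of a rest-to-task carry-over.

The default group templates encode effect *directions* only — higher
theta PF with lower wander and lower amplitude, lower alpha PF with
higher wander and lower amplitude, and a much smaller deviant-specific
variability modulation in the "MDD" template (0.1 vs 0.7); no published
effect magnitudes exist for these quantities in physical units, so the
sizes are the package's own choices, calibrated once so that each
configured direction dominates its estimation noise at realistic group
sizes. Two points deserve emphasis:

* The default quench values are *positive* (post-onset variability
  enhancement). This keeps the three generated facts mutually consistent:
  the weaker-responding group has the smaller deviant TTV AUC magnitude,
  reaction times are faster for subjects with larger variability
  modulation, and the deviant TTV-AUC-vs-RT correlation is negative.
  Negative (quenching) values are equally supported.
* The measured CV is not purely the configured wander: in-band background
  noise adds a floor of phase-derivative jitter that grows as oscillator
  amplitude falls. Template amplitudes and noise were chosen so the
  wander difference, not the floor, dominates the group contrast.

What the generator does **not** emulate: volume conduction and realistic
scalp topography (two channels with fixed weights), eye/muscle artifacts,
non-stationary drowsiness effects, and any ERP component structure beyond
a single damped oscillation. Passing the recovery tests therefore shows
the *pipeline* is correct and sensitive under the assumed generative
model, not that any clinical finding replicates on real data.

## Numerical and testing choices

* All randomness is seeded; a cohort is a pure function of
  `(cohort_config, templates, coupling, jitter)`, and the analysis
  manifest replays to byte-identical TSVs (`replay_manifest()`).
* Filtering edges are reflect-padded; summary means exclude one filter
  order per edge; AUC windows interpolate their end points so they need
  not fall on the sampling grid.
* Degenerate inputs fail loudly: all-zero signals (undefined phase),
  identical trials (zero onset SD), constant correlation inputs,
  sub-epsilon onset power, windows outside support, invalid proportions.
* The Monte-Carlo recovery tests run at scaled-down study conditions
  chosen once as the suite's problem size: 25 subjects per group with
  300-trial tasks and 40-60 s rest for effect-direction recovery, 90-trial
  balanced tasks for the deviant-vs-novel discrimination, and 12 + 12
  null cohorts for false-positive-rate control. The generator *defaults*
  remain the full session (800 trials, 180 s rest).

## Known limitations

* The KS exact p-value is unavailable in the presence of ties (ties do
  not arise with continuous synthetic data but can with quantized real
  recordings); the asymptotic value is used silently in that case.
* LZ76 on 150-sample windows is coarse (quantum ~0.05 in C(n)); per-trial
  averaging is what makes subject-level values usable.
* TTV AUC inherits the sampling noise of the onset SD estimate, which is
  common to the whole curve and does not average out across timepoints;
  group comparisons should use as many trials per condition as the
  paradigm allows.
* The pipeline assumes the two analysis channels are named Fz and Pz;
  real recordings with other montages must be relabeled or reconfigured
  via `analysis_config(electrodes =)`.
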