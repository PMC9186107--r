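---
title: "Linking prestimulus alpha power, slow drift and arousal: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking prestimulus alpha power, slow drift and arousal: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(slowdrift)
```

## The scientific question

Over the course of a long recording session, the spiking activity of a
cortical population drifts slowly along a shared low-dimensional direction.
This "slow drift" — the projection of binned, tuning-residualized spike
counts onto their first principal component — covaries with classic
noninvasive arousal markers: it rises with pupil diameter and falls as
microsaccade rate increases. `slowdrift` implements the analysis chain that
asks whether a *scalp* signal, prestimulus EEG power in the alpha band
(8–12 Hz), indexes the same internal state: within each session, residual
alpha power should correlate negatively with pupil size and slow drift and
positively with microsaccade rate, and across sessions the distribution of
those correlations should shift away from zero.

Because a desk-scale package cannot ship multi-gigabyte primate recordings,
the package pairs the analysis chain with a synthetic-session generator
whose ground truth makes every stage testable. The generator is first-class,
tested code: all acceptance properties are statements about how well the
pipeline recovers what the generator planted.

## The generative model

One standardized latent process `a(t)` ("arousal") drives every modality of
a session:

* **Latent.** Gaussian-smoothed white noise on a 1-s grid, standardized to
  zero mean and unit variance; the smoothing SD (default 30 min) *is* the
  process timescale, since the autocorrelation is
  `exp(-dt^2 / (4 sd^2))`. Event-level values are linear interpolations —
  adequate because every downstream reduction bins at one minute or more.
* **Task.** Trials alternate 400-ms stimulus periods (orientation 45 or 135,
  drawn at random) with fixation periods uniform on 300–500 ms; a trial ends
  in a hit, miss or false alarm (logistic modulation of the outcome
  probabilities by the latent, `fa_coupling > 0` by default so false alarms
  become more likely at high arousal).
* **Spikes.** `count ~ Poisson(exp(b_i + tuning_i(theta) + c_d w_i a(t)))`,
  with baselines spanning 4–12 counts per 400-ms period, antisymmetric
  orientation tuning, loading magnitudes uniform on [0.5, 1], and a fixed
  85% majority of positive loadings (the sign convention the drift
  extraction relies on).
* **EEG.** Per electrode, independent `1/f^chi` background noise (chi = 1,
  15 µV RMS) plus narrow-band rhythms projected to electrodes with random
  `N(0, 1)` "dipolar" gains: an 8–12 Hz alpha component whose amplitude is
  `alpha_rms * exp(alpha_coupling * a(t))` with `alpha_coupling = -0.5`
  (alpha power falls as arousal rises), and three arousal-*independent*
  nuisance rhythms (theta ≈ 5 Hz, low beta ≈ 14 Hz, high beta ≈ 22 Hz)
  whose power wanders slowly on its own. The nuisance rhythms matter: a
  300-ms Hanning window smears the alpha peak over several Hz, so without
  independent spectral structure every band's residual would be a noiseless
  copy of alpha and band specificity could not be assessed. Random dipolar
  gains (positive and negative across the scalp) are also what lets rhythms
  survive average referencing, as real cortical sources do.
* **Eyes.** Fixational drift is low-pass (< 2 Hz) noise with 0.05° SD per
  axis; microsaccades occur as a latent-modulated Poisson process
  (`rate = 1.5 * exp(msrate_coupling * a(t))`, `msrate_coupling = -0.5`)
  with a 150-ms minimum separation, amplitudes uniform on 0.05–1°, and
  raised-cosine velocity pulses obeying the main sequence
  `v_peak = 100 deg/s per deg` with 4% lognormal scatter. Pulse duration
  follows from the main sequence (`d = 2A / v_peak ≈ 20 ms`, clamped to
  8–30 ms), which keeps the largest microsaccades below the 100 deg/s
  exclusion bound — a fixed pulse duration would not. Hit and false-alarm
  trials additionally get large (~6°, > 250 deg/s) task saccades and return
  saccades. Pupil is `5 + pupil_coupling * a(t)` plus slow noise.

Couplings are *effect sizes of a clean model*: recovered correlations on
synthetic sessions are far stronger (|r| ≈ 0.9) than on real recordings
(median |r| ≈ 0.3–0.4), because the generator omits the nonstationarities,
measurement noise and behavioral idiosyncrasies of real sessions. Passing
recovery tests therefore demonstrates correctness of the chain, not expected
field performance.

### Period-level fidelity

`simulate_session(fidelity = "summary")` samples the identical statistical
model at the period level (per-segment alpha band power with lognormal
segment noise, per-period Poisson microsaccade counts, per-stimulus pupil
means, the same spike model) without synthesizing kilohertz waveforms. It
exists for replicate-cohort statistics — e.g., 50 null cohorts for type-I
error control — where only the binned series matter; it exercises binning,
drift extraction and the statistical machinery, but not the detector or the
spectral stages.

## The analysis chain

* **Microsaccade detection.** Velocity from the 5-point central difference
  (its implicit smoothing is the standard companion of median-based
  thresholding; raw differencing would inflate the noise estimate). The
  per-component threshold is 6 times the robust SD
  `sqrt(median(v^2) - median(v)^2)`, combined elliptically; runs of at least
  6 ms become events; events closer than 100 ms are *merged* (the
  alternative, deleting the second event, discards displacement; merging
  preserves it); amplitude is onset-to-offset displacement; events with
  amplitude > 1° or peak velocity > 100 deg/s are excluded as regular
  saccades. The amplitude–peak-velocity (main sequence) correlation of the
  detected events validates the detector.
* **EEG spectra.** The session is average-referenced; one segment is cut
  from the first 300 ms of every fixation period except each trial's initial
  one (eye position is still settling there). Screening uses three rules
  computed from pre-rejection session statistics, so one segment's fate
  never depends on another's: per-electrode SD above 10 times that
  electrode's session mean, flat channels (SD < 300 nV), and within-period
  eye-speed SD above twice the session-mean eye speed. The eye rule exists
  to remove eye-movement-contaminated EEG, and it does: fixation periods
  containing a microsaccade are rejected by it (roughly a third of segments
  at a 1.5/s microsaccade rate), which is intended behavior rather than a
  defect — the surviving segments are the ones whose spectra cannot be
  driven by eye movements. Each kept segment is Hanning-windowed and
  zero-padded to 1 s, giving a 1-Hz grid (the raw 300-ms grid has 3.3-Hz
  spacing and could not populate a 4-Hz sliding scan); power is `|X|^2 / N`
  so Parseval holds exactly.
* **Aperiodic removal.** Per 30-min bin and electrode,
  `log10 P = c - chi log10 f` is fit by least squares over 3–50 Hz excluding
  7–14 Hz — the guard keeps the alpha peak from biasing the fit; the exact
  fit range and guard are this package's choices, since "fit an exponential
  to the binned spectra" underdetermines both.
  Residual power is computed per electrode *before* averaging across
  electrodes, so electrode-specific backgrounds are removed first. Band
  powers use half-open intervals ([8, 12) and so on) to prevent double
  counting at band edges.
* **Slow drift.** Residual counts subtract each neuron's session-mean
  response per orientation; residuals are binned with the same 30-min/6-min
  geometry as everything else; PC1 of the bins-by-neurons matrix (neuron
  means removed — standard PCA centering; no per-neuron normalization, since
  the method is defined on raw residual counts) gives weights and drift.
  The arbitrary PCA sign is resolved by flipping so that a strict majority
  of weights is nonnegative; on an even split the weight sum decides, and a
  zero sum is left as computed. This makes the output independent of the
  SVD's internal sign choice; it does *not* make the drift invariant to
  negating the data — projections flip with the data, as they must.
* **Timescales.** For timescale estimation the binning is re-run with a
  1-min step. Points are split into 10 random folds; each held-out point is
  predicted as a Gaussian-weighted average of retained points for smoothing
  SDs 1–90 min; R² is pooled over all held-out predictions (stabler than
  per-fold averaging at ~91 points). The timescale is the smallest SD above
  the R² maximum where R² has dropped to 75% of that maximum — scanning
  upward, because increasing the SD progressively destroys fast structure;
  if the curve never drops, the estimate is censored at 90 min. Points
  whose kernel weights all underflow fall back to the nearest retained
  neighbor.
* **Statistics.** Within-session Pearson correlations on common bins only
  (bins can drop on either side via `min_segments`); across sessions, a
  Wilcoxon signed-rank test of zero median, exact by dynamic programming up
  to n = 25 (mid-ranked ties) and normal-approximated with continuity and
  tie corrections above. Cross-session nulls pair metric A of one session
  with metric B of every other. The variance-magnitude analysis z-scores
  within-session variances per subject before pooling, so between-subject
  variance differences cannot manufacture a correlation. Sliding-frequency
  p-values are reported uncorrected (23 windows), mirroring band-wise
  reporting conventions; users can apply `p.adjust` downstream.

## Problem sizes

Defaults describe a full recording: 120-min sessions, 1-kHz EEG and eye
traces, 8 electrodes, 40 neurons. Cohort-level simulations (the sign-pattern
and frequency-scan checks in the test suite and the acceptance script) use
20-session cohorts of 60-min sessions sampled at 500 Hz with a 15-min latent
timescale — the package's cohort problem size, chosen so a full cohort
analysis runs in minutes on a single CPU while leaving six 30-min/6-min bins
and 31 fine-step bins per session. Detector-recovery experiments use short
(4-min) eye-only sessions with exactly 200 injected events; drift recovery
runs at the full 120-min, 40-neuron scale (spike counts are cheap); null
replicate cohorts use the period-level fidelity described above. The
microsaccade count check uses the dead-time-corrected Poisson expectation
`lambda / (1 + lambda d)` because of the generator's 150-ms separation
floor.

## Known limitations

* The generator has one global latent; real arousal has multiple timescales,
  and in real recordings slow drift fluctuates much more slowly (tens of
  minutes) than prestimulus alpha power (minutes). That two-process
  structure is not built in — both synthetic series inherit the single
  latent's timescale — so the package tests timescale *recovery*, not the
  drift/alpha timescale gap.
* No blinks, no binocular data, no spike-sorting artifacts, no electrode
  drift; real-data users must pre-clean their traces.
* Spectral leakage of a strong synthetic alpha still bleeds into adjacent
  4-Hz windows; with the nuisance rhythms present the scan is selective
  (strongest correlation in windows overlapping 8–12 Hz), but neighboring
  windows can remain statistically nonzero at synthetic effect sizes.
* Session bundles are plain-text directories (CSV + JSON manifest) written
  with 17 significant digits; they are lossless but bulky for kilohertz
  traces. They are an interchange format, not an archival one.
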