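---
title: "Phase-lag-index brain networks and compact-CNN classification of oddball EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag-index brain networks and compact-CNN classification of oddball EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plinet)
```

## What this package models

`plinet` implements an end-to-end analysis of auditory-oddball EEG for
three-group comparisons (a chronic-primary-pain-like group, a
depression-like group, and controls): phase-lag-index (PLI) functional
connectivity, proportional-threshold graph analysis, one-way ANOVA with
Tukey post-hoc contrasts on channel-mean connectivity, and classification of
both raw epochs and connectivity matrices with a compact convolutional
network under subject-exclusive cross-validation. Because no clinical
recordings ship with the package, a synthetic cohort generator reproduces
the *structure* of such data — 22 scalp channels (10–20 montage, Cz
reference), 250 Hz sampling, 30 target plus 200 standard tones at
1000–1500 ms intervals, epochs from −0.2 s to 0.8 s around targets — with
band-specific inter-channel phase coupling as the group-distinguishing
signal.

## The connectivity statistic

For two channels with instantaneous phases $\phi_x(t), \phi_y(t)$ (from the
Hilbert analytic signal of the band-filtered record), the phase lag index is

$$\mathrm{PLI} = \left| \left\langle \mathrm{sign}\,\Delta\phi(t)
\right\rangle \right|, \qquad \Delta\phi \in (-\pi, \pi],$$

the absolute mean sign of the wrapped phase difference. A consistent nonzero
lag gives 1; no consistent lag gives 0; zero-lag (volume-conduction-like)
coupling is invisible to it by construction. Two conventions are fixed here
because exact ties do occur in constructed fixtures: `sign(0)` contributes
0, and a lag of exactly $\pi$ — which has no leading side — also counts as a
tie. The expectation is taken over time samples within a trial and the
trial matrices are averaged arithmetically to the subject level; group
matrices are means of subject matrices.

Both the band-pass filter (Hamming-window FIR, applied forward and
backward) and the Hilbert transform are applied to the *continuous* record
before epoching. Zero-phase filtering matters because any phase distortion
would bias PLI directly; computing the analytic signal on the continuous
record matters because the Hilbert transform of a finite epoch is distorted
at its edges, which measurably deflates PLI for perfectly coupled pairs
(about 3 % on 1 s epochs in our tests). Band edges are the conventional
delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45, wide 1–45 Hz —
the analysis band list is configurable since sources differ on these
conventions.

## The synthetic cohort generator

Each subject's record is a sum of three components:

* **1/f background noise** (`noise_sd`, default 8 µV): pink noise is the
  canonical EEG background, and because PLI is amplitude-blind but filters
  are not, a realistic spectral tilt is the relevant property to emulate.
* **Band-limited oscillators** (per-band relative amplitudes in
  `band_powers`, scaled by a 3 µV rms base): independent per channel,
  except that the two channels of a coupling rule share one oscillator.
  The second channel receives the shared oscillator rotated by
  `mean_lag` plus von Mises jitter with concentration `kappa`, redrawn in
  0.25 s blocks. The block structure makes the achieved PLI a monotone
  function of `kappa`: with a lag of $\pi/2$, the fraction of blocks whose
  jittered lag stays in $(0, \pi)$ is the von Mises mass on
  $(-\pi/2, \pi/2)$, so `kappa = 0` is indistinguishable from uncoupling
  and `kappa = Inf` locks the lag deterministically. This closed monotone
  relationship is what makes the generator calibratable, and is verified as
  a property test over a 5-point `kappa` grid.
* **A P300-like deflection**: a Gaussian-windowed half-sine peaking 300 ms
  after each target, parietal-maximal topography, amplitude per group
  profile. The group analyses never use ERP amplitude; the component exists
  so that epochs have realistic event-locked structure (and so that PLI is
  demonstrably robust to a time-locked zero-lag common component).

The default study conditions (`default_cohort_spec()`) give the pain-like
group strongly concentrated theta coupling on frontoparietal pairs
(FP1–P3, FP2–O2, FP1–O1, FP2–P4; `kappa = 10`), controls moderate coupling
there (`kappa = 2`) plus stronger CP5–O2 and FC2–F4 links, and the
depression-like group globally suppressed theta coupling (`kappa = 0.3`);
all groups share an identical alpha C3–C4 link so not every connection is
discriminative. A channel participating in several rules carries several
oscillators, which dilutes each pairwise coupling — deliberate, since real
hub channels face the same superposition.

What the generator does *not* emulate: ocular/muscle artifacts (the
amplitude-threshold `reject_artifacts()` stands in for component-based
cleaning, and the simulated data contain no such components),
volume-conduction/leadfield mixing, and non-stationarities across a session.
Passing tests therefore demonstrate the correctness and sensitivity of the
analysis chain under controlled coupling, not robustness to those artifact
classes.

Fixed sizes come from the emulated paradigm: 30 target epochs per subject,
250 samples per epoch (the half-open window $[-0.2, 0.8)$ s at 250 Hz gives
exactly 250). Record lengths are padded to 5-smooth integers so the spectral
synthesis stays $O(n \log n)$.

## Graph analysis

Subject matrices are proportionally thresholded: the strongest
`floor(0.30 * 231) = 69` of the 231 channel pairs are retained (ties broken
deterministically by ascending row, column index) and the surviving network
is binarized. On the binary graph the package reports degree centrality
$k_i/(N-1)$, betweenness centrality (pair-dependency sum normalized by
$(N-1)(N-2)/2$, unreachable pairs contributing zero), clustering
coefficient $2t_i/(k_i(k_i-1))$, local efficiency (efficiency of each
node's neighbour-induced subgraph) and global efficiency (mean inverse
shortest-path length, $1/\infty = 0$). Shortest paths are unweighted hop
counts. Degenerate nodes follow standard network-neuroscience conventions:
degree < 2 gives clustering 0, fewer than 2 neighbours gives local
efficiency 0. Metrics are computed on per-subject thresholded graphs and
averaged within group (group-level mean matrices are also exposed). All
five metrics are tested against hand-written exhaustive oracles (BFS
distances, simple-path enumeration, triangle counting) on every random
graph with up to 8 nodes across 20 seeds.

## Group statistics and their calibration

The dependent variable is the channel-mean PLI of each unthresholded
subject matrix (row mean excluding the diagonal). Two observation units are
exposed:

* **subject × channel** (the per-channel tables): one observation per
  subject per channel. Channels within a subject are correlated — they
  share pairs and each pair's phases — so treating them as replicates is
  pseudoreplication: under a true null the one-way ANOVA on this unit
  rejects at far above its nominal rate (about 38 % at $\alpha = 0.05$ in
  our simulations). It is kept because per-channel resolution is what the
  per-channel tables need, but its p-values should be read as descriptive.
* **per-subject mean** (`per_subject_mean = TRUE`): one independent
  observation per subject. On this unit the test is exactly calibrated;
  `null_anova_calibration()` demonstrates it by drawing all three groups
  from one exchangeable phase generator and running the package's own
  chain (trial PLI → subject matrix → strengths → ANOVA), giving uniform
  p-values (rejection rate at $\alpha = 0.05$ within Monte-Carlo error of
  5 % over 1000 simulated cohorts).

The calibration generator draws independent random-walk phase series
directly rather than synthesizing and filtering EEG, because the null
property being checked lives entirely downstream of phase extraction; this
keeps a 1000-cohort calibration inside a few minutes. Tukey's HSD provides
the pairwise post-hoc contrasts on either unit. No multiple-testing
correction is applied across bands.

## The compact CNN

The classifier is a compact convolutional network for ERP-scale EEG: a
bias-free temporal convolution (8 filters, kernel 125 — half the sampling
rate), batch normalization, a depthwise spatial convolution across all 22
channels (2 spatial filters per temporal filter, max-norm 1 constraint),
batch normalization + ELU, average pooling, dropout 0.5, a separable
convolution (depthwise temporal + 1×1 pointwise to 16 maps), batch
normalization + ELU, average pooling to width 1, dropout, and a 1×1
classification convolution with log-softmax over 3 classes. The `pli`
variant consumes 22 × 22 connectivity matrices and halves the first pooling
width (2 instead of 4) so the narrow input survives; its depthwise
separable kernel spans 22 samples with "same" padding (an even kernel grows
the trace by one: 11 → 12). The `eeg` variant consumes 22 × 250 epochs with
the conventional pooling widths (4, then 8 with a trailing global mean) and
separable kernel 16. The pli variant's per-layer trainable-parameter counts
(1000, 16, 352, 32, 352, 256, 32, 51; 2091 total) are asserted exactly in
the tests.

Training uses mini-batches of 32 and Adam
($\alpha = 10^{-4}, \beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$)
with standard bias correction of both moment estimates and *decoupled*
weight decay $\theta \leftarrow (1 - \alpha\lambda)\theta -
\alpha\,\hat m / (\sqrt{\hat v} + \epsilon)$ with $\lambda = 0.2$: a decay
term divided by $\sqrt{\hat v} + \epsilon$ degenerates as $\hat v \to 0$,
so the well-posed decoupled form is used, applied to convolution and
classifier weights but not to normalization parameters or biases. The loss
is the weighted negative log-likelihood on log-softmax outputs. Dropout is
active only in training; evaluation uses batch-norm running statistics
(momentum 0.1, biased variance). The forward/backward engine is written
directly in R — width-axis convolutions become multiplications by Toeplitz
matrices built from the kernels, so every layer is a handful of BLAS calls
— and the backward pass is verified against central finite differences.

Cross-validation assigns whole subjects to 10 folds, dealing each group's
shuffled subjects round-robin so per-fold group counts differ by at most
one; one fold is the test set, the next two are validation, the remaining
seven train (1 : 2 : 7). Subject exclusivity is asserted structurally on
every run. The reported checkpoint is the epoch with the best validation
accuracy (validation loss was the other candidate; accuracy is what the
evaluation reports, so the selection metric matches the target metric).
Training is bitwise reproducible from `(seed, config)`.

Two cohorts serve different purposes: `default_cohort_spec()` encodes the
study conditions for the statistical analyses, and
`separable_cohort_spec()` is the learnability benchmark — deterministic
theta coupling on disjoint pairs per group over a low-noise background —
on which the pli-variant network reaches well above chance (≥ 70 % test
accuracy, chance 33 %) within 150 epochs at the default learning rate.
At $\alpha = 10^{-4}$ the network is still far from converged at 150
epochs (full convergence takes on the order of 1000), so the benchmark
cohort is deliberately strongly separable; the default study cohort is
harder and needs longer training for comparable accuracy.

## Numerical choices and degenerate inputs

* Proportional thresholding and difference-matrix retention break ties by
  ascending (row, column) index — deterministic on all-equal inputs.
* `pli_pair` errors on length mismatch; phase extraction errors on
  identically zero channels (undefined phase).
* Epochs whose window exceeds the record are dropped with a warning and
  counted, so scheduled = emitted + dropped (+ rejected) always holds.
* Zero within-group variance in the ANOVA yields a flagged p-value at the
  smallest representable double rather than a silent 0.
* A class absent from the evaluation labels has undefined F1 and is
  excluded from the Macro-F1 mean with a warning.
* Upsampling requests are refused; integer-factor downsampling uses FIR
  anti-aliasing decimation (the general polyphase resampler overshoots
  pure tones by several percent and is used only for non-integer ratios).

## Problem sizes used by the shipped analyses

The analysis scripts and tests run at desk scale, chosen so each stage
remains a faithful miniature of the full design: 5 subjects per group for
the network and statistics walkthroughs, 15 per group for the theta-boost
detection check (the default coupling contrast is detected at p < 0.01
there), 1000 simulated cohorts of 4 subjects per group for the null
calibration, and 8 subjects per group × 30 trials for the classifier
benchmark. The montage is always the full 22 channels.

## Known limitations

* The 23rd recorded electrode (the Cz reference) is not an analysis
  channel; all matrices are 22 × 22.
* EDF import/export is not provided; the dataset container is the package's
  own manifest + float32 format.
* The container stores broadband *epochs*, so analyses driven from a
  container must band-filter 1 s segments, where a low-band FIR cannot
  develop its full transition band; low-frequency (delta/theta) PLI from
  containers is therefore attenuated relative to the continuous-record
  path. All shipped analyses and tests of band contrasts use the
  continuous path (regeneration from seeds), which is exact.
* Only binary (unweighted) graph metrics are implemented; weighted variants
  are out of scope.
* The eeg-variant architecture follows compact-CNN conventions but only the
  pli variant's layer plan is pinned row-for-row by the published table.
* PLI on short epochs carries a positive finite-sample bias (quantified by
  a property test: the uncoupled off-diagonal mean shrinks as epochs
  lengthen); comparisons should therefore use equal epoch lengths across
  groups, as all package code does.
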