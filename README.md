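# plinet

Phase-lag-index brain networks and compact-CNN classification for
auditory-oddball EEG.

## The problem

Chronic primary pain and depressive disorder overlap clinically, and both
alter task-evoked EEG. One way to separate them objectively is to compare
the *functional networks* their EEG forms during an auditory oddball task:
estimate inter-channel phase coupling, characterize the resulting graphs,
test the groups statistically, and ask whether a classifier can tell the
groups apart from single trials. `plinet` implements that entire analysis
for three groups (pain-like, depression-like, control), together with a
synthetic cohort generator that reproduces the structure of such data — so
the full pipeline is testable end-to-end without any clinical recordings.

## The statistics at its core

**Phase lag index.** For band-filtered channels with instantaneous phases
φ\_x, φ\_y (Hilbert analytic signal of the continuous record),

    PLI = | < sign(Δφ) > |,   Δφ = wrap(φ_x − φ_y) ∈ (−π, π]

— 1 for a consistently lagged pair, 0 for no consistent lag, blind to
zero-lag (volume-conduction-like) coupling. Trial-level matrices (22 × 22)
are averaged to subject level, thresholded to the strongest 30 % of the 231
pairs (69 edges), binarized, and characterized by degree centrality
k/(N−1), normalized betweenness, clustering coefficient 2t/(k(k−1)), local
efficiency and global efficiency (mean inverse shortest-path length).

**Group comparison.** One-way ANOVA on channel-mean connectivity with Tukey
HSD post-hoc contrasts, on either the per-channel unit (descriptive tables)
or the calibrated per-subject-mean unit.

**Classifier.** A compact convolutional network — temporal convolution,
constrained depthwise spatial convolution, separable convolution, 2091
trainable parameters in the connectivity variant — trained with Adam
(α = 1e−4) and decoupled weight decay (λ = 0.2) under subject-exclusive
10-fold cross-validation (1 test : 2 validation : 7 training folds). The
forward/backward engine, the optimizer and the training loop are
implemented in the package and verified against finite differences.

## Worked example

Generate a small three-group cohort under the default study conditions
(theta frontoparietal coupling enhanced in the pain-like group, globally
suppressed in the depression-like group), build theta-band PLI networks and
compare the groups:

```r
library(plinet)
cfg <- pipeline_config(
  cohort = default_cohort_spec(n_subjects_per_group = 5, seed = 2),
  bands = "theta", variants = character(0), seed = 2)
res <- run_pipeline(cfg)

res$bands$theta$stats$anova
gm <- res$bands$theta$group_matrices
round(c(cpp = gm$cpp$values["FP1", "P3"],
        dd  = gm$dd$values["FP1", "P3"],
        hc  = gm$hc$values["FP1", "P3"]), 3)
```

```
one-way ANOVA: SS_between=0.003097, MS=0.001549, F(2,327)=9.662, p=8.378e-05
  cpp    dd    hc
0.592 0.397 0.494
```

The pain-like group's FP1–P3 theta PLI (0.59) clearly exceeds the
depression-like group's (0.40), with controls in between (0.49) — the
configured frontoparietal contrast, recovered through filtering, phase
extraction and PLI estimation; the ANOVA on channel-mean connectivity
rejects group equality at p ≈ 8e−05. Training the connectivity-variant CNN
on the strongly separable benchmark cohort
(`separable_cohort_spec(8)`, 150 epochs; see `analysis/05_train_cnn.R`)
prints

```
accuracy 0.833, Macro-F1 0.830
     predicted
true  cpp dd hc
  cpp  26  1  3
  dd    3 20  7
  hc    0  1 29
```

— 83 % held-out-subject test accuracy against a 33 % chance level (the
test suite asserts ≥ 70 %).

The numbered scripts under `analysis/` walk the same stages narratively
(simulate → connectivity → graph metrics → statistics → classifier),
writing their tables under `results/`.

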