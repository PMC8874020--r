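---
title: "Multimodal pain assessment: simulation, cascade classification and decision-level fusion"
author: "painfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal pain assessment: simulation, cascade classification and decision-level fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painfuse)
```

## The problem

Pain intensity is usually assessed by self-report — here the verbal rating
scale (VRS), an integer from 0 (no pain) to 10 (worst pain).  An objective
complement records physiological channels while pain is induced
experimentally with a cold pressor test (hand immersed in iced water) and
asks how well the pain state can be decoded from those channels.  painfuse
implements that complete analysis for a nine-modality recording setup:

| Code | Modality | Rate | Session feature(s) |
|------|----------|------|--------------------|
| FE  | facial action units (17 AU probabilities) | 30 Hz | mean probability per AU |
| EEG | scalp EEG, 10–20 montage | 500 Hz | band power per channel × band |
| EM  | pupil diameter | 50 Hz | mean, SD (after artifact repair) |
| SC  | skin conductance | 2048 Hz | mean, slope |
| BVP | blood volume pulse | 2048 Hz | heart rate (peak detection) |
| EMG | surface EMG | 2048 Hz | RMS amplitude |
| RR  | respiration | 2048 Hz | breaths/min (peak detection) |
| ST  | skin temperature | 2048 Hz | mean, slope |
| BP  | cuff blood pressure | pre/post only | post − pre systolic and diastolic deltas |

A protocol run is a 20-s relaxed baseline followed by up to ten 20-s
immersion sessions, each ending with a VRS rating; subjects may withdraw
early, and each subject repeats the protocol on three days.  Windows are
labeled **B** (baseline, including sessions rated 0), **LP** (ratings 1–5)
and **HP** (ratings 6–10).

Because no public recording set exists for this protocol, the package's
first module is a synthetic-cohort generator that reproduces the
*statistical structure* the analysis consumes, so every downstream stage is
testable end to end.

## The synthetic cohort

`generator_config()` fixes the study conditions: 26 subjects × 3 days,
native sampling rates, and signed per-modality effect sizes expressed in
units of each modality's window-to-window noise SD per step of the pain
code (B = 0, LP = 1, HP = 2).  The default effects encode the study's
qualitative findings:

* responsive channels — skin conductance (+1.0), pupil diameter (+1.0),
  skin temperature (−1.0, peripheral cooling), systolic-BP delta (+2.0),
  EEG band power (+1.2 parietally in all bands, −1.2 over the
  central-parietal region in alpha/beta/gamma), and facial AUs (+1.2 on
  AU04/AU09/AU10, none on the blink AU45);
* null channels — heart rate, EMG and respiration rate (effect 0).

Facial expression and EEG carry the largest effects, so they dominate both
single-modality classification and fusion, and removing them degrades the
fused result — the ablation finding the package reproduces.

Pieces of the generative model that the protocol leaves open were fixed
once, on grounds of parsimony:

* **Subjects.** Sensitivity is lognormal(0, 0.3) and multiplies the latent
  pain growth rate; tolerance is uniform on [6, 10]; baseline physiology
  gets Gaussian between-subject offsets.  For FE and EEG the offset is
  *coherent along the pain-effect pattern* (one scalar per modality plus
  30% independent jitter): an expressive subject's pain AUs are all
  elevated, a high-arousal subject's regional band powers shift together.
  This coherence is what makes cross-subject generalization genuinely
  harder than within-subject generalization — the mechanism behind the
  leave-one-subject-out deficit.
* **Ratings.** The latent pain state rises logistically toward 10 across
  sessions with noise on the logistic argument; ratings are the rounded,
  clipped latent state.  Day-1 latent pain is shifted up by 1 VRS unit
  (acclimatization across repeated days).  After any session whose rating
  exceeds tolerance the subject withdraws with logistic probability.
* **Signals.**  Each window's target feature value is
  `baseline + effect × noise_sd × code + N(0, noise_sd)`; raw samples add
  fast within-window noise.  EEG windows are sums of five band-limited
  noise components built by spectral masking of white noise, so each
  channel × band variance equals its target exactly — spectral-power
  assertions therefore have closed-form expectations.  BVP is a
  quasi-periodic pulse wave at the window's target heart rate; respiration
  a noisy sinusoid; EMG zero-mean noise with the target RMS.  Blood
  pressure produces exactly one pre and one post cuff reading per day.
* **Montage.**  The default 8 channels are Fz, Cz, C3, C4, Pz, P3, P4, Oz.
  With no CP-row electrode in this reduction, C3/C4 stand in for the
  central-parietal contrast; channels outside the default set are grouped
  by their 10–20 name prefix.

What the generator does **not** attempt: biophysically realistic waveform
morphology (no heart-rate variability spectra, pulse-wave shapes, EMG burst
structure, or ocular artifacts), temporal autocorrelation of window-level
features beyond subject/day structure, or missing data.  Passing tests
therefore demonstrate that the *analysis machinery* behaves correctly under
the assumed statistical structure — not that the pipeline would reach any
particular accuracy on real recordings.

## Feature extraction

The EEG path band-passes each channel to 1–50 Hz and integrates a Welch
periodogram (2-s Hann segments, 50% overlap, segment means removed) over
the canonical bands delta 1–3, theta 4–8, alpha 8–13, beta 13–30 and gamma
30–50 Hz, half-open `[lo, hi)`.  The printed band table leaves 3–4 Hz
unassigned and the implementation mirrors that: the gap belongs to no band.
The band-pass is the squared magnitude response of a Butterworth cascade
(2nd-order high-pass at 1 Hz, 8th-order low-pass at 50 Hz) applied in the
frequency domain — the response that forward–backward filtering produces,
zero-phase, without boundary transients.

Pupil series pass a velocity filter: samples adjacent to any
first-difference velocity above 10 mm/s (a level physiological pupil change
never reaches, while blinks and tracking dropouts exceed it by an order of
magnitude) are flagged with one neighbor on each side and repaired by
linear interpolation; the repair is idempotent, and a window more than half
flagged is a data-quality error.  Heart rate and respiration rate come from
peak detection with minimum inter-peak separations of 0.33 s and 1.5 s
(caps of ~180 bpm and 40 breaths/min).  Slopes are least-squares fits with
time in seconds from window start.  The day-level blood-pressure deltas are
broadcast to all of that day's windows, because only one cuff pair exists
per day.

## Cascade classification and sensor scores

Three-class decoding uses a two-stage cascade: stage 1 separates pain from
no-pain on all windows, stage 2 separates LP from HP and is trained only on
pain windows.  Both stages are RBF-kernel SVMs (`e1071`, C = 1, bandwidth
by the median heuristic on standardized training rows, inverse-frequency
class weights since baseline windows are the rare class; a linear kernel is
available by configuration).  Features are z-scored with training-split
statistics only.  Decision values are calibrated to probabilities with a
Platt-style sigmoid fit on the training rows.  At prediction, stage-1
probability below 0.5 yields B and stage 2 is never consulted; ties at
exactly 0.5 go to the higher-pain branch (the cascade should not under-call
pain).

Each modality also gets its own cascade on its feature group alone.  Its
continuous *sensor score* is the expected class code under the chained
stage probabilities,

\[ s = p(\text{pain}) \, (1 + p(\text{HP} \mid \text{pain})) \in [0, 2], \]

which puts all nine sensors on the scale of the class codes the fusion
layer must match.

## Decision-level fusion

The fused score is the weighted sum \(f = \sum_{i=1}^{9} w_i s_i\) with
nonnegative weights constrained to the unit simplex (the constraint is an
identifiability choice: only relative sensor credit matters, and one-hot
weights then reproduce a single sensor exactly).  Weights are learned by a
real-coded genetic algorithm at its standard operating point — population
50, at most 50 generations, crossover rate 0.8, mutation rate 0.02 — with
tournament selection (size 3), per-gene arithmetic blend crossover,
Gaussian mutation (SD 0.1), clip-and-renormalize simplex repair after every
operator, and one elite individual.  Fitness is lexicographic: first the
number of *violations* (windows whose |fused − true| error exceeds 0.5, half
the class-code spacing), then mean absolute error as tiebreak.  The "true
score" is the class code 0/1/2, so fused scores and class decisions share a
scale; a raw-VRS target is available by configuration.  The run stops early
only on an exact fit — merely reaching zero violations must not stop it,
because with a 0.5 threshold many weight vectors satisfy every window and
the MAE tiebreak is what concentrates weight on the informative sensors.
Fused scores map to classes by nearest code, midpoints rounding toward the
higher-pain class.

`run_modality_sets()` reruns the GA with excluded sensors zeroed for the
three standard sets (all signals; EEG + FE only; all but EEG + FE) on a
stratified 70/30 window split, reporting held-out confusions and per-class
F1.

## Evaluation

`kfold_cv()` uses class-stratified 5-fold partitions (stratification keeps
the rare baseline class in every training split); `loso_cv()` holds out one
subject at a time, skipping a class absent from a test subject when
averaging that fold's per-class F1.  Per-class F1 is `2TP/(2TP+FP+FN)`,
zero when undefined; macro-F1 averages the three classes.  The
cross-validation unit is always the 20-s window.

The significance screen runs a repeated-measures ANOVA per feature across
the three pain states, pooling days.  The blocked test fits
`value ~ subject + state` on window-level observations (subject entered
first; the state F is the sequential test adjusted for the block), with
`dof_subject = n_subjects − 1`.  Blocking at the window level rather than
on subject-state means keeps the test exactly F-calibrated when subjects
contribute unequal window counts per state — cell means would have unequal
variances.  With iid window noise (true of the generator) the type-I rate
is nominal; on real data with within-day autocorrelation it would be
anticonservative, a known limitation.  EEG powers are log-transformed
before testing (spectral power is lognormal).  Blood-pressure deltas,
constant within a day, are instead tested as a paired pre/post design
(one-sample t on subject means, F = t²).  Raw p-values are primary;
a Bonferroni column is provided.

## Numerical choices and degenerate inputs

* Zero-variance features standardize with SD 1 instead of dividing by zero.
* Simplex repair maps an all-zero chromosome to uniform weights.
* Peak detection requires at least two peaks; flat windows raise
  data-quality errors rather than returning numbers.
* All stochastic steps (generation, partitions, the GA) are driven by
  explicit seeds through a mixing function, so identical configuration and
  seed reproduce datasets byte-for-byte and reports exactly.

## Problem sizes used in the shipped studies

The packaged tests and the acceptance script exercise the default cohort
(26 subjects × 3 days at native rates) for the cross-validation and fusion
ablation findings, 10 seeded replicates of it for the direction checks, and
replicate screens for the ANOVA pattern (100 cohorts of 12 subjects × 1
day) and type-I calibration (200 zero-effect cohorts of 8 subjects × 1
day).  The replicate screens run at `reduced_sampling_rates()` with a
4-channel montage: window-level summary statistics have the same
distribution at 256 Hz as at 2048 Hz, so the reduction changes nothing the
ANOVA sees while keeping hundreds of replicates tractable on a desktop.

## A small worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_subjects = 8, n_days = 1,
                        sampling_rates = reduced_sampling_rates(),
                        eeg_channels = c("Fz", "Cz", "C3", "Pz"), seed = 5)
feats <- simulate_cohort_features(cfg)
kfold_cv(feats, seed = 1)$macro_f1
loso_cv(feats)$macro_f1
res <- run_modality_sets(feats, ga_cfg = ga_config(seed = 3))
sapply(res, `[[`, "macro_f1")
head(significance_screen(feats)[, c("feature", "F", "p")])
```

## Known limitations

* Synthetic action-unit probabilities stand in for video-based AU
  extraction; no face detection or frame-level analysis is implemented.
* EEG artifact handling is reduced to an amplitude screen; no ICA.  The
  generator injects no ocular artifacts by default, so this path is
  exercised only by constructed tests.
* The per-sensor score definition (expected class code) is one reasonable
  choice among several the protocol leaves open; the cascade and fusion
  layers only require scores monotone in pain probability on [0, 2].
* Reported F1 values on synthetic cohorts characterize the pipeline under
  the generator's assumptions and are not predictions of accuracy on real
  recordings.
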