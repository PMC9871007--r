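---
title: "Methods: synthetic auscultation audio and ensemble-SVM lung-sound classification"
author: "auscult package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic auscultation audio and ensemble-SVM lung-sound classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Auscultation of pediatric patients distinguishes three broad classes of
lung sound: **normal (vesicular)** breath sounds, which are non-musical
low-pass-filtered noises whose energy drops off around 200 Hz;
**wheezes**, continuous musical sounds with tonal energy between 100 and
1000 Hz lasting longer than 80 ms, indicating airway narrowing; and
**crackles**, short explosive transients — fine crackles near 650 Hz
lasting about 5 ms, coarse crackles near 350 Hz lasting about 15 ms —
indicating intermittent closure and reopening of small airways.

`auscult` implements a complete classification pipeline for short
(one-to-two breath cycle) clips: BayesShrink wavelet denoising, fixed
6-second windowing, 40-coefficient MFCC features, and majority-voting
ensembles of RBF-kernel SVMs evaluated under stratified 10-fold and
nested cross-validation. Because no public corpus matches the pediatric
clinic recordings such pipelines are built on, the package also ships a
physics-informed synthetic audio generator that reproduces the corpus
statistics and acoustic event definitions above, so that every stage is
developed and tested against data with known ground truth.

## The synthetic generator

Each clip is composed additively at 44,100 Hz:

* **Vesicular base.** Gaussian noise through a 2nd-order Butterworth
  low-pass with its −3 dB point at 200 Hz (the "drop in energy at
  200 Hz" that defines vesicular sound), scaled to a reference RMS of
  0.1 and amplitude-modulated by a respiratory envelope. The envelope
  peaks mid-inspiration (`0.25 + 0.75 sin(pi p / f_i)` over the
  inspiratory phase fraction `f_i = 0.4`) and decays through expiration
  (`0.25 + 0.55 sin(pi q) e^{-3q}`), so inspiration and early expiration
  carry most of the power, as real vesicular sound does.
* **Crackles.** Exponentially damped sinusoids
  `sin(2 pi f t) e^{-t/tau}` with `tau = duration / 3.5`; the 3.5 (not
  `-ln(0.05) ~ 3`) compensates for the envelope peak sitting a
  quarter-period after onset, so the envelope is below 5% of its
  realized peak at the nominal duration (5 ms fine / 15 ms coarse).
  3–10 crackles are placed uniformly within each inspiratory segment,
  fine vs. coarse with probability 0.5, with ±5% frequency jitter.
* **Wheezes.** Tonal segments with mild second-harmonic content
  (relative amplitude 0.2) and a slow sinusoidal frequency drift of
  2–8%, tapered with a 10% raised-cosine ramp. Each wheezing clip
  carries 1–2 wheezes spanning 30–90% of an inspiratory or expiratory
  phase, with center frequency uniform on 150–900 Hz and duration
  clamped above 81 ms.
* **Heart sounds** (present with probability 0.75, matching the share
  of clips with audible heart sounds in the emulated corpus): S1/S2
  pairs of damped 40/60 Hz oscillations at a pediatric heart rate drawn
  from 80–160 bpm, peak-scaled to 3 times the vesicular RMS.
* **Ambient noise** at a white-noise floor drawn from 15–30 dB SNR,
  then peak normalization to 0.9.

Clip length and respiratory rate are drawn from truncated normal
distributions targeting the emulated corpus means of 4.1 s (SD 1.8,
bounds 1.5–10 s) and 30.2 breaths/min (SD 13.4, bounds 12–80/min).
Plain truncation at those bounds would bias the means upward (to about
4.37 s and 32.5/min), so the constructor solves for the pre-truncation
mean whose *truncated* mean hits the target exactly (closed-form
truncated-normal mean, `uniroot`). The truncated SDs come out slightly
below their targets (about 1.55 s and 12/min); only the means are
treated as binding. The recorded breath-cycle count (1 vs. 2, with
probabilities 0.203/0.797) is drawn independently of length and rate —
the three are physiologically linked, but their joint distribution in
real clinic data is not recoverable, so only the marginals are matched.

**Event loudness.** Clinical sources do not give event amplitudes
relative to vesicular sound, so these are package design choices, fixed
once: wheezes at 4–8 times the vesicular RMS (wheezes are loud, musical
sounds that dominate auscultation when present) and crackles at 1–2
times (brief transients that nevertheless spike well above the local
envelope — every crackle clip contains bursts exceeding 3 times the
surrounding 50-ms median envelope). These defaults reproduce the
qualitative task-difficulty ordering reported for real pediatric data:
normal vs. wheezing is the easiest discrimination and normal vs.
crackles the hardest of the normal-vs-X pairs.

**What the generator does not emulate:** heart murmurs, conversational
background, stethoscope contact artifacts (excluded from the emulated
corpus before analysis), inter-patient anatomical variation, and
device coloration. Passing tests on synthetic corpora therefore
demonstrate that the pipeline machinery is correct and that its
accuracy ordering behaves as reported — not that the trained models
transfer to clinic recordings.

## Preprocessing

Denoising uses multilevel wavelet shrinkage with the BayesShrink
threshold: noise scale estimated from the finest detail subband as
`median(|d1|)/0.6745`, each subband soft-thresholded at
`sigma_n^2 / sigma_x` with
`sigma_x = sqrt(max(sigma_y^2 - sigma_n^2, 0))`. The wavelet family and
depth are not dictated by the method, so the package defaults to sym8
with depth `floor(log2 n) - 6` capped to [1, 6] — deep enough that the
coarsest detail band reaches below the vesicular corner at 44.1 kHz,
shallow enough to stay cheap. The transform is a periodized orthogonal
DWT (odd-length subbands extended by repeating the final sample);
perfect reconstruction is verified to 1e-9 in the tests. The threshold
rule is linear in signal scale, so denoising commutes with gain — which
makes the whole feature pipeline gain-invariant once windows are
peak-normalized.

Windowing follows the duplicate-and-crop rule: clips longer than 6 s
keep their first 6 s; shorter clips are concatenated with whole copies
of themselves until longer than 6 s, then cropped. Denoising is applied
to the full clip *before* windowing, so the tiled copies are identical.
A clip of exactly 6 s passes through unchanged (whether "until longer"
treats equality as termination is unobservable in the output). Windows
are then peak-normalized; stethoscope gain is arbitrary, so features
should not depend on it.

## Features

40 MFCCs per frame with an FFT window of 660 samples, hop 512, periodic
Hann window, and centered frames via reflect padding, giving
`floor(n/512) + 1 = 517` frames on a 264,600-sample window. The mel
filterbank is the Slaney-style construction (linear below 1 kHz,
logarithmic above, area-normalized triangles) with 128 bands — the
filterbank size is a package default, as is the dB floor `amin = 1e-10`
that makes silent input produce a deterministic flat cepstrum.

The MFCC matrix is aggregated to a fixed-length vector; the default is
per-coefficient temporal mean and standard deviation (80 dimensions).
A compact vector is deliberate: flattening the full 40 × 517 matrix
would swamp a few hundred training clips with tens of thousands of
dimensions. Row-major flattening and mean-only aggregation remain
available for comparison.

## Classification

Four binary tasks are run: normal vs. abnormal (crackles and wheezing
pooled), crackles vs. wheezing, normal vs. crackles, and normal vs.
wheezing, with majority-voting ensembles of 1, 4, 10 and 4 RBF-kernel
SVMs respectively. Member diversity comes from seeded bootstrap
resamples of the training rows (fraction 1.0, with replacement) — the
minimal mechanism consistent with majority voting over identically
configured SVMs. Members emit calibrated probabilities; a vote is the
probability thresholded at 0.5, and an even split is broken in favor of
the class with the higher mean member probability (only the ordering of
the means matters, so calibration quality is not load-bearing).
Hyperparameters default to `C = 1` and `gamma = 1/(d * var(X))`.

Internal validation is stratified 10-fold cross-validation: indices are
shuffled within class and dealt round-robin, so per-fold class counts
deviate from the proportional share by less than one sample. For
prospective-style evaluation the fold ensembles are pooled into an
overall nested ensemble of `K x nMembers` members with the same voting
rule, and applied to a fresh synthetic corpus (default 28/31/31 clips
per class) generated from a disjoint seed stream.

Metrics are accuracy, precision, recall and F1. Reported
precision/recall/F1 are macro-averaged over the two classes by default
(positive-class averaging is available); zero-denominator ratios are
reported as 0 and flagged rather than dropped. Model-vs-rater accuracy
comparisons use the Pearson chi-square on the 2x2 correct/incorrect
table (1 df), with the Yates correction available but off by default;
rater groups are pooled (e.g. 5 raters x 90 clips = 450 Bernoulli
trials).

## Visualization

Mel spectrograms are rendered in dB with an 80 dB dynamic-range floor.
UMAP embeddings use 20 neighbors, minimum distance 0.3 and the cosine
metric, seeded for reproducibility (a fixed random state can cost some
embedding quality; testability wins here). The embedded vectors are the
same 80-dimensional feature vectors the SVMs consume. The embedding
runs through the umap-learn reference implementation via the system
`python`.

## Numerical choices and problem sizes

* Separability of the synthetic classes is asserted in the
  *standardized* feature space (per-column z-scores), because that is
  the space the SVM members actually consume (`e1071::svm` scales
  columns); raw MFCC columns have wildly different variances.
* Property tests that only exercise shape and contract logic run the
  generator at 8 kHz; every test asserting an acoustic or statistical
  target uses the full 44.1 kHz study configuration.
* The model-recovery properties use 300-clip corpora (100 per class),
  10-fold CV and three corpus seeds; corpus-moment checks use 1000
  clips. At these sizes the full suite and the acceptance script each
  run in minutes on a single CPU.
* All randomness is explicitly seeded; per-clip, per-member and
  per-fold seeds are derived deterministically from the master seed, so
  manifests, WAV bytes, feature tables, fold assignments and summary
  JSON reproduce bit-for-bit.

## Known limitations

* Synthetic-to-real transfer is untested by construction; the package's
  accuracy numbers characterize the generator's difficulty, not
  clinical performance.
* The exact MFCC-to-classifier aggregation used in comparable clinical
  pipelines is generally unreported; results here are for the mean/SD
  aggregation and are property-based (orderings, bounds), not
  value-matched to any published table.
* Cycles carrying both crackle and wheeze annotations in ICBHI-style
  data are excluded from the three-class tasks (the package's
  convention; reported alongside class counts).
* The ensemble-size sweep (1–10 members) is exposed but no empirical
  search is performed; the defaults fix the sizes at 1/4/10/4.
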