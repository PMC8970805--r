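---
title: "Decoding motor imagery from EEG: the miclass pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from EEG: the miclass pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Imagining a left- or right-hand movement suppresses the mu (8–12 Hz) and
beta (13–30 Hz) sensorimotor rhythms over the *contralateral* motor cortex —
event-related desynchronization (ERD). A brain–computer interface that decodes
this pattern from a three-electrode montage (C3, Cz, C4) must solve a noisy
two-class problem: single-trial EEG carries the ERD signature buried in
1/f background activity.

`miclass` implements one complete decoding pipeline:

1. **MSPCA denoising** — each channel is wavelet-decomposed; within every
   subband the channels' coefficients are reduced by PCA across channels and
   re-projected through the retained subspace, then resynthesized.
2. **CWT scalograms** — each trial becomes an H×W×3 time–frequency amplitude
   image (analytic Morlet wavelet, one image channel per electrode).
3. **Deep feature extraction** — a compact residual backbone with a feature
   pyramid and a 2-class head trained with focal loss; the penultimate
   global-average-pooled layer provides a fixed-width feature vector.
4. **AOA hyperparameter tuning** — the Arithmetic Optimization Algorithm, a
   population metaheuristic with division/multiplication (exploration) and
   subtraction/addition (exploitation) moves, optionally tunes the learning
   rate, the focal α/γ and the epoch budget.
5. **ID3 classification** — deep features are discretized into
   equal-frequency bins and classified with an information-gain decision
   tree.
6. **Reporting** — 2×2 confusion matrices and precision / recall / accuracy /
   F-score / Cohen's kappa, per repetition and averaged.

Every stage runs on synthetic data shipped with the package, so the whole
pipeline is testable without downloads.

## The synthetic generator as the study condition

`generate_mi_eeg()` emulates a cue-paced two-class paradigm: 9-second trials
at 128 Hz on C3/Cz/C4 (the geometry of the classic 3-channel benchmark sets,
which provide 280 trials, half of them labeled). A common mu+beta oscillation
(10 and 20 Hz, amplitudes 10 and 5 µV, random phase per trial) is mixed into
the channels with fixed gains (C3 = C4 = 1, Cz = 0.8); during the imagery
window (3–8 s) its amplitude on the contralateral channel is multiplied by
`1 - erd_depth`. Independent 1/f noise is added per channel at a configurable
SNR, defined full-band on the imagery window against the *unattenuated*
oscillation power, so the noise level never depends on the class label.
`snr_db = 5` is the default: strong enough that the band-limited mu rhythm
dominates its own band, as in an averaged-quality recording, while keeping
single-trial scalograms visibly noisy.

What the generator does **not** emulate: ocular/muscular artifacts,
inter-subject variability, non-stationary baseline drift, or volume-conduction
correlations beyond the single common source. Passing tests therefore show
that the pipeline recovers a contralateral band-power contrast under 1/f
noise — not that it handles artifact-laden clinical recordings.

## Numerical and design choices

**MSPCA.** The wavelet is db4 at 4 levels (configurable; db8 is available
when sharper subband edges matter). Coefficient matrices are mean-centered
before PCA — the covariance uses the n−1 denominator — with optional
z-scoring behind a flag; centering alone is the standard multiscale-PCA
normalization. Component retention defaults to the Kaiser rule (eigenvalues
above their mean, at least one). Symmetric boundary extension with redundant
boundary coefficients gives perfect reconstruction on any trial length, so
full retention is exactly the identity — a property the tests exercise.

**Scalograms.** Analytic Morlet with ω₀ = 6; 64 log-spaced frequencies over
4–40 Hz cover the mu and beta bands; the module default image size is
224×224 (the conventional CNN input), while the pipeline configuration
defaults to 32×32, the problem size at which the bundled backbone trains in
seconds on one CPU. Magnitudes (not powers) are min–max normalized to [0, 1]
**jointly across the three channels** (`per_image`). This default matters:
after subband-PCA denoising part of the ERD contrast appears as a global
C3-vs-C4 amplitude asymmetry, which per-channel scaling would cancel;
per-channel mode remains available for visualization.

**Feature network.** The default backbone is a deliberately small 8-layer
residual network (three stages at 8/16/32 channels, one residual block each);
deeper presets (18/34/50/101) follow the usual block counts and are exposed
for completeness, not required. Anchor boxes and box regression of the
detection architecture this design descends from are dropped — the network is
used purely as a classifier/feature extractor, keeping the two heads:
a feature layer (global-average-pooled top pyramid merge, dense to d = 256)
and a softmax classification layer. Losses use the natural logarithm with
probabilities clipped at 1e−7. Training is plain momentum SGD; the defaults
(learning rate 0.02, momentum 0.9) were fixed on a separable high-SNR fixture
where 0.05 was unstable. All convolutions are executed as nine indexed
BLAS matrix products per layer; backward passes are hand-derived and verified
against finite differences in the test suite.

**AOA.** Defaults follow the reference formulation: MOA from 0.2 to 0.9,
μ = 0.5, α = 5, ε at machine-epsilon scale in the division operator.
The explore-vs-exploit gate draws r1 per dimension and explores when
r1 > MOA(t). Candidates are clipped to the box and replace their agent only
on improvement, which guarantees a monotone best-so-far trace. Note the
canonical move scale `(ub − lb)·μ + lb` vanishes on boxes symmetric about
zero; benchmarks on such boxes converge by jumping through the origin, so the
tests also include an asymmetric shifted-sphere case.

**ID3 bridge.** Deep features are continuous; ID3 needs nominal attributes.
Equal-frequency (quantile) binning preserves the multiway-split semantics,
with open outer bins for unseen ranges. The pipeline defaults to 4 bins and
depth 3 — with ~60 training trials and 256 features, finer bins fragment
nodes into single-digit subsets and overfit. Ties in the gain argmax break to
the lowest attribute index, label ties to the lowest class, so induction is
deterministic. Splits use the gain argmax even when the best gain is zero
(attributes that no longer partition the node are excluded); this is what
lets the XOR configuration resolve at depth 2.

**Metrics.** The positive class is *left*. F is the harmonic mean of
precision and recall; kappa is Cohen's chance-corrected agreement computed
from the marginals. Display values are percentages rounded half-up to two
decimals; raw proportions are always retained. The five-iteration protocol
is five independent repetitions with distinct derived seeds and fresh
stratified 50/50 splits; the Average row is the arithmetic mean of the
per-iteration percentages. Tuning, when enabled, runs once and the winning
hyperparameters are reused across iterations.

**Determinism.** One global seed fans out to per-stage seeds through a fixed
integer derivation (`derive_seed`), so any stage can be re-run in isolation
and two runs of the same configuration are bit-identical.

## Problem sizes used in tests

The bundled checks run the complete pipeline at 60 trials per class,
32×32 images, the tiny backbone and 30 epochs — about 20 seconds per
repetition — and assess learnability at `erd_depth = 0.6` against a
no-signal (`erd_depth = 0`) control, which must stay in the chance band.
Unit tests use smaller fixtures (16×16 images, 2-second trials at 64 Hz)
chosen so each property is exercised in well under a second.

## Known limitations

* The EDF writer quantizes to 16 bits and stores labels on an auxiliary
  TRIG status channel — a convention, not part of the EDF standard; EDF+
  annotation records are not produced.
* The network has no batch normalization; very deep presets (50/101) are
  structurally available but were not designed to train stably at desk scale.
* ID3 has no pruning beyond the depth/min-samples regularizers and no
  continuous-threshold splits.
* Published kappa values for this family of experiments are not reproducible
  from their own confusion matrices under any standard kappa definition;
  kappa here is computed correctly (Cohen) and should be compared with that
  caveat.
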