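# miclass

Two-class motor-imagery EEG decoding in R: a complete, self-contained
pipeline from raw multichannel trials to a classification report.

Imagined left/right hand movement suppresses the mu (8–12 Hz) and beta
(13–30 Hz) rhythms over the contralateral motor cortex (event-related
desynchronization). `miclass` decodes that signature from a 3-electrode
montage (C3, Cz, C4) with the following stages, each usable on its own:

| Stage | Function(s) | Method |
|---|---|---|
| Simulation / I/O | `generate_mi_eeg()`, `read_trials()`, `write_trials()` | synthetic ERD trials; RDS / long CSV / EDF |
| Denoising | `mspca_denoise()` | multiscale PCA: per-subband PCA across channels on wavelet coefficients, `X = T·Pᵀ + E` with Kaiser retention |
| Time–frequency | `cwt()`, `batch_scalograms()` | analytic Morlet scalogram images, H×W×3 in [0, 1] |
| Features | `build_feature_extractor()`, `train_network()`, `extract_features()` | residual backbone + feature pyramid, focal loss `FL = −α_t (1−p_t)^γ log p_t`, penultimate layer as feature vector |
| Tuning | `aoa_optimize()`, `tune_hyperparameters()` | Arithmetic Optimization Algorithm: MOA/MOP schedules, ÷ × (explore) and − + (exploit) operators |
| Classification | `fit_discretizer()`, `build_tree()`, `predict()` | equal-frequency binning + ID3 information-gain tree, `Gain(A) = I(S) − E(A)` |
| Reporting | `confusion()`, `metrics_from_cm()`, `run_experiment()` | precision, recall, accuracy, F-score, Cohen's kappa; per-iteration + average tables |

Everything runs on synthetic data generated in code — no downloads — and the
whole chain is deterministic under one seed.

## Worked example

```r
library(miclass)

# 60 trials/class, 9 s at 128 Hz, ERD depth 0.6, 5 dB SNR
cfg <- pipeline_config(
  data = list(n_trials_per_class = 60, erd_depth = 0.6),
  seed = 1)
res <- run_pipeline(cfg)
res
#> <pipeline_result>
#>   held-out: precision 100.00%  recall 100.00%  accuracy 100.00%  F 100.00%  kappa 100.00%
#>   network validation accuracy: 1.000
```

The held-out metrics come from the ID3 tree applied to deep features of the
60 test trials (stratified 50/50 split): at this ERD depth the contralateral
mu/beta attenuation is fully recoverable. With `erd_depth = 0` (no class
signal) the same pipeline stays at chance (≈ 40–60%).

Single stages compose just as well:

```r
ts  <- generate_mi_eeg(synth_config(n_trials_per_class = 20, snr_db = 0, seed = 3))
den <- mspca_denoise(ts)                       # subband PCA denoising
mean((den$data - attr(ts, "template"))^2) /
  mean((ts$data - attr(ts, "template"))^2)     # ~0.56: MSE nearly halved
```

```r
m <- metrics_from_cm(rbind(c(67, 3), c(2, 68)))   # a 140-trial confusion matrix
m
#> precision 97.10%  recall 95.71%  accuracy 96.43%  F 96.40%  kappa 92.86%
```

A thin command-line front end (`inst/cli/miclass.R`) exposes the stages as
subcommands (`simulate`, `denoise`, `scalogram`, `tune`, `train`, `features`,
`classify`, `evaluate`, `run-all`) driven by a YAML configuration
(`load_config()` / `dump_config()`).

## Documentation

The methods vignette (`vignettes/motor-imagery-pipeline.Rmd`) describes the
model assumptions, what the synthetic generator does and does not emulate,
the numerical choices (wavelet boundary handling, normalization modes,
optimizer defaults, tie-breaking) and known limitations.
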