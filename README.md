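# frozemg

Training-free gesture recognition from surface electromyography (sEMG).

Multi-channel sEMG recordings with per-sample gesture labels — the
structure used by hand-gesture benchmarks sampled at 100 Hz over ten
forearm electrodes — are segmented, decomposed, and mapped through a bank
of *frozen* random convolutions; only a closed-form linear readout is
fitted. The package is aimed at researchers who want a lightweight,
fully reproducible alternative to trained CNNs for myoelectric
classification, plus the statistical tooling to compare classifiers on
paired predictions.

## What it computes

* **Motion segmentation with GLR refinement.** Label-based segments are
  re-bounded by per-channel generalized likelihood-ratio change-point
  detection under a two-state (rest/motion) Gaussian variance model,
  fused across channels by earliest-onset / latest-offset voting.
* **Improved variational mode decomposition.** Each channel is split into
  K band-limited modes u_k by the spectral ADMM scheme
  (Wiener update with bandwidth penalty α, centroid update of ω_k,
  dual-ascent multiplier with step τ), refined by DC re-assignment,
  full-length least-squares amplitude calibration, and quality gating
  with fallback.
* **Weighted mode selection.** Score_i = 0.4 ρ'_i + 0.4 E'_i + 0.2 (1 −
  S'_i) over min–max-normalized correlation, energy ratio and sample
  entropy; the top mode per channel feeds the second branch.
* **Frozen dual-branch features.** Per branch, three dilated convolution
  modules (k, d) = (3,1), (5,3), (11,8) with 256 Kaiming-Normal filters
  each, frozen at initialization; every filter is summarised by GAP
  (temporal mean) and PPV (proportion of positive values), giving a
  3072-dimensional fused vector.
* **Closed-form ridge readout.** W = (DᵀD + αI)⁻¹DᵀY with one-hot Y,
  α = 0.039; prediction by argmax. Reports accuracy, macro
  precision/recall/F1 and multiclass MCC, with exact McNemar tests and
  Holm–Bonferroni adjustment for paired comparisons.
* **Synthetic generator.** Ten-channel recordings with alternating
  rest/motion runs, classes distinguished by sub-1 Hz spectral envelopes,
  known true boundaries and configurable label jitter — every stage is
  testable without downloading anything.

## Worked example

```r
library(frozemg)

cfg <- experiment_config(
  synth = synth_config(n_classes = 3, n_repetitions = 4,
                       motion_duration = 200, motion_jitter = 20,
                       rest_duration = 150, rest_jitter = 15,
                       boundary_jitter = 15, seed = 5),
  test_repetitions = c(2, 4), seeds = 42L, cv_folds = 2)
res <- run_experiment(cfg)

print(res$per_seed[["42"]])
#> ACC 100.00  PRE 100.00  REC 100.00  F1 100.00  MCC 100.00  (n = 6)
median(res$boundary$raw_err)      # stored labels vs truth:   7.5 samples
median(res$boundary$refined_err)  # after GLR refinement:     1 sample
```

The report line gives the test-split metrics (six held-out segments:
three classes × two held-out repetitions); the boundary medians show the
GLR stage recovering the true activity bounds from jittered labels.
Individual stages work standalone, e.g. the decomposition:

```r
t <- 0:1099
x <- sin(2 * pi * 0.3 * t / 100) + sin(2 * pi * 5 * t / 100)
vr <- vmd_decompose(x, vmd_config(K = 2, alpha = 2000), fs = 100)
round(vr$center_freqs, 3)                 #> 0.287 4.997
signif(vr$quality$reconstruction_error, 3) #> 0.0455
```

Recordings round-trip through the DB1-style MAT container and a
tab-delimited dialect (`write_recording()` / `load_recording()`), and
`inst/cli/frozemg.R` exposes `simulate`, `run` and `compare`
subcommands for shell use.

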