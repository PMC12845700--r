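---
title: "A frozen random-convolution pipeline for sEMG gesture recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A frozen random-convolution pipeline for sEMG gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Surface electromyography (sEMG) gesture classifiers are usually trained
end to end, which is expensive on embedded hardware and sensitive to the
strong non-stationarity of muscle signals. `frozemg` implements the
opposite trade: *no* convolution weight is ever trained. A bank of
multi-scale dilated 1-D convolutions is drawn once from a Kaiming-Normal
distribution, frozen, and used as a fixed feature map; only a closed-form
linear readout is fitted.

The pipeline, stage by stage:

1. **Preprocessing.** Each channel is low-pass filtered (first-order
   Butterworth, 1 Hz cutoff, applied forward–backward so the phase is
   zero). For envelope-sampled recordings at 100 Hz the discriminative
   gesture content sits below 1 Hz, so this both denoises and isolates
   the informative band. Motion segments are cut wherever the per-sample
   stimulus label is nonzero; rest is discarded.
2. **GLR boundary refinement.** Stored labels are produced by visual
   inspection and can be tens of samples off. For each segment the search
   window is expanded by 25% of the segment length per side (clipped at
   the neighbouring segments), and each channel is modelled as two
   zero-mean Gaussian states — rest and motion — differing in variance.
   The onset (and, independently, the offset) is the candidate change
   point maximizing the two-state log-likelihood over the window; a
   channel whose best statistic falls below a floor keeps its raw bound.
   Channels are fused by voting: earliest onset, latest offset.
3. **Variational mode decomposition.** Every channel of every segment is
   decomposed into `K = 2` band-limited modes by the ADMM-style spectral
   scheme: a Wiener-filter mode update with bandwidth penalty
   `alpha = 2000` on the normalized frequency grid, a spectral-centroid
   update of each center frequency, and a dual-ascent multiplier update
   with step `tau = 0` (which leaves the multiplier exactly at its
   initialization — implemented literally and verified by a test).
   Three refinements make the decomposition robust in practice: the DC
   offset is removed first and re-added to the lowest-frequency mode;
   mode amplitudes are recalibrated by full-length least squares (which
   can only reduce the reconstruction error); and quality indicators —
   relative L2 reconstruction error, per-mode energy ratio, convergence —
   gate a fallback. When the error exceeds 10% or the iteration cap is
   hit, the filtered channel itself substitutes for the selected mode
   downstream.
4. **Mode selection.** Per channel, each mode is scored by
   `Score = 0.4 * rho' + 0.4 * E' + 0.2 * (1 - S')`, where `rho` is the
   Pearson correlation with the original signal, `E` the energy ratio and
   `S` the sample entropy (m = 2, r = 0.2 SD, Chebyshev distance,
   self-matches excluded), each min–max normalized across the channel's
   modes. The top-scoring mode is kept (one per electrode channel, so the
   mode branch has the same shape as the raw branch).
5. **Frozen features.** Both the raw segment and the selected-mode
   segment (each standardized to 1100 samples: zero-padded at the end or
   head-truncated) pass through their own convolution bank. Each bank has
   three modules with kernel/dilation pairs (3,1), (5,3), (11,8) — local,
   mid-range and long-range receptive fields — 256 filters each, "same"
   zero padding `d(k-1)/2`, weights `N(0, 2/(C_in k))`, zero biases, and
   a ReLU. Each filter is summarised by two statistics: GAP (temporal
   mean) and PPV (fraction of strictly positive activations). That is
   512 values per module, 1536 per branch, 3072 fused.
6. **Ridge readout.** The only trained component:
   `W = (D'D + alpha I)^{-1} D' Y` with one-hot `Y` and `alpha = 0.039`;
   prediction is the row-wise argmax. For `n < d` the identical solution
   is computed through the dual form `W = D'(DD' + alpha I)^{-1} Y`.
7. **Protocol.** Recordings are split by repetition (test repetitions
   {2, 5, 10} by default), five run seeds {42, 123, 777, 2024, 2025}
   re-draw the frozen bank, and a group-aware five-fold cross-validation
   over training repetitions accompanies every run. The run seeds label
   independent replicates of the frozen bank and are treated as fixed
   protocol constants; the synthetic-data seed is the free randomness
   knob.

## The synthetic generator

`synth_config()` / `generate_recording()` emulate the structure of a
ten-channel, 100 Hz envelope-sampled recording: alternating rest and
motion runs organised in repetition blocks, per-sample stimulus and
repetition vectors, and known true activity boundaries. Each gesture
class is a rectified sum of two to four sub-1 Hz sinusoids — a distinct
dominant frequency on a deterministic grid plus random minor components —
scaled by fixed per-channel gains and a small per-execution amplitude
factor, with additive Gaussian noise everywhere. Stored labels are
shifted from the true boundaries by up to ±30 samples so that boundary
refinement has a measurable target.

Defaults (10 channels, 100 Hz, motion runs of 500 ± 50 samples, rest runs
of 300 ± 30, noise SD 0.1 against envelope amplitudes near 1, gain spread
±0.2) were chosen once as a plausible desk-scale regime: gestures of
about five seconds separated by a few seconds of rest, signal-to-noise
high enough that classes are separable by construction. The generator
emulates *structure*, not physiology: there are no motor-unit action
potentials, no electrode-placement effects, no inter-subject variability,
and the noise statistics are not calibrated to any real acquisition
system. Passing tests therefore demonstrate that the pipeline's stages do
what they claim on signals with known ground truth — not that any
particular accuracy will transfer to real recordings.

## Numerical choices

* **Zero-phase filtering** avoids boundary shifts; the signal is
  odd-reflection padded (six filter time constants) before the
  forward–backward pass to suppress edge transients.
* **GLR input signal.** Change points are detected on the *rectified
  unfiltered* signal. The zero-phase 1 Hz low-pass smears the rest/motion
  power step over roughly a second in both directions, which biases
  likelihood-based change points outward; on the raw signal the power
  step is abrupt and the detector is sample-accurate. Segment data is
  still cut from the filtered recording at the refined bounds.
* **VMD initialization** is deterministic: zero mode spectra, center
  frequencies uniformly spaced over (0, fs/4], zero multiplier. The
  signal is mirror-extended to double length before the FFT and cropped
  after inversion. Convergence uses the summed per-mode relative spectral
  change against `tol = 1e-7`, capped at 500 iterations. Center
  frequencies are reported sorted ascending.
* **Sample entropy** returns the sentinel `log((n-m)(n-m-1))` — the log
  of the reciprocal of the smallest resolvable match ratio — when either
  template count is zero; a constant series scores exactly 0.
* **Min–max degeneracy.** When all modes tie on an indicator
  (including the K = 1 case) the normalized value is 0.5: neutral and
  symmetric.
* **Score convention.** The combined score uses the *normalized* energy
  ratio, consistent with the normalization of the other two indicators;
  the raw-energy variant is available via `energy = "raw"`. For two
  modes, min–max pins the per-indicator normalized values to {0, 1}, so
  the scores are determined by which mode wins each indicator — only the
  selection outcome is meaningful, not the score magnitudes.
* **Convolution convention** is cross-correlation (no kernel flip), the
  deep-learning convention; biases are initialized to zero so the PPV
  statistic depends on the signal alone. The feature ordering — GAP block
  then PPV block per module, modules in configuration order, raw branch
  before the mode branch — is frozen as the on-disk contract, and both
  branches are drawn from one seeded stream so a single integer
  reproduces the whole bank.
* **Feature scaling.** z-scoring before the ridge fit is available but
  off by default. A quarter of the GAP/PPV features can have near-zero
  variance across a small training set (padding-dominated filters), and
  dividing test deviations by those tiny training scales amplifies noise
  enough to cost accuracy; GAP and PPV are already bounded and
  commensurate, and the dual-form solve is well conditioned without
  scaling.
* **Ties** break toward the lower index everywhere (mode selection,
  argmax prediction).

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen so each stage is exercised meaningfully: the benchmark is 8
classes × 10 repetitions × 10 channels (80 motion segments, 56 train /
24 test), decomposed per channel (800 VMD runs), with all five run seeds
and the GAP-only / PPV-only / combined ablation. Oracle checks (brute
force convolution, template-counting entropy, conjugate-gradient ridge,
binomial McNemar enumeration) run on small random instances.

## Known limitations

* The generator's spectral-template classes make the benchmark separable
  by construction; accuracy numbers on it are ceiling-level and say
  nothing quantitative about real electrode data.
* The multiplier update is inert at the default `tau = 0`; reconstruction
  fidelity rests on the Wiener updates plus least-squares recalibration.
* `K` is fixed per configuration; there is no automatic mode-count
  selection.
* The MAT container codec covers the uncompressed double-matrix dialect
  used by the writer (and by common scientific writers with compression
  disabled); it is not a general MAT reader.
* Metrics macro-average one-vs-rest precision/recall/F1 and use the
  Gorodkin multiclass Matthews correlation; binary formulas are recovered
  in the two-class case.
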