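---
title: "Rhythm and time-scale analysis of emotional EEG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm and time-scale analysis of emotional EEG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmeeg)
```

## The problem

Emotional state leaves signatures in scalp EEG that are specific both to
*frequency rhythm* — the canonical delta/theta/alpha/beta/gamma bands, each
associated with a different cognitive regime — and to *time scale*: affect
has a short-term-memory character, so the window length over which a
classifier integrates evidence matters. This package implements a pipeline
that makes that joint dependence measurable. For each pairing of a rhythm
band with a window length, it

1. reconstructs the band-limited rhythm signal from the multichannel
   recording by discrete wavelet transform (DWT) level selection,
2. cuts the rhythm signal into contiguous rectangular windows of `tS`
   seconds and flattens each window channel-major into one vector, giving a
   `T x E` sequence per trial (`E = n_channels * tS * sR`,
   `T = floor(duration / tS)`),
3. classifies the sequence with a gated recurrent (LSTM) network — one
   binary prediction per trial, targeting either the valence
   (negative/positive) or the arousal (passive/active) dimension of the
   affect circumplex, with ratings binarized at the inclusive cut-offs
   `<= 3` and `>= 7` — and
4. scores each cell with stratified ten-fold cross-validation (accuracy,
   sensitivity, specificity, macro-F1; mean ± SD over folds), selecting
   the (band, `tS`) cell with the highest mean macro-F1.

## Rhythm extraction

### Why a DWT and which one

The dyadic DWT splits a signal sampled at `fs` into detail levels covering
`(fs/2^(j+1), fs/2^j]` and a final approximation `[0, fs/2^(J+1)]`.
Reconstructing from a subset of levels yields a time-domain signal
containing only those bands. We use the 4th-order Daubechies wavelet
(8 taps) by default — compactly supported, near-standard in EEG band work —
with `db2` and `haar` available; the analysis filters are the published
orthonormal coefficients.

The decomposition depth defaults to `round(log2(fs)) - 3`, which places the
deepest detail level exactly over theta (4–8 Hz): depth 5 at 256 Hz, depth
4 at 128 Hz. Each detail level is assigned to the named band containing its
geometric-center frequency, and the approximation belongs to delta. At
256 Hz this gives theta ← d5, alpha ← d4 (8–16 Hz), beta ← d3 (16–32 Hz)
and gamma ← d2 *and* d1 (32–128 Hz). Gamma deliberately absorbs every
level above the beta levels: the level sets then partition the pyramid, so
the five band reconstructions *sum to the input exactly* — the central
correctness invariant of the module, tested to 1e-6 relative error and in
practice exact to machine precision.

### Boundary handling

We use periodized signal extension rather than symmetric mirroring. With
periodization the transform matrix is orthonormal, which buys three exact
properties at once: perfect reconstruction, energy conservation
(Parseval), and additivity of partial reconstructions. Symmetric extension
is friendlier to strong edge trends but makes perfect reconstruction only
approximate at the boundaries; for windows of stationary oscillatory EEG
the periodization artifact is negligible and exactness is worth more.
Odd-length segments are replicate-padded to even length at each pyramid
stage, with original lengths recorded so the inverse is still exact.

### Printed versus dyadic band edges

The conventional printed band table (alpha 8–13 Hz, beta 14–30 Hz) cannot
be realized by a dyadic transform, whose edges at 256 Hz fall on
4/8/16/32/64 Hz. The default mode therefore uses the nearest dyadic edges
(alpha ≈ 8–16, beta ≈ 16–32), as is standard in DWT-EEG work. An optional
`exact_edges = TRUE` mode reconstructs from *all* levels overlapping the
printed range and then applies a zero-phase FFT band-pass at the printed
edges. That mode sharpens the edges but sacrifices exact five-band
additivity, which is why it is not the default.

## Windowing

Windows are non-overlapping and contiguous (stride = window length), the
flattening order is channel-major (all of CH1's samples, then CH2's, ...),
and a trailing remainder shorter than one window is dropped rather than
zero-padded — padding would inject a spurious amplitude step exactly where
the classifier is most sensitive. All three choices are pinned by tests.
A whole trial yields one sequence and one prediction; windows are time
steps of that sequence, not independent training samples. An optional
mean-pooling factor can reduce `E` for very long windows; it is off by
default because pooling averages an oscillation toward zero.

## The sequence classifier

No statement about layer sizes, optimizer or epochs is inherent to the
method, so these are engineering defaults, all configurable through
`model_config()`:

| parameter | default | rationale |
|---|---|---|
| layers / hidden units | 1 × 24 | smallest standard design that learns the synthetic benchmark reliably |
| optimizer | Adam, lr 1e-2 | fast convergence at small n; BPTT is the standard backward pass |
| batch size | 16 | more updates per epoch than full batch, converges in far fewer epochs |
| epochs | ≤ 40, early stop patience 8 | monitored on a seeded stratified 15% validation split |
| class weights | inverse frequency | rating binarization yields imbalanced classes |
| input scaling | per-feature z-score | computed on training folds only, so no leakage into test folds |

The readout is a single sigmoid unit on the final hidden state; class 1 is
predicted iff the probability is at least 0.5. The forget-gate bias is
initialized to 1 (standard), gradients are clipped at global norm 5, and
every random element — initialization, validation split, batch order —
derives from one integer seed, making training bit-reproducible. With
full-batch updates (`batch_size = Inf`) training is additionally invariant
to trial order; with mini-batches the internal shuffle is seed-controlled,
so reruns are still identical.

The z-scoring has a useful exact consequence: rescaling all inputs by any
positive constant and retraining reproduces the same model, because the
normalized features are unchanged.

## Evaluation

Accuracy, sensitivity (TPR) and specificity (TNR) are reported in percent;
macro-F1 is the harmonic mean of macro-precision and macro-recall, each
averaged over the two classes (the second class's precision/recall are
computed on the class-swapped confusion matrix). Macro-F1 is reported on
the `[0, 1]` scale and also ×100, since both conventions circulate. A
metric with a zero denominator is reported as `NA` with a warning — never
silently as 0, which would corrupt grid comparisons.

Cross-validation is stratified by class (plain random tenfold can empty
the minority class from folds at realistic imbalance, e.g. 222 vs 373
trials), splits by trial with subjects pooled, and reports the across-fold
sample standard deviation (ddof 1). Fold assignment and per-fold model
seeds derive deterministically from the CV seed.

## The grid experiment

`run_grid()` crosses the four default bands theta/alpha/beta/gamma with
the nine default time scales 0.25–6 s (36 cells per emotion dimension; the
delta band is supported but excluded from the default grid, matching common
practice of discarding the drift-dominated band). Rhythm extraction is
computed once per band and shared across scales. Each cell is evaluated
with seed `base_seed + cell_index`, so a single-cell rerun reproduces its
full-grid result exactly and the grid is embarrassingly parallel in
principle. Cells can be checkpointed to disk and are reused on resume;
infeasible cells (window longer than the trial) are flagged failed while
the rest of the grid continues.

The best cell maximizes mean macro-F1, with ties broken by higher mean
accuracy and then by the smaller time scale (cheaper windows). Selection
by macro-F1 rather than raw accuracy is a deliberate choice: with
imbalanced classes accuracy rewards majority-class bias, and macro-F1 is
the metric that treats both affect poles symmetrically.

## The synthetic benchmark

`synth_spec()` / `generate_trials()` produce two-class trials that are
Gaussian broadband noise on every channel plus, on an affected subset of
channels, a sinusoid with trial-random frequency inside one rhythm band
and channel-random phase. Class 1 carries the oscillation at
`effect_amplitude_ratio` times the class-0 amplitude; ratings are 2 and 8,
so binarization recovers the classes away from its boundaries. A
sinusoid-in-noise design was chosen over AR-model EEG surrogates because
its band power is analytically controllable, which is exactly what
validating rhythm selectivity requires.

The standard benchmark (`benchmark_suite()`) fixes the study conditions at
40 trials per class, 8 channels, 12 s at 128 Hz, amplitude ratio 3 on half
the channels, with a null (ratio 1), a theta-effect and an alpha-effect
dataset. These sizes keep a full 36-cell grid with tenfold CV to a few
minutes on one CPU while leaving the planted effect clearly detectable.
On this benchmark the grid selects the planted band with best-cell
accuracy typically in the high 80s, and the null dataset stays at chance
(no cell's macro-F1 exceeding 0.5 by more than two fold-SDs).

What the benchmark does *not* emulate: 1/f background spectra, volume
conduction and channel covariance, non-stationarity, artifacts, or
inter-subject variability. Passing it demonstrates that the pipeline's
plumbing, band mapping, training and selection logic are correct — not
that any particular accuracy will transfer to real recordings, where
effect sizes are far smaller and published binary affect accuracies
cluster in the 60–70% range.

## Degenerate inputs and numerical choices

* Recordings with NaN/Inf samples are rejected at construction, naming the
  channel and sample index.
* Downsampling applies a zero-phase Butterworth low-pass (≥ 40 dB above the
  target Nyquist) before decimation; rational ratios go through
  Fourier-domain resampling. Upsampling is refused.
* EDF I/O quantizes to 16 bits over the per-channel range; flat channels
  are widened by one unit to avoid a zero quantization step. Long
  recordings are split across EDF records transparently.
* A decomposition deeper than the signal allows is refused with the
  maximum feasible depth; a band entirely above Nyquist is an error.
* Tie-breaks in best-cell selection are total and documented, so the
  selection is deterministic.

## Preprocessing scope

Artifact removal and blind source separation are upstream of this package:
public affect benchmarks ship preprocessed, already-cleaned releases, and
ICA is a solved problem in dedicated toolboxes. `preprocess_hook()` is the
seam where such cleaning can be slotted in; its default is a pass-through.
Note that different releases of the same benchmark circulate at different
sampling rates — the I/O layer always records the rate found in the file
metadata and the pipeline uses that, rather than assuming a nominal rate.

## Known limitations

* The dyadic band edges only approximate the printed alpha/beta edges (see
  above); `exact_edges` trades additivity for edge fidelity.
* The LSTM consumes raw rhythm samples, as the method prescribes; at large
  `tS` the flattened window dimension `E` grows into the tens of
  thousands, which slows training and (at fixed trial counts) starves the
  sequence dimension — on the synthetic benchmark small windows dominate
  for exactly this reason.
* Cross-validation pools subjects (subject-dependent evaluation); a
  leave-subject-out mode would need per-trial subject identifiers, which
  the trial container does not yet carry.
* No statistical test is attached to between-cell comparisons; the grid
  reports means and fold-SDs only.
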