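---
title: "Digitizing and classifying cardiotocography charts: methods and design"
author: "ctgvision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing and classifying cardiotocography charts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electronic fetal monitoring produces cardiotocograms (CTGs): paired traces
of fetal heart rate (FHR, beats per minute) and uterine activity (UC, mmHg)
that obstetricians read visually. Inter-reader variability is a well-known
weakness of visual interpretation, which motivates objective, image-based
triage of recordings into a binary decision: *Reassuring* (routine care)
versus *Non-Reassuring* (heightened surveillance). The non-reassuring class
amalgamates the FIGO "suspicious" and "abnormal" categories, since both
demand clinical attention; when an objective outcome is preferred, an
umbilical-artery pH below 7.05 defines the abnormal class, with the
boundary value 7.05 itself counted as normal.

`ctgvision` implements the full chain as a testable artifact:

1. **chart synthesis** — simulate 20-minute recordings with
   class-conditional morphology and render them as gridded report pages
   with exact pixel-level ground truth;
2. **digitization** — recover physical-unit time series from a page image;
3. **model** — a CBAM-enhanced EfficientNet-B0 classifier built from first
   principles;
4. **evaluation** — confusion-matrix metrics, ROC/PR analysis, stratified
   cross-validation, staged t-SNE embeddings, and cohort-comparison
   statistics;
5. **pipeline** — one orchestrated, seeded experiment runner plus a WFDB
   adapter for external signal databases.

Because no clinical images ship with the package, the synthetic generator
is first-class code: every downstream stage is exercised end to end against
known ground truth.

## Digitization model

**Grid removal.** On CTG report pages the curves print brighter than the
grid and shadow background. After conversion to 8-bit grayscale (Rec. 601
luminance for RGB input), a single global threshold of 65 separates them:
pixels with gray value at least 65 are trace, everything below is
background. The boundary value 65 itself is kept as foreground. The
synthetic renderer enforces the same contract from the other side (grid and
shadow strictly below 65, trace ink at or above), which makes binarization
an exact inverse of rendering and lets the test suite require pixel-perfect
mask recovery.

**Pixel-to-value mapping.** Each of the four curve regions (FHR then UC for
the first ten minutes, FHR then UC for the second) carries a linear value
axis: `v = vmin + y'/h * (vmax - vmin)`, where `y'` counts rows upward from
the bottom edge of the region and `h` is the row span `rowMax - rowMin`.
Image rows grow downward while values grow upward, so the bottom row maps
to `vmin` (60 bpm for FHR, 0 mmHg for UC) and the top row to `vmax`
(210 bpm / 100 mmHg). This orientation convention is the package's own
(and is tested against an independent interpolation oracle); the renderer
uses its exact inverse with nearest-neighbour row placement and no
anti-aliasing, so vertical quantization — one row, i.e. `(vmax - vmin)/h`
physical units — is the only systematic round-trip error for constant
traces.

**Column sampling and gaps.** Output samples are taken at fixed horizontal
intervals set by the region width and the recording duration (default
4 Hz, matching the convention of the public intrapartum CTG database used
for external validation). In each sampled column the trace row is the
*median* foreground row, which is robust to trace thickness and isolated
speckles; the median of an even run falls between rows and is mapped
fractionally. Columns without foreground are flagged invalid and filled by
linear interpolation between the nearest valid neighbours; gaps touching
the region edge hold the nearest valid value. The validity mask is kept on
every `TraceSignal` so downstream consumers and tests can exclude
interpolated stretches.

**Splicing and standardization.** The two 10-minute segments per channel
are concatenated chronologically into 20-minute series. For the
classifier, the reconstructed series — not the raw photograph — are
re-rendered onto a blank 224 x 224 canvas (FHR in the upper half, UC in the
lower, each against its own axis via the same linear mapping), replicated
to three channels and Z-score normalized per image with an epsilon guard
(a zero-variance canvas yields an all-zero tensor). Re-rendering was one of
two defensible readings of the pipeline description; it was adopted because
it guarantees the model input depends only on the recovered signals, never
on residual page artifacts.

## Network

The classifier is an EfficientNet-B0 backbone with a convolutional block
attention module (CBAM), implemented in this package from first principles
(R with C++ kernels) with hand-derived backpropagation. There is no deep
learning framework dependency; every operator — dense and depthwise
convolution, batch normalization, SiLU, pooling, gating — is verified in
the test suite against brute-force oracles and central finite differences.

* **Stem**: 3x3 stride-2 convolution + batch normalization + SiLU, mapping
  `3 x 224 x 224` to `32 x 112 x 112`.
* **Backbone**: the canonical B0 schedule of mobile inverted bottleneck
  (MBConv) blocks — widths 16/24/40/80/112/192/320, repeats 1/2/2/3/3/4/1,
  kernels 3/3/5/3/5/5/3, strides 1/2/2/2/1/2/1 — ending in a `320 x 7 x 7`
  feature map. The first stage uses expansion 1 (MBConv1), the rest
  expansion 6 (MBConv6). The published description names B0 but prints no
  stage table, so the canonical schedule is adopted; descriptions that
  count "six MBConv stages" group the seven width changes differently, and
  the spatial ladder (112 -> 56 -> 28 -> 14 -> 7) is identical either way.
* **MBConv block**: 1x1 expansion (skipped at expansion 1), depthwise
  convolution (same padding `k %/% 2`), squeeze-and-excitation gate
  `sigmoid(W2 relu(W1 GAP(F)))` with hidden width `floor(cin/4)` relative
  to the block's input channels, 1x1 projection, and the inverted residual
  `Y = X + F(X)` exactly when stride is 1 and channel counts match.
* **CBAM**: applied once, on the final `320 x 7 x 7` feature (the stated
  placement "after the final projection layer"; per-block insertion is a
  possible alternative reading that is not implemented). Channel gate:
  `Mc = sigmoid(MLP(AvgPool F) + MLP(MaxPool F))` with a shared MLP and
  reduction 16 (the original CBAM default; the source states none).
  Spatial gate: `Ms = sigmoid(conv7x7([mean_c F'; max_c F']))`. Refinement
  is serial: `F'' = Ms (x) (Mc (x) F)`. Both maps are sigmoid outputs, so
  refinement can only attenuate activations — a property the tests assert.
* **Head**: adaptive average pooling to a 320-vector, dropout 0.2 (training
  only), and a fully connected layer to 2 logits with softmax
  cross-entropy. The canonical B0 1x1 expansion to 1280 channels before
  pooling is available behind `buildNetwork(expandedHead = TRUE)` but off
  by default, following the stated head layout. The published parameter
  count ("5.00 million") matches neither head variant exactly and is not
  asserted; the default build has about 3.6 million parameters.
* **Compound scaling** (`compoundScale()`): the B1-B7 power law
  `d = alpha^phi, w = beta^phi, r = gamma^phi` is provided as a utility;
  only B0 is instantiated.

**Initialization and determinism.** Weights are He-normal from a seed; no
pretrained weights are downloaded (transfer learning is out of scope for a
self-contained artifact). Batch normalization uses eps `1e-5` and momentum
0.1 (common framework defaults; the source states none). All randomness —
initialization, shuffling, dropout — derives from explicit seeds, and
training is bit-reproducible.

## Training

`trainConfig()` defaults follow the reference protocol for clinical-scale
data: Adam with learning rate `1e-4`, batch size 64, weight decay `1e-5`
(added to gradients), cross-entropy loss, and early stopping with patience
5 on the validation loss, restoring the best-epoch weights.

The **toy experiment** that the test suite and acceptance script run end to
end uses a configuration chosen for training from random initialization on
a few hundred synthetic charts: learning rate `1e-3`, batch size 8, at most
8 epochs (within the ten-epoch budget the evaluation protocol allows). The
smaller batch gives ~40 gradient updates per epoch on 320 training images
— appropriate when no pretrained features are available — and also bounds
activation memory on a single CPU. Problem sizes used: the acceptance test
trains on n = 400 charts (stratified 80/20 holdout), the acceptance script
on n = 200; round-trip digitization is checked on 50 charts; unit tests use
miniature tensors throughout.

## Synthetic data: what it does and does not emulate

`makeDataset()` draws per-recording parameters from fixed ranges:

* baseline FHR uniform in 120-160 bpm; resting uterine tone 5-15 mmHg;
  contractions every 2-3 minutes lasting 60-90 s with peaks of 40-80 mmHg;
* **reassuring** recordings: band-limited variability with peak-to-peak
  amplitude 5-15 bpm plus 3-6 accelerations of 15-25 bpm lasting 15-30 s
  (the standard "15 bpm for 15 s" acceleration criterion);
* **non-reassuring** recordings: reduced variability (1-3 bpm) and late
  decelerations — dips of 20-40 bpm lasting 30-60 s whose nadir lags the
  contraction peak by 20-60 s.

These are textbook CTG pattern definitions; the source names the patterns
(late decelerations, reduced variability) but provides no generator, so
the ranges above are this package's explicit modelling choice, fixed once.
Variability is a sum of random-phase sinusoids in the 0.03-0.3 Hz band
normalized to the requested peak-to-peak amplitude; events are Gaussian
bumps truncated to their stated windows, so an event's peak equals its
nominal amplitude exactly — which gives the simulators sharp, testable
contracts. FHR is clipped to the chart range 60-210 bpm and UC to
0-100 mmHg.

The renderer emulates bright traces over a darker grid with shadow bands
and the four-region page layout (default 1200 x 800 px, configurable via
`ChartLayout`; the exact geometry of any vendor's report is unknown and
not imitated). It does **not** emulate page skew or warp, ink bleed,
anti-aliasing, scanner noise, overlapping annotations, or grid ink that
crosses the binarization threshold. Passing the round-trip and end-to-end
tests therefore demonstrates that the pipeline's mechanics are correct and
that the classifier can learn the class-defining morphology from its own
inputs — it does not establish clinical performance on real report
images, which the original study measured on private data.

## Evaluation choices

* Non-Reassuring is the positive class everywhere. `metricsFromConfusion`
  returns accuracy, sensitivity (recall), specificity, precision, the
  positive-class F1 and the macro F1 (mean of the two per-class F1 scores;
  published F1 values are treated as macro). Zero-denominator ratios
  surface as `NaN` with a warning rather than silently.
* AUC uses the rank (Mann-Whitney) formulation with midranks for ties; AP
  is the step-wise, non-interpolated sum evaluated at distinct score
  thresholds, whose random-ranking baseline equals the positive prevalence
  (0.37 for the 602 : 1020 cohort).
* Stratified k-fold assignment deals each class out as evenly as possible,
  sending remainders to the currently smallest folds so fold sizes stay
  balanced; fold metrics aggregate as mean and *sample* (n-1) standard
  deviation, and fold confusion matrices sum elementwise.
* Cohort comparison uses Welch's t-test computed from summary statistics
  (raw cohort data are unavailable by construction) and, for 2x2 tables,
  the *continuity-corrected* chi-square: the corrected form reproduces the
  published cohort p-values (0.543, 0.992, 0.155) to three decimals,
  whereas the uncorrected Pearson statistic does not (0.114 for the Apgar
  row), so the corrected form is what the published table actually used
  despite its note naming Pearson's test generically.
* Staged embeddings tap the raw input, the end of backbone stages 3 and 6,
  and the post-CBAM pooled vector, and reduce each with an exact
  (non-approximated) t-SNE implemented in the package — no R t-SNE
  dependency is available — with perplexity 30 capped at `(n-1)/3`, early
  exaggeration for 100 iterations and 1000 iterations total, seeded.

## Numerical and degenerate-input conventions

* Binarization: `>= threshold` keeps a pixel; a uniform sub-threshold page
  digitizes to a "no trace found" error rather than an empty series.
* Median row of an even-length foreground run is fractional; the linear
  map handles fractional rows exactly.
* Z-score standardization uses the population standard deviation (so the
  normalized tensor has exactly unit variance) and an `eps` guard for
  constant canvases.
* WFDB adapter: format-16 records only; FHR samples equal to 0 are treated
  as sensor dropout (invalid + interpolated, the same gap policy as
  digitization); records longer than 20 minutes are cropped to the final
  20 minutes, closest to delivery — a package convention, not a claim
  about the original study's windowing.
* `pH = 7.05` maps to reassuring (the boundary is inclusive on the normal
  side); FIGO "suspicious" and "abnormal" both map to non-reassuring.

## Known limitations

* The chart layout is configuration, not inference: region boxes must be
  supplied (or defaulted) rather than detected, so pages from unknown
  devices need a one-off layout description.
* The digitizer assumes ideal geometry; skewed or warped scans are out of
  scope.
* Training at the published clinical scale (1,622 recordings, pretrained
  backbone, GPU) is not reproduced; the package demonstrates correctness
  at desk scale with seeded synthetic data, and the published cohort-level
  accuracies are touched only through their printed confusion-matrix
  worked examples.
* The t-SNE implementation is exact and therefore quadratic in the number
  of samples; it is intended for the few hundred points the staged
  embedding analysis uses.
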