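---
title: "Guiding CNN attention with human gaze spotlights: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guiding CNN attention with human gaze spotlights: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeSpotlight)
```

## The scientific question

Deep convolutional networks recognize objects well, but do they *look* at
the same image parts humans do? One way to probe this is purely
data-driven: record where people fixate while categorizing images, keep the
fixated regions sharp while blurring everything else (a **Human-Spotlight**,
HS), or do the inverse (**Anti-Spotlight**, AS, blurring exactly the fixated
regions), fine-tune otherwise identical classifiers on each version, and
ask whether the models' Grad-CAM saliency now aligns better or worse with
human gaze. The package implements this pipeline end to end and quantifies
human-likeness as the per-image Pearson correlation between a model's
saliency map and the cohort-averaged fixation-density heatmap, transformed
to Fisher Z for linear comparability.

The interesting prediction is asymmetric: removing the features humans use
(AS) should make attention reliably *less* human-like — especially on
images containing faces, which attract fixations strongly — while the loss
in categorization accuracy stays modest, because much class information
survives in the un-fixated context.

## Pipeline

1. **Gaze heatmaps** (`selectInImage()`, `windowSamples()`,
   `accumulateDensity()`, `smoothAndNormalize()`, `averageParticipants()`):
   1,000 Hz gaze samples are clipped to the displayed image, converted to
   image-pixel coordinates, tallied per pixel, grouped into 50 ms windows
   over the first 1,000 ms (20 discrete windows) or pooled over the whole
   1,500 ms presentation, smoothed with a Gaussian (SD 20 px at the native
   227 px resolution), peak-normalized per participant, averaged across
   participants and peak-normalized again.
2. **Spotlight manipulation** (`tertileMask()`, `applySpotlight()`):
   pixels whose pooled, peak-normalized density falls below the first
   tertile of the value range (threshold 1/3) are blurred (HS) or kept
   (AS); a Gaussian blur (window 30, SD 7) is composited with the sharp
   image through the binary mask softened by an edge taper (window 35,
   SD 9).
3. **Fine-tuning** (`buildTrainingSet()`, `fineTune()`, `repeatRuns()`):
   a frozen convolutional backbone with a replaced softmax head, trained
   with SGDM (momentum 0.9), batch 42, learning rate 1e-4 with a factor-20
   multiplier in the head, at most 30 epochs, validation patience 5, no
   augmentation. Repeated over seeded runs (10 per condition by default)
   with shuffled stratified train/validation splits.
4. **Saliency** (`gradcam()`): Grad-CAM from the last convolutional layer
   for the true class label (also for misclassified images), channel
   weights = spatially averaged gradients of the pre-softmax logit,
   rectified weighted activation sum, bilinear upsampling, min–max
   normalization.
5. **Metrics** (`pearsonFisher()`, `similarityTable()`,
   `faceDetectionIndex()`, `groupSummary()`, `tradeoffCurve()`): per-image
   similarity records (overall and per 50 ms window), a face-detection
   index (attention mass inside the face ROI divided by mass outside),
   grouped summaries with seeded percentile-bootstrap CIs (B = 2000,
   resampling images), and accuracy-versus-similarity trade-off tables
   across manipulation ratios (100 → 0 % in steps of 10, i.e. 11 dataset
   variants).

Correlations are always computed per image and then aggregated — never
pooled across images at the pixel level.

## The synthetic cohort: what it emulates, and what it does not

No human recordings ship with the package. The `synthetic_data` functions
generate both sides of the comparison:

- **Stimuli** (`generateStimulusSet()`): 12 entry-level categories
  (6 animate, 6 inanimate), 30 exemplars each, at a configurable
  resolution. Inanimate categories carry distinct saturated body hues —
  color alone identifies a car or a flower. Animate categories share a
  narrow band of warm, overlapping hues (animals are brown-gray-ish) and
  carry, with probability 0.75, a circular face patch: a stripe texture
  whose orientation and spatial frequency are category-specific, plus two
  dark eye dots shared across the family. The face texture is therefore
  *partially* class-discriminative: a classifier can lean on it, but color
  and body shape carry information too. This is the configuration under
  which the AS manipulation can dissociate accuracy from human-likeness —
  blurring faces removes a cue the model would use *and* the region humans
  fixate, while enough context survives for categorization. The 0.75 face
  probability matches the roughly three-quarters share of face-bearing
  exemplars among animate images in comparable natural-image sets.
- **Gaze** (`simulateScanpath()`, `simulateCohort()`): a two-state renewal
  process. Gaze starts at screen center (the fixation-cross position),
  stays there for a saccade-programming latency (mean 175 ms, SD 15 ms,
  i.e. inside the 150–200 ms feedforward-sweep window), then lands on the
  face-ROI centroid with probability `faceBias` (0.85 by default, when a
  face is present) or the object centroid otherwise, with Gaussian landing
  noise; subsequent refixations occur at 2 Hz and scan the object (uniform
  points within the object ROI, or the face again under the bias).
  Participants perturb latency, face bias and noise through log-/logit-
  normal hyper-distributions; every seed is recorded in the manifest.

The generator does **not** model pupil dynamics, blinks, smooth pursuit,
microsaccades, saliency-driven free viewing, or natural image statistics.
Passing tests therefore show that the *pipeline* recovers planted structure
(a face bias expressed after a realistic latency), not that the effects
would replicate on natural images — the directional conclusions at native
scale depend on real gaze and real photographs. The native-scale parameter
defaults are kept wherever a published recipe exists; per-participant
fixation statistics are stated assumptions, not calibrated fits.

## Numerical choices

- **Tertile rule.** "Below the first tertile" is read as a *value*
  threshold of 1/3 on the peak-normalized density, not the 33rd percentile
  of pixel values: a percentile rule would blur exactly a third of every
  image by construction, whereas a value threshold on a focal density
  blurs most of it under HS and little of it under AS — the asymmetry the
  blurred-extent statistics require. The threshold is configurable.
- **Gaussian filters.** "W" is the square kernel window in px at the
  stated SD. Even windows would shift the image by half a pixel, so they
  are rounded up to the next odd size; the SD governs the blur. Borders
  are reflective (symmetric), which conserves total mass exactly — density
  smoothing therefore redistributes, never loses, gaze mass. Smoothing
  kernels without an explicit window are truncated at 4 SD.
- **Resolution scaling.** Kernel geometry (smoothing SD 20 px, blur 30/7,
  taper 35/9) and gaze noise (20 screen px ≈ half a degree at the
  reference 454 px display) are defined at the native 227 px scale.
  `scaledHeatmapConfig()`, `scaledManipulationSpec()` and
  `scaledGazeModelParams()` rescale them proportionally so the geometry
  covers the same image fraction at the 64 px desk scale used by the test
  suite.
- **Accumulation rule.** Raw 1 kHz samples are tallied per pixel
  (dwell-time weighting); no fixation-event detection. Sample coordinates
  are mapped into image pixels (floor after subtracting the origin and
  dividing by the display scale factor) and accumulated at image
  resolution directly, avoiding a resampling-kernel choice. The window
  clock runs on presentation time; out-of-image samples are dropped but do
  not shift window boundaries. Windows are contiguous and non-overlapping
  (20 at the defaults), with a cumulative mode available as a flag.
- **Edge taper target.** The taper is applied to the binary keep mask
  (soft alpha compositing), not to the composited seam — the "edge taper"
  reading that keeps the composite a pointwise convex combination of the
  sharp and blurred image.
- **Backbone.** No pretrained weights are assumed: the desk-scale "small"
  backbone (3 conv + 2 fully connected layers) uses a seeded He
  initialization with two deliberate twists. Convolution filters are made
  zero-mean, so units respond to local structure (edges, texture, color
  opponency) rather than absolute luminance, and the conv stage ends in
  global average pooling, so the class evidence reaching the head stays
  tied to last-conv channels — the layout Grad-CAM attributes most
  faithfully, which matters when the backbone is random rather than
  pretrained. Frozen fully connected layers get a small positive bias
  (0.1) so random ReLU units stay alive. An "alexnet-like" preset
  (5 conv + 3 fc, flattening) exists as a configuration option.
- **Head training.** Features are standardized with training-split
  statistics before the head (standard practice for a linear probe on
  fixed features); the standardization is part of the trained model and is
  used consistently at evaluation and in the Grad-CAM backward pass. The
  validation split is stratified by category so every class is covered at
  30 exemplars per category; "validation patience 5" is early stopping on
  the validation loss evaluated once per epoch, returning the
  best-validation weights. Momentum defaults to 0.9 (unstated in the
  recipe, configurable). A training loss that turns non-finite aborts with
  diagnostics.
- **Grad-CAM.** The gradient target is the pre-softmax logit of the true
  class (stable under adding constants to all logits); upsampling is
  bilinear with the half-pixel center convention; normalization is min–max
  after rectification. A constant-positive pre-map normalizes to all ones;
  an identically zero map is returned flagged, not as an error. Pearson r
  is invariant to positive affine rescaling of either map, so the
  normalization dialect cannot affect similarity.
- **Degenerate records.** Zero-variance maps raise a classed condition and
  the record is dropped with a logged reason — never silently recorded as
  zero. The face index floors the outside mass at 1e-9 of the total and
  flags capped values; images without a face ROI are excluded from face
  analyses.
- **Determinism.** Every stage draws from named sub-streams of one master
  seed (`deriveSeed()`), and package functions restore the caller's RNG
  state. Stimulus sets, cohorts and repeated runs are bit-reproducible.

## Desk-scale study conditions

`runSpotlightExperiment()` runs the whole design in a few minutes on one
CPU at the following sizes, chosen once as the package's standard synthetic
conditions: 64 px stimuli, 12 categories × 30 training exemplars, a
disjoint 12 × 15 test set with its own simulated cohort, 23 simulated
participants, face bias 0.85, and 10 head-only runs per manipulation mode;
`runTradeoffSweep()` reuses the cached context for ratio sweeps (the test
suite sweeps 3 ratios × 5 seeds). The training cohort's pooled 1,500 ms
heatmaps drive the manipulation; the test cohort provides the pooled and
per-window comparison maps, mirroring the train-on-one-half /
test-on-the-other-half design of eye-tracking experiments.

```{r, eval = FALSE}
exp <- runSpotlightExperiment(masterSeed = 1, modes = c("STD", "HS", "AS"))
exp$summary                       # per-mode accuracy, Fisher-Z, face index
sweep <- runTradeoffSweep(exp, mode = "AS", ratios = c(100, 50, 0),
                          nRunsPerRatio = 5)
sweep$curve                       # accuracy/similarity vs ratio with CIs
```

The tidy outputs (`exp$similarity`, `exp$runSummary`, `exp$faceIndexModel`,
`exp$faceIndexHuman`, `exp$blur`) are keyed by mode, run, image and window
so any external statistics tool can consume them; inferential tests
(Welch-ANOVA, Kruskal–Wallis, Wilcoxon, ANOVA-type statistics,
dependent-correlation comparisons) are deliberately not reimplemented here
— those are library-grade routines, and this package's contribution is the
measurement pipeline.

## Known limitations

- The synthetic backbone is randomly initialized, not pretrained; only the
  head is fine-tuned, so absolute accuracies and similarities are not
  comparable to published values obtained with a pretrained AlexNet on
  natural images — only the directional contrasts are.
- Grad-CAM resolution is the last-conv grid (16 × 16 at 64 px input)
  upsampled bilinearly; fine-grained attention structure below that grid
  is invisible.
- The scanpath model is a renewal process with centroid/ROI targets; it
  has no saliency competition, no inhibition of return, and no
  center-of-gravity landing effects.
- The "first tertile" value-threshold reading, the mask-target edge taper
  and the mass-ratio face index are interpretive choices where the recipe
  is ambiguous; each is flagged in the relevant class and exposed as a
  parameter.
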