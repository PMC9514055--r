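# gazeSpotlight

Can human overt visual attention be transplanted into a convolutional
image classifier through the training data alone? `gazeSpotlight`
implements the full measurement pipeline for that question, aimed at
computational-neuroscience and vision researchers comparing model saliency
with eye-tracking data:

- **Fixation-density heatmaps** from 1,000 Hz gaze samples: in-image
  selection, 50 ms time windows over the first 1,000 ms (20 discrete
  windows), per-pixel dwell counts, Gaussian smoothing (SD 20 px at
  227 px resolution, reflective borders), peak normalization, participant
  averaging.
- **Spotlight manipulations**: *Human-Spotlight* (HS) blurs image parts
  whose pooled fixation density falls below the first tertile of the
  normalized value range (threshold 1/3) and keeps fixated parts sharp;
  *Anti-Spotlight* (AS) is the exact complement. Blur: Gaussian W = 30,
  SD = 7; edge taper on the keep mask: W = 35, SD = 9. Ratio-mixed
  training sets replace 0–100 % of each category's images in 10 % steps
  (11 variants).
- **Transfer learning**: frozen backbone, replaced softmax head, SGDM
  (momentum 0.9), batch 42, learning rate 1e-4 with a ×20 head factor,
  ≤ 30 epochs, validation patience 5, no augmentation, repeated seeded
  runs.
- **Grad-CAM saliency** for the true class from the last convolutional
  layer: channel weights are the spatial mean of the pre-softmax logit's
  gradient, maps are rectified weighted activation sums, bilinearly
  upsampled and min–max normalized.
- **Human-likeness metrics**: per image,
  `r = cor(saliency, gaze heatmap)` over pixels and `z = atanh(r)`
  (Fisher Z), overall and per time window; a face-detection index
  (attention mass inside the face ROI / mass outside); grouped summaries
  with percentile-bootstrap CIs; accuracy-versus-similarity trade-off
  curves across manipulation ratios.

A seeded synthetic-data module generates category-discriminative stimuli
with object/face ROI masks and simulates gaze cohorts (central onset,
~150–200 ms saccade latency, configurable face bias, participant
variability), so the entire pipeline is testable without human
recordings. See the methods vignette
(`vignettes/guided-attention.Rmd`) for the model, parameter and design
details.

## Worked example

A reduced experiment (12 categories × 15 training images, 10 simulated
participants, 5 runs per mode, ~30 s on one CPU):

```r
library(gazeSpotlight)
exp <- runSpotlightExperiment(masterSeed = 1, nImagesPerCategory = 15,
                              nTestPerCategory = 8, nParticipants = 10,
                              nRuns = 5, modes = c("STD", "AS"))
print(exp$summary, digits = 3)
#>   mode mean_accuracy sd_accuracy mean_z median_z median_face_index
#> 1  STD          91.5        1.36  0.738    0.726             0.344
#> 2   AS          66.5        5.72  0.662    0.514             0.249
#>   mean_blur_fraction
#> 1             0.0000
#> 2             0.0928
```

Reading the table: networks fine-tuned on standard images (STD) reach
91.5 % mean test accuracy and a mean Fisher-Z similarity of 0.74 between
their Grad-CAM maps and the simulated cohort's gaze heatmaps. Networks
fine-tuned on Anti-Spotlight images — where exactly the fixated regions
(mostly faces, 9.3 % of pixels on average) were blurred — lose some
accuracy but, more tellingly, become *less human-like* (mean z 0.66,
median 0.51) and attend faces less (median face index 0.25 vs 0.34).
`exp$similarity` holds the tidy per-(run, image, window) records behind
these summaries, `exp$faceIndexHuman` the time-resolved human face bias,
and `runTradeoffSweep(exp, ...)` sweeps manipulation ratios.

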