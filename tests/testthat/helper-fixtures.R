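# Shared fixtures, built in code and cached per test session.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- builder()
  .fixtureEnv[[name]]
}

# a tiny stimulus set: 2 categories x 3 images at 48 px
tinyStimuli <- function() {
  fixture("tinyStimuli", function()
    generateStimulusSet(stimulusSpec(nCategories = 2, nImagesPerCategory = 3,
                                     imageSize = 48, faceProbability = 1,
                                     seed = 404)))
}

# a small but trainable set: 4 categories x 10 images at 64 px
smallStimuli <- function() {
  fixture("smallStimuli", function()
    generateStimulusSet(stimulusSpec(nCategories = 4, nImagesPerCategory = 10,
                                     imageSize = 64, seed = 808),
                        idPrefix = "tr_"))
}

smallBackbone <- function() {
  fixture("smallBackbone", function() buildBackbone("small", 64, 4, seed = 99))
}

# a trained run on the small set (STD data), with cached features
smallRun <- function() {
  fixture("smallRun", function() {
    ds <- buildTrainingSet(smallStimuli(), NULL, "STD", 0, seed = 1)
    fineTune(smallBackbone(), ds, trainingConfig(seed = 11))
  })
}

# a toy run on 8 px random-pixel images (two classes), for gradient checks
toyRun8 <- function() {
  fixture("toyRun8", function() {
    set.seed(321)
    ids <- c("a1", "a2", "b1", "b2")
    images <- lapply(ids, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
    names(images) <- ids
    mf <- data.frame(image_id = ids, category = rep(c("a", "b"), each = 2),
                     animate = FALSE, has_face = FALSE, manipulated = FALSE,
                     blur_fraction = 0, mode = "STD",
                     stringsAsFactors = FALSE)
    ds <- new("TrainingSet", images = images, manifest = mf, mode = "STD",
              ratioPercent = 0, seed = 1L)
    bb <- buildBackbone("small", 8, 2, seed = 13)
    fineTune(bb, ds, trainingConfig(maxEpochs = 2, validationPatience = 2,
                                    valFraction = 0.3, seed = 4))
  })
}

# synthetic peak-normalized density map (single Gaussian bump)
gaussianDensityMap <- function(S = 48, cx = 30, cy = 18, sd = 6,
                               imageId = "dm") {
  xs <- matrix(seq_len(S), S, S, byrow = TRUE)
  ys <- matrix(seq_len(S), S, S)
  v <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sd^2))
  new("FixationDensityMap", imageId = imageId, windowIndex = "all",
      windowOnsetMs = 0, windowOffsetMs = 1500, values = v / max(v),
      normalization = "peak")
}

# the end-to-end experiment at the study conditions (STD vs AS, 10 seeded
# runs each, 12 x 30 training images, 23 simulated participants, 64 px);
# computed once and shared between the directional and trade-off checks
acceptanceExperiment <- function() {
  fixture("acceptanceExperiment", function()
    runSpotlightExperiment(masterSeed = 7041L, imageSize = 64L,
                           nCategories = 12L, nImagesPerCategory = 30L,
                           nTestPerCategory = 15L, nParticipants = 23L,
                           faceBias = 0.85, modes = c("STD", "AS"),
                           nRuns = 10L))
}
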