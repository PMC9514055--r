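# S4 classes for the guided-attention pipeline.

#' @import methods
NULL

# ---------------------------------------------------------------- stimuli ----

#' Specification of a synthetic stimulus set
#'
#' Describes the category structure of a synthetic image dataset: how many
#' entry-level categories, how many exemplars each, the image resolution,
#' which fraction of categories is animate, and how likely an animate-category
#' exemplar is to contain a face patch.
#'
#' @slot nCategories number of categories (>= 2).
#' @slot nImagesPerCategory exemplars per category.
#' @slot imageSize image side length in pixels (>= 32).
#' @slot animateFraction fraction of categories flagged animate.
#' @slot faceProbability probability that an animate-category image contains
#'   a face region. Default 0.75 (roughly the observed share of face images
#'   among animate exemplars in comparable natural-image sets).
#' @slot seed integer seed; all image randomness derives from it.
#' @export
setClass("StimulusSpec",
  representation(nCategories = "integer", nImagesPerCategory = "integer",
                 imageSize = "integer", animateFraction = "numeric",
                 faceProbability = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nCategories < 2L) msg <- c(msg, "nCategories must be >= 2")
    if (object@imageSize < 32L)
      msg <- c(msg, "imageSize must be >= 32 (too small to place object and face)")
    if (object@faceProbability < 0 || object@faceProbability > 1)
      msg <- c(msg, "faceProbability must be in [0, 1]")
    if (object@animateFraction < 0 || object@animateFraction > 1)
      msg <- c(msg, "animateFraction must be in [0, 1]")
    if (object@nImagesPerCategory < 1L) msg <- c(msg, "nImagesPerCategory must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Create a StimulusSpec
#'
#' @param nCategories,nImagesPerCategory,imageSize,animateFraction,faceProbability,seed
#'   see the class documentation.
#' @return A [StimulusSpec-class] object.
#' @export
stimulusSpec <- function(nCategories = 12L, nImagesPerCategory = 30L,
                         imageSize = 227L, animateFraction = 0.5,
                         faceProbability = 0.75, seed = 1L) {
  new("StimulusSpec", nCategories = as.integer(nCategories),
      nImagesPerCategory = as.integer(nImagesPerCategory),
      imageSize = as.integer(imageSize),
      animateFraction = as.numeric(animateFraction),
      faceProbability = as.numeric(faceProbability), seed = as.integer(seed))
}

#' A synthetic stimulus image with region-of-interest masks
#'
#' Pixels are an H x W x 3 array in [0, 1] (rows index y, columns x).
#' `objectRoi` marks the drawn object (including any face patch) and
#' `faceRoi` the face patch; `faceRoi` is always a subset of `objectRoi`.
#'
#' @slot imageId unique identifier.
#' @slot category category label.
#' @slot animate whether the category is animate.
#' @slot pixels H x W x 3 numeric array in [0, 1].
#' @slot objectRoi H x W logical matrix, non-empty.
#' @slot faceRoi H x W logical matrix (all-FALSE when no face).
#' @slot hasFace TRUE iff `faceRoi` is non-empty.
#' @export
setClass("StimulusImage",
  representation(imageId = "character", category = "character",
                 animate = "logical", pixels = "array",
                 objectRoi = "matrix", faceRoi = "matrix", hasFace = "logical"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3L] != 3L) msg <- c(msg, "pixels must be H x W x 3")
    if (min(object@pixels) < 0 || max(object@pixels) > 1)
      msg <- c(msg, "pixels must lie in [0, 1]")
    if (!any(object@objectRoi)) msg <- c(msg, "objectRoi must be non-empty")
    if (any(object@faceRoi & !object@objectRoi))
      msg <- c(msg, "faceRoi must be a subset of objectRoi")
    if (object@hasFace != any(object@faceRoi))
      msg <- c(msg, "hasFace must equal any(faceRoi)")
    if (length(msg)) msg else TRUE
  })

#' A set of stimulus images with a tidy manifest
#'
#' @slot images named list of [StimulusImage-class] objects (by imageId).
#' @slot manifest data.frame with columns image_id, category, animate, has_face.
#' @slot spec the generating [StimulusSpec-class].
#' @export
setClass("StimulusSet",
  representation(images = "list", manifest = "data.frame", spec = "StimulusSpec"))

# ------------------------------------------------------------------- gaze ----

#' Parameters of the simulated gaze model
#'
#' A two-state renewal scanpath: gaze starts at screen center (the fixation
#' cross position), remains there for a saccade-programming latency, then
#' lands on the face-region centroid (with probability `faceBias`, when a
#' face is present) or the object centroid, and refixates at `refixationRate`
#' thereafter. Coordinate noise is expressed in screen pixels.
#'
#' @slot samplingRate samples per second (default 1000 Hz).
#' @slot presentationMs stimulus duration (default 1500 ms).
#' @slot centralOnsetMs mean initial central-fixation duration before the
#'   first saccade (default 175 ms, i.e. within the 150--200 ms range that
#'   saccade programming after the feedforward sweep is thought to take).
#' @slot centralOnsetSdMs trial-to-trial jitter of that latency (default 15 ms).
#' @slot saccadeNoisePx SD of the landing error in screen px.
#' @slot faceBias probability that a saccade targets the face rather than
#'   the object centroid, when a face is present (default 0.85).
#' @slot fixationJitterPx within-fixation tremor SD in screen px.
#' @slot refixationRate new saccades per second after the first landing.
#' @slot seed integer seed (NA uses the current RNG stream).
#' @export
setClass("GazeModelParams",
  representation(samplingRate = "numeric", presentationMs = "numeric",
                 centralOnsetMs = "numeric", centralOnsetSdMs = "numeric",
                 saccadeNoisePx = "numeric", faceBias = "numeric",
                 fixationJitterPx = "numeric", refixationRate = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
    if (object@presentationMs <= 0) msg <- c(msg, "presentationMs must be > 0")
    if (object@faceBias < 0 || object@faceBias > 1)
      msg <- c(msg, "faceBias must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Create gaze-model parameters
#' @param samplingRate,presentationMs,centralOnsetMs,centralOnsetSdMs,saccadeNoisePx,faceBias,fixationJitterPx,refixationRate,seed
#'   see the class documentation.
#' @return A [GazeModelParams-class] object.
#' @export
gazeModelParams <- function(samplingRate = 1000, presentationMs = 1500,
                            centralOnsetMs = 175, centralOnsetSdMs = 15,
                            saccadeNoisePx = 20, faceBias = 0.85,
                            fixationJitterPx = 3, refixationRate = 2,
                            seed = NA_integer_) {
  new("GazeModelParams", samplingRate = samplingRate,
      presentationMs = presentationMs, centralOnsetMs = centralOnsetMs,
      centralOnsetSdMs = centralOnsetSdMs, saccadeNoisePx = saccadeNoisePx,
      faceBias = faceBias, fixationJitterPx = fixationJitterPx,
      refixationRate = refixationRate, seed = as.integer(seed))
}

#' Display geometry of the eye-tracking setup
#'
#' The stimulus is shown magnified on screen (display pixels per image pixel
#' = `scaleFactor`) while analyses run at native image resolution.
#'
#' @slot screenW,screenH screen size in px (defaults 1920 x 1080).
#' @slot imageSize native image side length in px.
#' @slot imageDisplaySize displayed side length in screen px.
#' @slot imageOrigin (x, y) of the displayed image's top-left corner,
#'   0-based screen coordinates.
#' @slot scaleFactor display px per image px.
#' @export
setClass("DisplayGeometry",
  representation(screenW = "numeric", screenH = "numeric",
                 imageSize = "integer", imageDisplaySize = "numeric",
                 imageOrigin = "numeric", scaleFactor = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@imageOrigin) != 2L) msg <- c(msg, "imageOrigin must be (x, y)")
    if (abs(object@scaleFactor - object@imageDisplaySize / object@imageSize) > 1e-9)
      msg <- c(msg, "scaleFactor must equal imageDisplaySize / imageSize")
    ox <- object@imageOrigin[1L]; oy <- object@imageOrigin[2L]
    if (ox < 0 || oy < 0 || ox + object@imageDisplaySize > object@screenW ||
        oy + object@imageDisplaySize > object@screenH)
      msg <- c(msg, "displayed image must lie fully inside the screen")
    if (length(msg)) msg else TRUE
  })

#' Create a display geometry
#'
#' By default the image is scaled by factor two and centered on a
#' 1920 x 1080 screen (so a 227 px image is displayed at 454 px).
#'
#' @param imageSize native image side length in px.
#' @param screenW,screenH screen size in px.
#' @param scaleFactor display px per image px (default 2).
#' @param imageOrigin optional (x, y) top-left corner; default centers the image.
#' @return A [DisplayGeometry-class] object.
#' @export
displayGeometry <- function(imageSize = 227L, screenW = 1920, screenH = 1080,
                            scaleFactor = 2, imageOrigin = NULL) {
  disp <- imageSize * scaleFactor
  if (is.null(imageOrigin)) {
    imageOrigin <- c(floor((screenW - disp) / 2), floor((screenH - disp) / 2))
  }
  new("DisplayGeometry", screenW = screenW, screenH = screenH,
      imageSize = as.integer(imageSize), imageDisplaySize = disp,
      imageOrigin = as.numeric(imageOrigin), scaleFactor = scaleFactor)
}

# --------------------------------------------------------------- heatmaps ----

#' Configuration of fixation-density heatmaps
#'
#' @slot windowMs time-window length (default 50 ms).
#' @slot horizonMs analyzed horizon (default 1000 ms; must be a multiple of
#'   `windowMs`), giving 20 discrete windows at the defaults.
#' @slot smoothingSdPx Gaussian smoothing SD at image resolution
#'   (default 20 px at the native 227 px scale).
#' @slot cumulative if TRUE windows accumulate from stimulus onset instead
#'   of being disjoint.
#' @slot fullPresentation if TRUE all in-image samples over the whole
#'   presentation are pooled into a single map (used for the maps that drive
#'   the image manipulation).
#' @export
setClass("HeatmapConfig",
  representation(windowMs = "numeric", horizonMs = "numeric",
                 smoothingSdPx = "numeric", cumulative = "logical",
                 fullPresentation = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@windowMs <= 0) msg <- c(msg, "windowMs must be > 0")
    if (object@horizonMs %% object@windowMs != 0)
      msg <- c(msg, "horizonMs must be a multiple of windowMs")
    if (object@smoothingSdPx <= 0) msg <- c(msg, "smoothingSdPx must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Create a heatmap configuration
#' @param windowMs,horizonMs,smoothingSdPx,cumulative,fullPresentation see
#'   the class documentation.
#' @return A [HeatmapConfig-class] object.
#' @export
heatmapConfig <- function(windowMs = 50, horizonMs = 1000, smoothingSdPx = 20,
                          cumulative = FALSE, fullPresentation = FALSE) {
  new("HeatmapConfig", windowMs = windowMs, horizonMs = horizonMs,
      smoothingSdPx = smoothingSdPx, cumulative = cumulative,
      fullPresentation = fullPresentation)
}

#' A smoothed, normalized fixation-density map
#'
#' @slot imageId image the map belongs to.
#' @slot windowIndex "all" or the 0-based window index as character.
#' @slot windowOnsetMs,windowOffsetMs window bounds in presentation time.
#' @slot values H x W nonnegative matrix at image resolution.
#' @slot normalization "peak" (max = 1) or "none" (e.g. an all-zero map).
#' @export
setClass("FixationDensityMap",
  representation(imageId = "character", windowIndex = "character",
                 windowOnsetMs = "numeric", windowOffsetMs = "numeric",
                 values = "matrix", normalization = "character"),
  validity = function(object) {
    msg <- character()
    if (min(object@values) < 0) msg <- c(msg, "values must be nonnegative")
    if (object@normalization == "peak" && max(object@values) > 0 &&
        abs(max(object@values) - 1) > 1e-9)
      msg <- c(msg, "peak-normalized map must have max 1")
    if (!object@normalization %in% c("peak", "none"))
      msg <- c(msg, "normalization must be 'peak' or 'none'")
    if (length(msg)) msg else TRUE
  })

# -------------------------------------------------------------- spotlight ----

#' Specification of a spotlight manipulation
#'
#' Human-Spotlight (HS) keeps image parts with fixation density at or above
#' the threshold sharp and blurs the rest; Anti-Spotlight (AS) is the exact
#' complement; STD leaves images untouched. The default threshold of 1/3 on
#' the peak-normalized density realizes the "first tertile" rule on the
#' value range. Window/SD defaults are stated at the native 227 px scale;
#' see [scaledManipulationSpec()] for other resolutions.
#'
#' @slot mode "STD", "HS" or "AS".
#' @slot threshold density threshold in (0, 1).
#' @slot blurWindow,blurSd Gaussian blur kernel window and SD in px
#'   (defaults 30 and 7).
#' @slot taperWindow,taperSd edge-taper Gaussian applied to the binary keep
#'   mask (defaults 35 and 9).
#' @slot taperTarget "mask" (the soft alpha-compositing reading of the edge
#'   taper; the only implemented target).
#' @export
setClass("ManipulationSpec",
  representation(mode = "character", threshold = "numeric",
                 blurWindow = "numeric", blurSd = "numeric",
                 taperWindow = "numeric", taperSd = "numeric",
                 taperTarget = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("STD", "HS", "AS"))
      msg <- c(msg, "mode must be STD, HS or AS")
    if (object@threshold <= 0 || object@threshold >= 1)
      msg <- c(msg, "threshold must be in (0, 1)")
    if (object@blurWindow <= 0 || object@blurSd <= 0 ||
        object@taperWindow <= 0 || object@taperSd <= 0)
      msg <- c(msg, "blur/taper windows and SDs must be positive")
    if (length(msg)) msg else TRUE
  })

#' Create a manipulation specification
#' @param mode,threshold,blurWindow,blurSd,taperWindow,taperSd see the class
#'   documentation.
#' @return A [ManipulationSpec-class] object.
#' @export
manipulationSpec <- function(mode = c("HS", "AS", "STD"), threshold = 1 / 3,
                             blurWindow = 30, blurSd = 7,
                             taperWindow = 35, taperSd = 9) {
  mode <- match.arg(mode)
  new("ManipulationSpec", mode = mode, threshold = threshold,
      blurWindow = blurWindow, blurSd = blurSd, taperWindow = taperWindow,
      taperSd = taperSd, taperTarget = "mask")
}

#' Scale a manipulation specification to another image resolution
#'
#' Blur and taper geometry is defined at the native 227 px scale; this
#' helper rescales windows and SDs proportionally so the manipulation covers
#' the same image fraction at other resolutions.
#'
#' @param mode manipulation mode.
#' @param imageSize target image side length in px.
#' @param threshold density threshold (unchanged by scaling).
#' @return A [ManipulationSpec-class] object.
#' @export
scaledManipulationSpec <- function(mode = c("HS", "AS", "STD"), imageSize,
                                   threshold = 1 / 3) {
  s <- imageSize / 227
  manipulationSpec(mode = match.arg(mode), threshold = threshold,
                   blurWindow = max(3, round(30 * s)), blurSd = max(0.75, 7 * s),
                   taperWindow = max(3, round(35 * s)), taperSd = max(1, 9 * s))
}

#' A keep/blur spotlight mask derived from a fixation-density map
#'
#' @slot imageId source image.
#' @slot mode "STD", "HS" or "AS".
#' @slot keep H x W matrix in [0, 1]; 1 = fully sharp.
#' @slot binaryKeep H x W logical pre-taper mask.
#' @slot blurFraction proportion of pixels with binaryKeep FALSE.
#' @export
setClass("SpotlightMask",
  representation(imageId = "character", mode = "character", keep = "matrix",
                 binaryKeep = "matrix", blurFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (min(object@keep) < -1e-12 || max(object@keep) > 1 + 1e-12)
      msg <- c(msg, "keep must lie in [0, 1]")
    if (object@blurFraction < 0 || object@blurFraction > 1)
      msg <- c(msg, "blurFraction must be in [0, 1]")
    if (length(msg)) msg else TRUE
  })

# ----------------------------------------------------------------- models ----

#' A small convolutional backbone with an identifiable last conv layer
#'
#' Layers are stored as plain parameter lists; the forward pass uses im2col
#' matrix products. Architectures: "small" (3 conv + 2 fully connected) for
#' desk-scale experiments and "alexnet-like" (5 conv + 3 fully connected).
#' The layer before the classification head is the feature layer; the last
#' convolutional layer is what Grad-CAM attributes to.
#'
#' @slot architecture preset name.
#' @slot inputSize input side length in px (multiple of 8).
#' @slot nClasses number of output classes.
#' @slot seed init seed.
#' @slot layers list of layer parameter lists.
#' @slot featureDim dimension of the penultimate (feature) layer.
#' @slot lastConvShape c(H, W, C) of the last conv layer's output.
#' @slot globalPool whether the conv stage ends in global average pooling
#'   (TRUE for "small") rather than flattening.
#' @export
setClass("CNNBackbone",
  representation(architecture = "character", inputSize = "integer",
                 nClasses = "integer", seed = "integer", layers = "list",
                 featureDim = "integer", lastConvShape = "integer",
                 globalPool = "logical"))

#' Fine-tuning configuration
#'
#' Transfer-learning recipe: all backbone layers frozen, the classification
#' head replaced and trained with stochastic gradient descent with momentum
#' (SGDM), mini-batch 42, base learn rate 1e-4 with a factor-20 multiplier
#' in the replaced head, at most 30 epochs with a validation patience of 5,
#' and no data augmentation.
#'
#' @slot momentum SGDM momentum (0.9).
#' @slot batchSize mini-batch size (42).
#' @slot learnRate base learning rate (1e-4).
#' @slot headLrFactor learning-rate multiplier in the replaced head (20).
#' @slot maxEpochs maximum epochs (30).
#' @slot validationPatience epochs without validation-loss improvement
#'   before early stopping (5).
#' @slot augmentation must be "none".
#' @slot valFraction validation fraction of the training set (0.2),
#'   stratified by category.
#' @slot seed controls head init and the train/validation shuffle.
#' @export
setClass("TrainingConfig",
  representation(momentum = "numeric", batchSize = "integer",
                 learnRate = "numeric", headLrFactor = "numeric",
                 maxEpochs = "integer", validationPatience = "integer",
                 augmentation = "character", valFraction = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@validationPatience > max(object@maxEpochs, 1L))
      msg <- c(msg, "validationPatience must not exceed maxEpochs")
    if (object@augmentation != "none")
      msg <- c(msg, "augmentation must be 'none'")
    if (object@valFraction <= 0 || object@valFraction >= 1)
      msg <- c(msg, "valFraction must be in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Create a training configuration
#' @param momentum,batchSize,learnRate,headLrFactor,maxEpochs,validationPatience,valFraction,seed
#'   see the class documentation.
#' @return A [TrainingConfig-class] object.
#' @export
trainingConfig <- function(momentum = 0.9, batchSize = 42L, learnRate = 1e-4,
                           headLrFactor = 20, maxEpochs = 30L,
                           validationPatience = 5L, valFraction = 0.2,
                           seed = 1L) {
  new("TrainingConfig", momentum = momentum, batchSize = as.integer(batchSize),
      learnRate = learnRate, headLrFactor = headLrFactor,
      maxEpochs = as.integer(maxEpochs),
      validationPatience = as.integer(validationPatience),
      augmentation = "none", valFraction = valFraction, seed = as.integer(seed))
}

#' A fine-tuned model run
#'
#' Holds the frozen backbone, the trained head, feature standardization
#' statistics, the train/validation split manifest, per-epoch history and
#' (after [evaluateAccuracy()]) the test evaluation.
#'
#' @slot runId identifier.
#' @slot mode manipulation mode of the training data ("STD"/"HS"/"AS").
#' @slot ratioPercent manipulation ratio of the training data.
#' @slot seed run seed.
#' @slot backbone the frozen [CNNBackbone-class].
#' @slot headW,headB trained head parameters.
#' @slot featMean,featSd feature standardization fitted on the training split.
#' @slot splitManifest data.frame image_id/category/role ("train"/"val").
#' @slot history per-epoch data.frame (epoch, trainLoss, valLoss, valAcc).
#' @slot classes class labels in head output order.
#' @slot evaluation list filled by [evaluateAccuracy()]: overall accuracy
#'   (percent), per-category/per-split tables, confusion matrix, per-image
#'   correctness.
#' @export
setClass("ModelRun",
  representation(runId = "character", mode = "character",
                 ratioPercent = "numeric", seed = "integer",
                 backbone = "CNNBackbone", headW = "matrix", headB = "numeric",
                 featMean = "numeric", featSd = "numeric",
                 splitManifest = "data.frame", history = "data.frame",
                 classes = "character", evaluation = "list"))

#' A Grad-CAM saliency map
#'
#' Rectified, channel-weighted activation of the last convolutional layer
#' for the true class, bilinearly upsampled to image resolution and min-max
#' normalized to [0, 1]. Static per image (no temporal dimension).
#'
#' @slot imageId,runId identifiers.
#' @slot targetClass the true class label the map attributes to.
#' @slot values H x W matrix in [0, 1].
#' @slot sourceLayer name of the last conv layer.
#' @slot flagged TRUE when the pre-normalization map was identically zero.
#' @export
setClass("SaliencyMap",
  representation(imageId = "character", runId = "character",
                 targetClass = "character", values = "matrix",
                 sourceLayer = "character", flagged = "logical"),
  validity = function(object) {
    msg <- character()
    if (min(object@values) < 0) msg <- c(msg, "values must be nonnegative")
    mx <- max(object@values)
    if (!object@flagged && mx > 0 && abs(mx - 1) > 1e-9)
      msg <- c(msg, "non-degenerate saliency map must have max 1")
    if (length(msg)) msg else TRUE
  })

#' A ratio-mixed fine-tuning dataset
#'
#' @slot images named list of H x W x 3 pixel arrays (by image_id).
#' @slot manifest data.frame: image_id, category, animate, has_face,
#'   manipulated, mode, blur_fraction.
#' @slot mode manipulation mode.
#' @slot ratioPercent percentage of images per category replaced by their
#'   manipulated versions.
#' @slot seed selection seed.
#' @export
setClass("TrainingSet",
  representation(images = "list", manifest = "data.frame", mode = "character",
                 ratioPercent = "numeric", seed = "integer"))

# ------------------------------------------------------------------ show -----

setMethod("show", "StimulusSpec", function(object) {
  cat(sprintf("StimulusSpec: %d categories x %d images at %d px (animate %.0f%%, P(face)=%.2f, seed %d)\n",
              object@nCategories, object@nImagesPerCategory, object@imageSize,
              100 * object@animateFraction, object@faceProbability, object@seed))
})

setMethod("show", "StimulusSet", function(object) {
  m <- object@manifest
  cat(sprintf("StimulusSet: %d images, %d categories (%d animate), %d with faces, %d px\n",
              nrow(m), length(unique(m$category)),
              length(unique(m$category[m$animate])), sum(m$has_face),
              object@spec@imageSize))
})

setMethod("show", "StimulusImage", function(object) {
  cat(sprintf("StimulusImage %s [%s%s]: %d x %d px, object ROI %d px%s\n",
              object@imageId, object@category,
              if (object@animate) ", animate" else "",
              nrow(object@objectRoi), ncol(object@objectRoi),
              sum(object@objectRoi),
              if (object@hasFace) sprintf(", face ROI %d px", sum(object@faceRoi)) else ""))
})

setMethod("show", "FixationDensityMap", function(object) {
  cat(sprintf("FixationDensityMap %s window %s [%g, %g) ms: %d x %d, normalization %s\n",
              object@imageId, object@windowIndex, object@windowOnsetMs,
              object@windowOffsetMs, nrow(object@values), ncol(object@values),
              object@normalization))
})

setMethod("show", "SpotlightMask", function(object) {
  cat(sprintf("SpotlightMask %s (%s): %d x %d, blur fraction %.3f\n",
              object@imageId, object@mode, nrow(object@keep), ncol(object@keep),
              object@blurFraction))
})

setMethod("show", "CNNBackbone", function(object) {
  nconv <- sum(vapply(object@layers, function(l) l$type == "conv", logical(1)))
  nfc <- sum(vapply(object@layers, function(l) l$type == "fc", logical(1)))
  cat(sprintf("CNNBackbone '%s': %d conv + %d frozen fc (+ replaceable head), input %d px, %d classes, last conv %s\n",
              object@architecture, nconv, nfc, object@inputSize, object@nClasses,
              paste(object@lastConvShape, collapse = "x")))
})

setMethod("show", "ModelRun", function(object) {
  acc <- if (length(object@evaluation)) sprintf(", test accuracy %.2f%%", object@evaluation$overall) else ""
  cat(sprintf("ModelRun %s: mode %s ratio %g%%, seed %d, %d epochs trained%s\n",
              object@runId, object@mode, object@ratioPercent, object@seed,
              nrow(object@history), acc))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap %s (run %s, class %s): %d x %d from %s%s\n",
              object@imageId, object@runId, object@targetClass,
              nrow(object@values), ncol(object@values), object@sourceLayer,
              if (object@flagged) " [degenerate: all zero]" else ""))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d images, mode %s at ratio %g%% (%d manipulated)\n",
              nrow(object@manifest), object@mode, object@ratioPercent,
              sum(object@manifest$manipulated)))
})

# ------------------------------------------------------------- accessors -----

#' Accessor generics for pipeline objects
#'
#' `imageId()` returns the image identifier, `mapValues()` the numeric
#' matrix of a density, saliency or keep map, `blurFraction()` the blurred
#' pixel proportion of a mask, and `runAccuracy()` the overall test accuracy
#' (percent) of an evaluated run.
#'
#' @param object a package S4 object.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("blurFraction", function(object) standardGeneric("blurFraction"))
#' @rdname accessors
#' @export
setGeneric("runAccuracy", function(object) standardGeneric("runAccuracy"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))

#' @rdname accessors
setMethod("imageId", "StimulusImage", function(object) object@imageId)
#' @rdname accessors
setMethod("imageId", "FixationDensityMap", function(object) object@imageId)
#' @rdname accessors
setMethod("imageId", "SaliencyMap", function(object) object@imageId)
#' @rdname accessors
setMethod("imageId", "SpotlightMask", function(object) object@imageId)

#' @rdname accessors
setMethod("mapValues", "FixationDensityMap", function(object) object@values)
#' @rdname accessors
setMethod("mapValues", "SaliencyMap", function(object) object@values)
#' @rdname accessors
setMethod("mapValues", "SpotlightMask", function(object) object@keep)

#' @rdname accessors
setMethod("blurFraction", "SpotlightMask", function(object) object@blurFraction)

#' @rdname accessors
setMethod("runAccuracy", "ModelRun", function(object) {
  if (!length(object@evaluation)) stop("run has not been evaluated yet; call evaluateAccuracy()")
  object@evaluation$overall
})

#' @rdname accessors
setMethod("manifest", "StimulusSet", function(object) object@manifest)
#' @rdname accessors
setMethod("manifest", "TrainingSet", function(object) object@manifest)
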