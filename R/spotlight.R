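# Spotlight manipulation: tertile keep/blur masks from fixation-density
# maps, Gaussian blur with an edge taper, and ratio-mixed training sets.

#' Derive a keep/blur spotlight mask from a fixation-density map
#'
#' Image parts with peak-normalized fixation density below the threshold
#' (default 1/3 of the value range -- the "first tertile") are blurred under
#' HS and kept under AS; the two binary masks are exact complements. The
#' soft `keep` matte is the binary mask smoothed by the edge-taper Gaussian
#' and clipped to [0, 1] (taper applied to the mask, i.e. soft alpha
#' compositing, not to the image seam).
#'
#' @param density a peak-normalized [FixationDensityMap-class].
#' @param spec a [ManipulationSpec-class] with mode "HS" or "AS" ("STD"
#'   yields an all-keep mask).
#' @return A [SpotlightMask-class].
#' @export
tertileMask <- function(density, spec) {
  v <- density@values
  if (density@normalization == "peak" && max(v) > 0 && abs(max(v) - 1) > 1e-6)
    stop("density map must be peak-normalized")
  binary <- switch(spec@mode,
    STD = matrix(TRUE, nrow(v), ncol(v)),
    HS = v >= spec@threshold,
    AS = v < spec@threshold)
  if (spec@mode == "HS" && !any(binary))
    warning(sprintf("all-zero density for image %s: HS keeps nothing (degenerate trial)",
                    density@imageId))
  keep <- if (spec@mode == "STD") {
    matrix(1, nrow(v), ncol(v))
  } else {
    .clamp(gaussianSmooth(binary + 0, spec@taperSd, spec@taperWindow), 0, 1)
  }
  new("SpotlightMask", imageId = density@imageId, mode = spec@mode,
      keep = keep, binaryKeep = binary, blurFraction = mean(!binary))
}

#' Apply a spotlight mask to an image
#'
#' The image is blurred per channel with the blur Gaussian and composited
#' with the original: `out = keep * image + (1 - keep) * blurred`. STD mode
#' returns the input bit-exactly.
#'
#' @param image a [StimulusImage-class] or an H x W x 3 array.
#' @param mask a [SpotlightMask-class] of the same size.
#' @param spec the [ManipulationSpec-class] providing the blur kernel.
#' @return Same type as `image`, with manipulated pixels.
#' @export
applySpotlight <- function(image, mask, spec) {
  px <- if (is(image, "StimulusImage")) image@pixels else image
  if (!identical(dim(px)[1:2], dim(mask@keep)))
    stop("mask and image sizes differ")
  if (spec@mode == "STD") return(image)
  blurred <- gaussianSmooth(px, spec@blurSd, spec@blurWindow)
  keep <- array(rep(mask@keep, 3L), dim(px))
  out <- keep * px + (1 - keep) * blurred
  out <- .clamp(out, 0, 1)
  if (is(image, "StimulusImage")) {
    initialize(image, pixels = out)
  } else {
    out
  }
}

#' Manipulate every image of a stimulus set once (cached versions)
#'
#' Derives the spotlight mask from each image's full-presentation density
#' map and applies it. Training-set assembly ([buildTrainingSet()]) then
#' only selects between these cached manipulated versions and the originals,
#' so manipulated pixels are identical across runs and ratios.
#'
#' @param stimuli a [StimulusSet-class].
#' @param densityMaps named list (by image id) of [FixationDensityMap-class]
#'   objects or of lists containing an "all" entry.
#' @param spec a [ManipulationSpec-class].
#' @return Named list (by image id) of `list(pixels, blurFraction, mask)`.
#' @export
manipulateStimulusSet <- function(stimuli, densityMaps, spec) {
  out <- vector("list", length(stimuli@images))
  names(out) <- names(stimuli@images)
  for (id in names(stimuli@images)) {
    dm <- densityMaps[[id]]
    if (is.list(dm) && !is(dm, "FixationDensityMap")) dm <- dm[["all"]]
    if (is.null(dm)) stop(sprintf("missing density map for image %s", id))
    mask <- tertileMask(dm, spec)
    manip <- applySpotlight(stimuli@images[[id]], mask, spec)
    out[[id]] <- list(pixels = manip@pixels, blurFraction = mask@blurFraction,
                      mask = mask)
  }
  out
}

#' Assemble a ratio-mixed fine-tuning dataset
#'
#' Within each category, `round(ratioPercent/100 * n)` images (selected by a
#' seeded draw) are replaced by their manipulated versions; the rest remain
#' standard. Ratio 0 is the all-standard dataset, ratio 100 the fully
#' manipulated one.
#'
#' @param stimuli a [StimulusSet-class].
#' @param manipulated cached versions from [manipulateStimulusSet()]
#'   (may be NULL for mode "STD" or ratio 0).
#' @param mode manipulation mode label ("STD", "HS", "AS").
#' @param ratioPercent percentage in \{0, 10, ..., 100\}.
#' @param seed selection seed.
#' @return A [TrainingSet-class] whose manifest records per-image
#'   provenance.
#' @export
buildTrainingSet <- function(stimuli, manipulated = NULL,
                             mode = c("STD", "HS", "AS"), ratioPercent = 100,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (!ratioPercent %in% seq(0, 100, 10))
    stop("ratioPercent must be one of 0, 10, ..., 100")
  mf <- stimuli@manifest
  mf$manipulated <- FALSE
  if (mode != "STD" && ratioPercent > 0) {
    withSeed(deriveSeed(seed, "trainingSetDraw"), {
      for (cat in unique(mf$category)) {
        ids <- mf$image_id[mf$category == cat]
        nSel <- round(ratioPercent / 100 * length(ids))
        sel <- sample(ids, nSel)
        mf$manipulated[mf$image_id %in% sel] <- TRUE
      }
    })
  }
  images <- vector("list", nrow(mf))
  names(images) <- mf$image_id
  mf$blur_fraction <- 0
  for (i in seq_len(nrow(mf))) {
    id <- mf$image_id[i]
    if (mf$manipulated[i]) {
      mv <- manipulated[[id]]
      if (is.null(mv)) stop(sprintf("missing manipulated version for image %s", id))
      images[[id]] <- mv$pixels
      mf$blur_fraction[i] <- mv$blurFraction
    } else {
      images[[id]] <- stimuli@images[[id]]@pixels
    }
  }
  mf$mode <- ifelse(mf$manipulated, mode, "STD")
  new("TrainingSet", images = images, manifest = mf, mode = mode,
      ratioPercent = as.numeric(ratioPercent), seed = as.integer(seed))
}
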