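# Synthetic stimulus generation: category-discriminative images with object
# and face regions of interest.

# canonical entry-level category names used at the default 12-category layout
.animateNames <- c("human", "dog", "cat", "bird", "fish", "snake")
.inanimateNames <- c("car", "train", "house", "bed", "flower", "ball")

.categoryTable <- function(spec) {
  nA <- round(spec@animateFraction * spec@nCategories)
  nI <- spec@nCategories - nA
  nameFor <- function(pool, fallback, n) {
    if (n <= length(pool)) pool[seq_len(n)] else sprintf("%s%02d", fallback, seq_len(n))
  }
  cats <- data.frame(
    category = c(nameFor(.animateNames, "animate", nA),
                 nameFor(.inanimateNames, "inanimate", nI)),
    animate = rep(c(TRUE, FALSE), c(nA, nI)),
    stringsAsFactors = FALSE)
  # class signatures: inanimate categories get distinct saturated hues (color
  # alone identifies them, as for cars or flowers); animate categories share a
  # narrow band of overlapping warm hues (animals are brown-gray-ish), so the
  # face texture below is a primary cue for telling them apart
  k <- nrow(cats)
  cats$hue <- NA_real_
  cats$hue[cats$animate] <- seq(0.00, 0.30, length.out = max(sum(cats$animate), 1L))[seq_len(sum(cats$animate))]
  cats$hue[!cats$animate] <- seq(0.38, 0.95, length.out = max(sum(!cats$animate), 1L))[seq_len(sum(!cats$animate))]
  cats$sat <- ifelse(cats$animate, 0.6, 0.85)
  cats$shape <- c("ellipse", "rectangle", "triangle", "diamond")[(seq_len(k) - 1) %% 4 + 1]
  # animate categories additionally get a face-texture orientation: a shared
  # texture family (stripes + eye dots) whose orientation is only partially
  # class-specific
  cats$faceTheta <- NA_real_
  cats$faceFreq <- NA_real_
  if (nA > 0) {
    cats$faceTheta[cats$animate] <- pi * (seq_len(nA) - 1) / nA
    # spatial frequency of the stripe texture also varies by category
    cats$faceFreq[cats$animate] <- seq(0.18, 0.40, length.out = nA)
  }
  cats
}

.hueToRgb <- function(h, s = 0.85, v = 0.8) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

# draw one exemplar; all randomness comes from the caller's RNG state
.drawStimulus <- function(cat_row, image_id, S, face_probability) {
  xs <- matrix(seq_len(S), S, S, byrow = TRUE)  # column index (x)
  ys <- matrix(seq_len(S), S, S)                # row index (y)
  # per-exemplar appearance jitter keeps color informative but not
  # sufficient on its own, so texture cues (including the face patch)
  # carry class information too
  col <- .hueToRgb((cat_row$hue + stats::rnorm(1, 0, 0.02)) %% 1,
                   s = .clamp(stats::rnorm(1, cat_row$sat, 0.06), 0.2, 1),
                   v = .clamp(stats::rnorm(1, 0.75, 0.1), 0.4, 1))

  # background: weak category-correlated tint over gray, plus white noise
  bgNoise <- matrix(stats::rnorm(S * S, 0, 0.02), S, S)
  pixels <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    pixels[, , ch] <- 0.45 + 0.05 * (col[ch] - 0.5) + bgNoise
  }

  # body placement
  cx <- stats::runif(1, 0.38, 0.62) * S
  cy <- stats::runif(1, 0.38, 0.62) * S
  a <- stats::runif(1, 0.17, 0.24) * S  # half-width (x)
  b <- stats::runif(1, 0.17, 0.24) * S  # half-height (y)
  body <- switch(cat_row$shape,
    ellipse = ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1,
    rectangle = abs(xs - cx) <= a & abs(ys - cy) <= b,
    triangle = ys >= cy - b & ys <= cy + b &
      abs(xs - cx) <= a * (ys - (cy - b)) / (2 * b),
    diamond = abs(xs - cx) / a + abs(ys - cy) / b <= 1)

  shade <- 1 + 0.15 * (ys - cy) / max(b, 1)  # mild vertical shading
  bodyNoise <- matrix(stats::rnorm(S * S, 0, 0.03), S, S)
  for (ch in 1:3) {
    plane <- pixels[, , ch]
    plane[body] <- (col[ch] * shade + bodyNoise)[body]
    pixels[, , ch] <- plane
  }

  # face patch: shared high-frequency texture family whose stripe orientation
  # is category-specific (partially discriminative by design)
  face <- matrix(FALSE, S, S)
  if (cat_row$animate && stats::runif(1) < face_probability) {
    rf <- max(4, round(0.15 * S))
    fcx <- cx + stats::runif(1, -0.2, 0.2) * a
    fcy <- cy - 0.3 * b
    face <- (xs - fcx)^2 + (ys - fcy)^2 <= rf^2
    theta <- cat_row$faceTheta + stats::rnorm(1, 0, 0.08)
    wavelength <- max(2.5, 1 / cat_row$faceFreq * S / 64)
    stripes <- sin(2 * pi * ((xs - fcx) * cos(theta) + (ys - fcy) * sin(theta)) / wavelength)
    eyeOff <- rf * 0.45
    eyes <- ((xs - (fcx - eyeOff))^2 + (ys - (fcy - eyeOff * 0.6))^2 <= (rf * 0.22)^2) |
            ((xs - (fcx + eyeOff))^2 + (ys - (fcy - eyeOff * 0.6))^2 <= (rf * 0.22)^2)
    faceTex <- 0.68 + 0.38 * stripes
    faceTex[eyes] <- 0.05
    for (ch in 1:3) {
      plane <- pixels[, , ch]
      plane[face] <- faceTex[face]
      pixels[, , ch] <- plane
    }
  }

  objectRoi <- body | face
  pixels <- .clamp(pixels, 0, 1)
  new("StimulusImage", imageId = image_id, category = cat_row$category,
      animate = cat_row$animate, pixels = pixels, objectRoi = objectRoi,
      faceRoi = face, hasFace = any(face))
}

#' Generate a synthetic stimulus set
#'
#' Produces category-discriminative synthetic images over a weakly
#' category-tinted noisy background. Inanimate categories carry distinct
#' saturated body hues (color alone identifies them); animate categories
#' share a narrow band of overlapping warm hues, and their exemplars carry,
#' with probability `faceProbability`, a face patch from a texture family
#' shared across animate categories (stripes with category-specific
#' orientation and spatial frequency, plus eye dots). The face texture is
#' thus partially class-discriminative -- the configuration under which
#' blurring fixated face regions (Anti-Spotlight) degrades human-likeness
#' more than accuracy. Object and face ROI masks exactly delimit the drawn
#' regions, and the face ROI is always inside the object ROI. Fully
#' deterministic for a fixed seed.
#'
#' @param spec a [StimulusSpec-class].
#' @param idPrefix prefix for image identifiers (default ""), useful to keep
#'   train and test sets disjoint.
#' @return A [StimulusSet-class].
#' @examples
#' set <- generateStimulusSet(stimulusSpec(nCategories = 2,
#'   nImagesPerCategory = 2, imageSize = 48, seed = 7))
#' manifest(set)
#' @export
generateStimulusSet <- function(spec, idPrefix = "") {
  validObject(spec)
  cats <- .categoryTable(spec)
  S <- spec@imageSize
  withSeed(deriveSeed(spec@seed, paste0("images", idPrefix)), {
    images <- list()
    rows <- vector("list", spec@nCategories * spec@nImagesPerCategory)
    n <- 0L
    for (ci in seq_len(nrow(cats))) {
      for (i in seq_len(spec@nImagesPerCategory)) {
        id <- sprintf("%s%s_%03d", idPrefix, cats$category[ci], i)
        img <- .drawStimulus(cats[ci, ], id, S, spec@faceProbability)
        images[[id]] <- img
        n <- n + 1L
        rows[[n]] <- data.frame(image_id = id, category = img@category,
                                animate = img@animate, has_face = img@hasFace,
                                stringsAsFactors = FALSE)
      }
    }
    manifest <- do.call(rbind, rows)
    new("StimulusSet", images = images, manifest = manifest, spec = spec)
  })
}

#' Centroid of a binary region of interest
#'
#' @param roi logical matrix.
#' @return c(x, y) in 0-based image pixel coordinates, or NULL for an empty
#'   ROI.
#' @export
roiCentroid <- function(roi) {
  if (!any(roi)) return(NULL)
  idx <- which(roi, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}
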