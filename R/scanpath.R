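# Simulated gaze: a two-state (center -> object/face) renewal scanpath model.
#
# The generator's obligations are the statistical structure the analysis
# assumes: 1000 Hz sampling, central-fixation onset, a ~150-200 ms saccade
# latency, a configurable bias of the first object saccade toward the face
# region, and participant-level variability. Pupil size, blinks, smooth
# pursuit and microsaccades are out of scope.

#' A simulated gaze cohort
#'
#' @slot samples data.frame with columns participant_id, image_id, t_ms,
#'   x_px, y_px (0-based screen coordinates, origin top-left, x = column).
#' @slot participants per-participant parameter manifest (including the
#'   derived seeds), one row per participant.
#' @slot params the base [GazeModelParams-class].
#' @slot geometry the [DisplayGeometry-class] used.
#' @slot masterSeed seed the cohort was derived from.
#' @export
setClass("GazeCohort",
  representation(samples = "data.frame", participants = "data.frame",
                 params = "GazeModelParams", geometry = "DisplayGeometry",
                 masterSeed = "integer"))

setMethod("show", "GazeCohort", function(object) {
  cat(sprintf("GazeCohort: %d participants, %d samples over %d images (seed %d)\n",
              nrow(object@participants), nrow(object@samples),
              length(unique(object@samples$image_id)), object@masterSeed))
})

# map a 0-based continuous image coordinate to the screen pixel at the center
# of the corresponding displayed region
.imageToScreen <- function(cxy, geometry) {
  geometry@imageOrigin + (cxy + 0.5) * geometry@scaleFactor
}

# core single-trial simulator; consumes the current RNG stream
.simulateTrialCore <- function(image, geometry, samplingRate, presentationMs,
                               centralOnsetMs, centralOnsetSdMs, saccadeNoisePx,
                               faceBias, fixationJitterPx, refixationRate) {
  n <- round(presentationMs * samplingRate / 1000)
  dt <- 1000 / samplingRate
  t_ms <- (seq_len(n) - 1) * dt

  latency <- .clamp(stats::rnorm(1, centralOnsetMs, centralOnsetSdMs),
                    80, presentationMs)
  onsets <- latency
  if (refixationRate > 0) {
    while (onsets[length(onsets)] < presentationMs && length(onsets) < 60L) {
      onsets <- c(onsets, onsets[length(onsets)] +
                    stats::rexp(1, rate = refixationRate / 1000))
    }
    onsets <- onsets[onsets < presentationMs]
    if (!length(onsets)) onsets <- latency
  }

  faceC <- roiCentroid(image@faceRoi)
  objC <- roiCentroid(image@objectRoi)
  objIdx <- which(image@objectRoi, arr.ind = TRUE)
  k <- length(onsets)
  useFace <- if (image@hasFace) stats::runif(k) < faceBias else rep(FALSE, k)
  tx <- numeric(k); ty <- numeric(k)
  for (j in seq_len(k)) {
    ctr <- if (useFace[j]) {
      faceC
    } else if (j == 1L) {
      objC  # the first object saccade lands at the object centroid
    } else {
      # later refixations scan the object: a uniformly drawn ROI point
      p <- objIdx[sample.int(nrow(objIdx), 1L), ]
      c(x = unname(p[2L]) - 1, y = unname(p[1L]) - 1)
    }
    scr <- .imageToScreen(c(ctr[["x"]], ctr[["y"]]), geometry)
    tx[j] <- scr[1] + stats::rnorm(1, 0, saccadeNoisePx)
    ty[j] <- scr[2] + stats::rnorm(1, 0, saccadeNoisePx)
  }

  center <- c(geometry@screenW, geometry@screenH) / 2
  idx <- findInterval(t_ms, onsets)
  x <- c(center[1], tx)[idx + 1L]
  y <- c(center[2], ty)[idx + 1L]
  if (fixationJitterPx > 0) {
    x <- x + stats::rnorm(n, 0, fixationJitterPx)
    y <- y + stats::rnorm(n, 0, fixationJitterPx)
  }
  list(t_ms = t_ms, x_px = x, y_px = y, firstLanding = c(tx[1], ty[1]),
       latencyMs = latency)
}

#' Gaze-model parameters scaled to another display size
#'
#' Landing noise and fixation jitter are expressed in screen pixels and
#' stated at the reference display scale (a 227 px image shown at 454 px,
#' where 20 px is about half a degree of visual angle). This helper rescales
#' them proportionally so the gaze geometry covers the same image fraction
#' at other resolutions.
#'
#' @param imageSize native image side length in px.
#' @param scaleFactor display px per image px (default 2).
#' @param ... passed to [gazeModelParams()].
#' @return A [GazeModelParams-class].
#' @export
scaledGazeModelParams <- function(imageSize, scaleFactor = 2, ...) {
  s <- (imageSize * scaleFactor) / 454
  gazeModelParams(saccadeNoisePx = 20 * s, fixationJitterPx = 3 * s, ...)
}

#' Simulate one gaze trial over a stimulus image
#'
#' Samples are spaced exactly 1/samplingRate apart over the presentation.
#' Gaze begins at screen center (the fixation-cross position), saccades
#' after a jittered central-onset latency to the face-ROI centroid (with
#' probability `faceBias`, when a face is present; otherwise it falls back
#' to the object-ROI centroid) plus Gaussian landing noise, and refixates at
#' `refixationRate` thereafter. Coordinates are screen pixels and may fall
#' outside the image bounds.
#'
#' @param image a [StimulusImage-class].
#' @param params a [GazeModelParams-class]; if its seed is not NA the trial
#'   is reproducible on its own, otherwise the current RNG stream is used.
#' @param geometry a [DisplayGeometry-class].
#' @param participantId participant label for the output stream.
#' @return data.frame with columns participant_id, image_id, t_ms, x_px,
#'   y_px; attribute "firstLanding" holds the first landing point (screen px).
#' @examples
#' set <- generateStimulusSet(stimulusSpec(nCategories = 2,
#'   nImagesPerCategory = 1, imageSize = 48, seed = 1))
#' geom <- displayGeometry(48)
#' tr <- simulateScanpath(set@images[[1]],
#'   gazeModelParams(seed = 5), geom, "p01")
#' nrow(tr)  # 1500 samples at 1000 Hz over 1500 ms
#' @export
simulateScanpath <- function(image, params, geometry, participantId = "p01") {
  validObject(params)
  run <- function() .simulateTrialCore(
    image, geometry, params@samplingRate, params@presentationMs,
    params@centralOnsetMs, params@centralOnsetSdMs, params@saccadeNoisePx,
    params@faceBias, params@fixationJitterPx, params@refixationRate)
  tr <- if (!is.na(params@seed)) withSeed(params@seed, run()) else run()
  out <- data.frame(participant_id = participantId, image_id = image@imageId,
                    t_ms = tr$t_ms, x_px = tr$x_px, y_px = tr$y_px,
                    stringsAsFactors = FALSE)
  attr(out, "firstLanding") <- tr$firstLanding
  attr(out, "latencyMs") <- tr$latencyMs
  out
}

#' Draw per-participant parameter perturbations
#'
#' Each simulated participant perturbs the base gaze model: latency mean
#' (normal, SD 12 ms), face bias (logit-normal, SD 0.25), landing noise and
#' jitter (log-normal, SD 0.15). The manifest records every derived seed.
#'
#' @param nParticipants number of participants.
#' @param params base [GazeModelParams-class].
#' @param masterSeed cohort master seed.
#' @param participantIds optional explicit ids; duplicates are rejected.
#' @return data.frame, one row per participant.
#' @export
simulateCohortManifest <- function(nParticipants, params, masterSeed,
                                   participantIds = NULL) {
  stopifnot(nParticipants >= 1)
  if (is.null(participantIds)) {
    participantIds <- sprintf("p%02d", seq_len(nParticipants))
  }
  if (anyDuplicated(participantIds)) stop("duplicate participant ids")
  if (length(participantIds) != nParticipants)
    stop("participantIds length must equal nParticipants")
  withSeed(deriveSeed(masterSeed, "participants"), {
    fb <- .clamp(params@faceBias, 0.01, 0.99)
    data.frame(
      participant_id = participantIds,
      central_onset_ms = .clamp(stats::rnorm(nParticipants, params@centralOnsetMs, 12), 120, 260),
      face_bias = if (params@faceBias %in% c(0, 1)) rep(params@faceBias, nParticipants)
                  else stats::plogis(stats::qlogis(fb) + stats::rnorm(nParticipants, 0, 0.25)),
      saccade_noise_px = params@saccadeNoisePx * exp(stats::rnorm(nParticipants, 0, 0.15)),
      fixation_jitter_px = params@fixationJitterPx * exp(stats::rnorm(nParticipants, 0, 0.15)),
      refixation_rate = params@refixationRate,
      seed = vapply(participantIds,
                    function(p) deriveSeed(masterSeed, paste0("participant/", p)),
                    integer(1)),
      stringsAsFactors = FALSE)
  })
}

# one trial from a participant manifest row, seeded by (masterSeed, pid, image)
.simulateTrialFromManifest <- function(image, prow, geometry, params, masterSeed) {
  seed <- deriveSeed(masterSeed, paste0("trial/", prow$participant_id, "/", image@imageId))
  withSeed(seed, .simulateTrialCore(
    image, geometry, params@samplingRate, params@presentationMs,
    prow$central_onset_ms, params@centralOnsetSdMs, prow$saccade_noise_px,
    prow$face_bias, prow$fixation_jitter_px, prow$refixation_rate))
}

#' Simulate a gaze cohort over a stimulus set
#'
#' One gaze stream per (participant, image), with per-participant parameter
#' perturbations drawn from the hyper-distributions documented in
#' [simulateCohortManifest()]. All randomness derives from `masterSeed`
#' through named sub-streams, so repeated calls are identical.
#'
#' @param stimuli a [StimulusSet-class].
#' @param nParticipants number of simulated participants (>= 1).
#' @param params base [GazeModelParams-class].
#' @param geometry a [DisplayGeometry-class].
#' @param masterSeed cohort master seed.
#' @param participantIds optional explicit participant ids.
#' @param outDir if non-NULL, per-participant gaze CSVs and a JSON manifest
#'   are written there (see [writeGazeCohort()]).
#' @return A [GazeCohort-class].
#' @export
simulateCohort <- function(stimuli, nParticipants, params, geometry,
                           masterSeed = 1L, participantIds = NULL,
                           outDir = NULL) {
  participants <- simulateCohortManifest(nParticipants, params, masterSeed,
                                         participantIds)
  pieces <- vector("list", nrow(participants) * length(stimuli@images))
  k <- 0L
  for (pi in seq_len(nrow(participants))) {
    prow <- participants[pi, ]
    for (img in stimuli@images) {
      tr <- .simulateTrialFromManifest(img, prow, geometry, params, masterSeed)
      k <- k + 1L
      pieces[[k]] <- data.table::data.table(
        participant_id = prow$participant_id, image_id = img@imageId,
        t_ms = tr$t_ms, x_px = tr$x_px, y_px = tr$y_px)
    }
  }
  samples <- as.data.frame(data.table::rbindlist(pieces))
  cohort <- new("GazeCohort", samples = samples, participants = participants,
                params = params, geometry = geometry,
                masterSeed = as.integer(masterSeed))
  if (!is.null(outDir)) writeGazeCohort(cohort, outDir)
  cohort
}
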