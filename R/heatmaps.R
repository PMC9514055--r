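# Fixation-density heatmaps: select in-image samples, group into 50 ms
# windows, accumulate per-pixel sample counts (dwell-time weighting at
# 1 kHz), smooth with a Gaussian and peak-normalize, average participants.

#' Heatmap configuration scaled to another image resolution
#'
#' The smoothing SD (default 20 px) is defined at the native 227 px scale;
#' this helper rescales it proportionally so the smoothed density covers the
#' same image fraction at other resolutions.
#'
#' @param imageSize image side length in px.
#' @param ... passed to [heatmapConfig()].
#' @return A [HeatmapConfig-class].
#' @export
scaledHeatmapConfig <- function(imageSize, ...) {
  heatmapConfig(smoothingSdPx = max(1, 20 * imageSize / 227), ...)
}

#' Restrict gaze samples to the displayed image and localize coordinates
#'
#' Retains only samples whose screen coordinates fall inside the displayed
#' image rectangle (half-open: `[origin, origin + displaySize)`) and
#' converts them to 0-based image pixel coordinates by subtracting the
#' origin, dividing by the scale factor and flooring.
#'
#' @param samples data.frame with columns x_px, y_px (screen px) and t_ms.
#' @param geometry a [DisplayGeometry-class].
#' @return The retained rows with integer columns x_img, y_img appended,
#'   each in `[0, imageSize)`.
#' @export
selectInImage <- function(samples, geometry) {
  ox <- geometry@imageOrigin[1L]; oy <- geometry@imageOrigin[2L]
  d <- geometry@imageDisplaySize
  keep <- samples$x_px >= ox & samples$x_px < ox + d &
          samples$y_px >= oy & samples$y_px < oy + d
  out <- samples[keep, , drop = FALSE]
  out$x_img <- as.integer(floor((out$x_px - ox) / geometry@scaleFactor))
  out$y_img <- as.integer(floor((out$y_px - oy) / geometry@scaleFactor))
  # guard against floating-point edge cases at the upper boundary
  out$x_img <- pmin(out$x_img, geometry@imageSize - 1L)
  out$y_img <- pmin(out$y_img, geometry@imageSize - 1L)
  rownames(out) <- NULL
  out
}

#' Group samples into discrete time windows
#'
#' Windows are `[k * windowMs, (k+1) * windowMs)` over presentation time for
#' k = 0 ... horizonMs/windowMs - 1. The window clock runs on presentation
#' time: out-of-image samples should be dropped beforehand (they do not
#' shift window boundaries). With `cumulative = TRUE` window k contains all
#' samples up to its offset.
#'
#' @param samples time-sorted data.frame with a t_ms column.
#' @param config a [HeatmapConfig-class].
#' @return Named list of exactly horizonMs/windowMs data.frames (possibly
#'   empty), names "0", "1", ....
#' @export
windowSamples <- function(samples, config) {
  if (config@horizonMs %% config@windowMs != 0)
    stop("horizonMs must be a multiple of windowMs")
  K <- as.integer(config@horizonMs / config@windowMs)
  w <- floor(samples$t_ms / config@windowMs)
  out <- vector("list", K)
  for (k in seq_len(K) - 1L) {
    sel <- if (config@cumulative) w <= k else w == k
    out[[k + 1L]] <- samples[sel, , drop = FALSE]
  }
  names(out) <- as.character(seq_len(K) - 1L)
  out
}

#' Accumulate image-local samples into a raw count matrix
#'
#' Cell (r, c) counts the samples landing on image pixel (y = r-1, x = c-1);
#' the matrix total equals the number of samples. Raw 1 kHz sample counts
#' approximate dwell time, so no fixation-event parsing is performed.
#'
#' @param sampleGroup data.frame with integer columns x_img, y_img.
#' @param imageSize image side length in px.
#' @return Integer imageSize x imageSize matrix.
#' @export
accumulateDensity <- function(sampleGroup, imageSize) {
  S <- as.integer(imageSize)
  if (nrow(sampleGroup) == 0L) return(matrix(0L, S, S))
  xi <- sampleGroup$x_img; yi <- sampleGroup$y_img
  if (any(xi < 0L | xi >= S | yi < 0L | yi >= S))
    stop("image-local coordinates out of range; run selectInImage() first")
  lin <- yi + 1L + xi * S
  matrix(tabulate(lin, nbins = S * S), S, S)
}

#' Smooth a raw count matrix and peak-normalize it
#'
#' Gaussian smoothing with SD `smoothingSdPx`, truncated at 4 SD, with
#' reflective borders (mass-conserving), then normalized so the maximum is
#' 1. An all-zero input stays all-zero with normalization recorded as
#' "none".
#'
#' @param raw nonnegative count matrix.
#' @param config a [HeatmapConfig-class].
#' @param imageId,windowIndex,onsetMs,offsetMs map metadata.
#' @return A [FixationDensityMap-class].
#' @export
smoothAndNormalize <- function(raw, config, imageId = "", windowIndex = "all",
                               onsetMs = 0, offsetMs = NA_real_) {
  if (min(raw) < 0) stop("raw density must be nonnegative")
  sm <- gaussianSmooth(raw + 0, config@smoothingSdPx)
  sm[sm < 0] <- 0  # numerical guard
  mx <- max(sm)
  if (mx > 0) {
    sm <- sm / mx
    norm <- "peak"
  } else {
    norm <- "none"
  }
  new("FixationDensityMap", imageId = imageId,
      windowIndex = as.character(windowIndex), windowOnsetMs = onsetMs,
      windowOffsetMs = if (is.na(offsetMs) && windowIndex != "all") config@windowMs else offsetMs,
      values = sm, normalization = norm)
}

#' Average per-participant density maps and renormalize
#'
#' Element-wise mean of peak-normalized participant maps, then
#' peak-normalized again (so a single participant's map is returned
#' unchanged).
#'
#' @param maps list of [FixationDensityMap-class] for the same image and
#'   window.
#' @return A [FixationDensityMap-class].
#' @export
averageParticipants <- function(maps) {
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1L]]
  for (m in maps) {
    if (!identical(dim(m@values), dim(ref@values)))
      stop("mismatched map shapes")
    if (m@imageId != ref@imageId || m@windowIndex != ref@windowIndex)
      stop("maps must belong to the same image and window")
  }
  acc <- Reduce(`+`, lapply(maps, function(m) m@values)) / length(maps)
  mx <- max(acc)
  norm <- if (mx > 0) { acc <- acc / mx; "peak" } else "none"
  new("FixationDensityMap", imageId = ref@imageId,
      windowIndex = ref@windowIndex, windowOnsetMs = ref@windowOnsetMs,
      windowOffsetMs = ref@windowOffsetMs, values = acc, normalization = norm)
}

# ---- streaming cohort pipeline ----------------------------------------------

# smooth + peak normalize a raw count matrix given a precomputed 1-D operator
.smoothNorm <- function(raw, M) {
  sm <- M %*% raw %*% t(M)
  sm[sm < 0] <- 0
  mx <- max(sm)
  if (mx > 0) sm / mx else sm
}

#' Cohort-averaged fixation-density maps, computed by streaming
#'
#' Simulates each (participant, image) trial from the cohort manifest,
#' localizes in-image samples, accumulates per-window counts, smooths and
#' peak-normalizes each participant map, and averages across participants --
#' without materializing the full sample table. Numerically identical to
#' running [simulateCohort()] followed by the individual heatmap operations.
#'
#' @param stimuli a [StimulusSet-class].
#' @param nParticipants number of simulated participants.
#' @param params base [GazeModelParams-class].
#' @param geometry a [DisplayGeometry-class].
#' @param config a [HeatmapConfig-class]. With `fullPresentation = TRUE`
#'   only the pooled "all" map is produced; otherwise the
#'   horizonMs/windowMs windows are produced, plus the pooled map when
#'   `includeAll = TRUE`.
#' @param masterSeed cohort master seed (must match the [simulateCohort()]
#'   seed for identical gaze).
#' @param participants optional precomputed manifest from
#'   [simulateCohortManifest()].
#' @param includeAll also emit the full-presentation "all" map in windowed
#'   mode.
#' @return Named list (by image id) of named lists of
#'   [FixationDensityMap-class] ("all" and/or "0" ... "19").
#' @export
cohortDensityMaps <- function(stimuli, nParticipants, params, geometry, config,
                              masterSeed = 1L, participants = NULL,
                              includeAll = TRUE) {
  if (is.null(participants)) {
    participants <- simulateCohortManifest(nParticipants, params, masterSeed)
  }
  S <- geometry@imageSize
  M <- smoothingMatrix(S, config@smoothingSdPx)
  ox <- geometry@imageOrigin[1L]; oy <- geometry@imageOrigin[2L]
  d <- geometry@imageDisplaySize; sf <- geometry@scaleFactor
  windowed <- !config@fullPresentation
  K <- if (windowed) as.integer(config@horizonMs / config@windowMs) else 0L
  keys <- c(if (windowed) as.character(seq_len(K) - 1L),
            if (!windowed || includeAll) "all")
  nP <- nrow(participants)

  out <- vector("list", length(stimuli@images))
  names(out) <- names(stimuli@images)
  for (id in names(stimuli@images)) {
    img <- stimuli@images[[id]]
    sums <- lapply(keys, function(k) matrix(0, S, S))
    names(sums) <- keys
    for (pi in seq_len(nP)) {
      tr <- .simulateTrialFromManifest(img, participants[pi, ], geometry,
                                       params, masterSeed)
      keep <- tr$x_px >= ox & tr$x_px < ox + d &
              tr$y_px >= oy & tr$y_px < oy + d
      xi <- pmin(as.integer(floor((tr$x_px[keep] - ox) / sf)), S - 1L)
      yi <- pmin(as.integer(floor((tr$y_px[keep] - oy) / sf)), S - 1L)
      tt <- tr$t_ms[keep]
      lin <- yi + 1L + xi * S
      if ("all" %in% keys) {
        raw <- matrix(tabulate(lin, nbins = S * S), S, S)
        sums[["all"]] <- sums[["all"]] + .smoothNorm(raw, M)
      }
      if (windowed) {
        w <- floor(tt / config@windowMs)
        for (k in seq_len(K) - 1L) {
          sel <- if (config@cumulative) w <= k else w == k
          raw <- matrix(tabulate(lin[sel], nbins = S * S), S, S)
          sums[[as.character(k)]] <- sums[[as.character(k)]] + .smoothNorm(raw, M)
        }
      }
    }
    maps <- vector("list", length(keys))
    names(maps) <- keys
    for (k in keys) {
      acc <- sums[[k]] / nP
      mx <- max(acc)
      norm <- if (mx > 0) { acc <- acc / mx; "peak" } else "none"
      onset <- if (k == "all") 0 else as.numeric(k) * config@windowMs
      offset <- if (k == "all") params@presentationMs
                else if (config@cumulative) (as.numeric(k) + 1) * config@windowMs
                else (as.numeric(k) + 1) * config@windowMs
      maps[[k]] <- new("FixationDensityMap", imageId = id, windowIndex = k,
                       windowOnsetMs = if (k == "all" || !config@cumulative) onset else 0,
                       windowOffsetMs = offset, values = acc,
                       normalization = norm)
    }
    out[[id]] <- maps
  }
  out
}
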