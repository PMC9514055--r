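# Human-likeness metrics: per-image Pearson/Fisher-Z similarity between
# saliency and gaze maps, face-detection index, grouped bootstrap
# summaries, and the accuracy-versus-similarity trade-off table.
#
# Aggregation order follows the measurement design: correlations are
# computed per image and then averaged/transformed, never pooled across
# images at the pixel level.

.R_CLAMP <- 1 - 1e-7

#' Pearson correlation and Fisher-Z between two maps
#'
#' Correlation over flattened pixels; the Fisher transform uses r clamped
#' to +/-(1 - 1e-7) so perfectly (anti)correlated maps stay finite.
#' Symmetric in its arguments. A zero-variance map raises a classed error
#' (`gazeSpotlight_zero_variance`) so callers can drop the record with a
#' logged reason rather than record a silent zero.
#'
#' @param a,b numeric matrices (or map objects) of identical shape.
#' @return list(r, z).
#' @export
pearsonFisher <- function(a, b) {
  if (is(a, "FixationDensityMap") || is(a, "SaliencyMap")) a <- mapValues(a)
  if (is(b, "FixationDensityMap") || is(b, "SaliencyMap")) b <- mapValues(b)
  if (!identical(dim(a), dim(b))) stop("maps must have identical shape")
  av <- as.numeric(a); bv <- as.numeric(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    stop(structure(class = c("gazeSpotlight_zero_variance", "error", "condition"),
                   list(message = "zero-variance map (degenerate)", call = sys.call())))
  }
  r <- stats::cor(av, bv)
  z <- atanh(.clamp(r, -.R_CLAMP, .R_CLAMP))
  list(r = r, z = z)
}

#' Similarity records between model saliency and human gaze maps
#'
#' One record per (run, image, window) for the requested windows, plus an
#' "all"-window record against the full-presentation averaged heatmap.
#' Misclassified images are included (saliency is always computed for the
#' true class); per-image correctness is attached when the run has been
#' evaluated. Records whose maps are degenerate (zero variance) are
#' dropped and listed in the "skipped" attribute.
#'
#' @param runs list of [ModelRun-class].
#' @param saliencyMaps list by run id of lists by image id of
#'   [SaliencyMap-class].
#' @param humanMaps list by image id of lists by window key ("all",
#'   "0", "1", ...) of [FixationDensityMap-class].
#' @param stimManifest data.frame with image_id, category, animate,
#'   has_face.
#' @param windows window keys to include besides "all" (default: all
#'   windowed keys present in `humanMaps`).
#' @return Tidy data.frame of similarity records.
#' @export
similarityTable <- function(runs, saliencyMaps, humanMaps, stimManifest,
                            windows = NULL) {
  imageIds <- intersect(stimManifest$image_id, names(humanMaps))
  if (is.null(windows)) {
    windows <- setdiff(names(humanMaps[[imageIds[1L]]]), "all")
  }
  keys <- c("all", windows)
  # precompute centered human map vectors and their norms
  hprep <- lapply(imageIds, function(id) {
    lapply(keys, function(k) {
      m <- humanMaps[[id]][[k]]
      if (is.null(m)) return(NULL)
      v <- as.numeric(m@values)
      v <- v - mean(v)
      n <- sqrt(sum(v^2))
      list(v = v, n = n)
    })
  })
  names(hprep) <- imageIds
  for (id in imageIds) names(hprep[[id]]) <- keys

  mrows <- match(imageIds, stimManifest$image_id)
  recs <- list(); skipped <- list()
  for (run in runs) {
    sal <- saliencyMaps[[run@runId]]
    correctMap <- if (length(run@evaluation)) {
      stats::setNames(run@evaluation$perImage$correct,
                      run@evaluation$perImage$image_id)
    } else NULL
    rs <- matrix(NA_real_, length(imageIds), length(keys),
                 dimnames = list(imageIds, keys))
    for (ii in seq_along(imageIds)) {
      id <- imageIds[ii]
      sm <- sal[[id]]
      if (is.null(sm)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          run_id = run@runId, image_id = id, window = "all",
          reason = "missing saliency map")
        next
      }
      sv <- as.numeric(sm@values)
      sv <- sv - mean(sv)
      sn <- sqrt(sum(sv^2))
      if (sn == 0) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          run_id = run@runId, image_id = id, window = "*",
          reason = "zero-variance saliency map")
        next
      }
      for (k in keys) {
        hp <- hprep[[id]][[k]]
        if (is.null(hp)) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            run_id = run@runId, image_id = id, window = k,
            reason = "missing gaze map")
          next
        }
        if (hp$n == 0) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            run_id = run@runId, image_id = id, window = k,
            reason = "zero-variance gaze map")
          next
        }
        rs[ii, k] <- sum(sv * hp$v) / (sn * hp$n)
      }
    }
    long <- data.frame(
      mode = run@mode, ratio_percent = run@ratioPercent, run_id = run@runId,
      image_id = rep(imageIds, times = length(keys)),
      window = rep(keys, each = length(imageIds)),
      r = as.numeric(rs),
      category = rep(stimManifest$category[mrows], times = length(keys)),
      animate = rep(stimManifest$animate[mrows], times = length(keys)),
      has_face = rep(stimManifest$has_face[mrows], times = length(keys)),
      stringsAsFactors = FALSE)
    long <- long[!is.na(long$r), , drop = FALSE]
    long$z <- atanh(.clamp(long$r, -.R_CLAMP, .R_CLAMP))
    long$correct <- if (!is.null(correctMap)) unname(correctMap[long$image_id]) else NA
    recs[[length(recs) + 1L]] <- long
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Face-detection index of an attention map
#'
#' Ratio of attention mass inside the face region of interest to the mass
#' outside it: high when attention concentrates on the face, low when it is
#' distributed across the image. A vanishing outside mass is floored at
#' `eps` times the total mass; the returned value then carries a "capped"
#' attribute.
#'
#' @param map nonnegative matrix or map object.
#' @param faceRoi non-empty logical matrix.
#' @param eps relative floor for the outside mass (default 1e-9).
#' @return Numeric index (>= 0), with attribute "capped" when floored.
#' @export
faceDetectionIndex <- function(map, faceRoi, eps = 1e-9) {
  if (is(map, "FixationDensityMap") || is(map, "SaliencyMap")) map <- mapValues(map)
  if (!any(faceRoi)) stop("empty face ROI: image is excluded from face analyses")
  if (min(map) < 0) stop("map must be nonnegative")
  total <- sum(map)
  if (total == 0) return(structure(0, capped = FALSE))
  inside <- sum(map[faceRoi])
  outside <- total - inside
  capped <- outside < eps * total
  structure(inside / max(outside, eps * total), capped = capped)
}

#' Prepare a region-of-interest mask for analysis or export
#'
#' Rater-drawn ROI masks are conventionally averaged, normalized and
#' smoothed with a Gaussian (window 10, SD 5) for visualization; index
#' computation uses the mask binarized at a threshold. Synthetic ROIs are
#' already exact, so this mainly matters when importing hand-segmented
#' masks.
#'
#' @param masks a logical/numeric matrix or a list of them (e.g. one per
#'   rater), averaged before smoothing.
#' @param window,sd smoothing Gaussian window and SD in px (defaults 10
#'   and 5).
#' @param threshold binarization threshold on the smoothed, peak-normalized
#'   weights (default 0.5).
#' @return list with `weights` (smoothed, peak-normalized matrix) and
#'   `mask` (logical matrix, `weights >= threshold`).
#' @export
prepareRoi <- function(masks, window = 10, sd = 5, threshold = 0.5) {
  if (!is.list(masks)) masks <- list(masks)
  avg <- Reduce(`+`, lapply(masks, function(m) m + 0)) / length(masks)
  w <- gaussianSmooth(avg, sd, window)
  mx <- max(w)
  if (mx > 0) w <- w / mx
  list(weights = w, mask = w >= threshold)
}

# percentile bootstrap CI over a vector
.bootCI <- function(x, B, statFun) {
  if (length(x) == 1L) return(c(x, x))
  stats::quantile(vapply(seq_len(B), function(i)
    statFun(x[sample.int(length(x), replace = TRUE)]), numeric(1)),
    c(0.025, 0.975), names = FALSE)
}

#' Grouped summary with percentile bootstrap confidence intervals
#'
#' Aggregates records per image within each cell (mean over runs), then
#' reports the cell mean and median with seeded percentile bootstrap CIs
#' (B resamples of images within the cell).
#'
#' @param records data.frame of similarity (or index/accuracy) records
#'   with an image_id column.
#' @param split "none", "animacy", "face", "category", "mode" or "window";
#'   cells are crossed with mode when present.
#' @param valueCol column to summarize (default "z").
#' @param B bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @return Tidy data.frame: one row per cell with n, mean, median and CI
#'   bounds.
#' @export
groupSummary <- function(records, split = c("none", "animacy", "face",
                                            "category", "mode", "window"),
                         valueCol = "z", B = 2000L, seed = 1L) {
  split <- match.arg(split)
  cellCols <- switch(split,
    none = character(),
    animacy = "animate",
    face = "has_face",
    category = "category",
    mode = character(),
    window = "window")
  if ("mode" %in% names(records)) cellCols <- c("mode", cellCols)
  key <- if (length(cellCols)) {
    interaction(records[cellCols], drop = TRUE, sep = "|")
  } else factor(rep("all", nrow(records)))
  out <- list()
  withSeed(deriveSeed(seed, "groupSummary"), {
    for (cell in levels(key)) {
      sub <- records[key == cell, , drop = FALSE]
      perImage <- tapply(sub[[valueCol]], sub$image_id, mean)
      x <- as.numeric(perImage)
      ciM <- .bootCI(x, B, mean)
      ciMd <- .bootCI(x, B, stats::median)
      row <- data.frame(cell = cell, n_images = length(x), mean = mean(x),
                        ci_lo = ciM[1], ci_hi = ciM[2],
                        median = stats::median(x),
                        median_lo = ciMd[1], median_hi = ciMd[2],
                        stringsAsFactors = FALSE)
      parts <- strsplit(cell, "|", fixed = TRUE)[[1L]]
      for (ci in seq_along(cellCols)) row[[cellCols[ci]]] <- parts[ci]
      out[[length(out) + 1L]] <- row
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Accuracy-versus-similarity trade-off table
#'
#' One point per (mode, ratio) with the mean accuracy and mean Fisher-Z
#' over runs plus seeded percentile bootstrap CIs over runs. Ready for
#' plotting or export as a tidy CSV.
#'
#' @param runSummary data.frame with one row per run: mode, ratio_percent,
#'   run_id, accuracy, mean_z.
#' @param B bootstrap resamples.
#' @param seed bootstrap seed.
#' @return Tidy data.frame of trade-off points, ordered by mode then ratio.
#' @export
tradeoffCurve <- function(runSummary, B = 2000L, seed = 1L) {
  cells <- unique(runSummary[c("mode", "ratio_percent")])
  cells <- cells[order(cells$mode, cells$ratio_percent), , drop = FALSE]
  out <- list()
  withSeed(deriveSeed(seed, "tradeoff"), {
    for (i in seq_len(nrow(cells))) {
      sub <- runSummary[runSummary$mode == cells$mode[i] &
                        runSummary$ratio_percent == cells$ratio_percent[i], ]
      ciA <- .bootCI(sub$accuracy, B, mean)
      ciZ <- .bootCI(sub$mean_z, B, mean)
      out[[i]] <- data.frame(
        mode = cells$mode[i], ratio_percent = cells$ratio_percent[i],
        n_runs = nrow(sub),
        accuracy = mean(sub$accuracy), accuracy_lo = ciA[1], accuracy_hi = ciA[2],
        mean_z = mean(sub$mean_z), mean_z_lo = ciZ[1], mean_z_hi = ciZ[2])
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
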