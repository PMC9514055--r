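# End-to-end experiment drivers: synthetic cohort -> heatmaps -> spotlight
# manipulation -> repeated fine-tuning -> Grad-CAM -> similarity metrics.

# assemble cached features for a ratio-mixed dataset
.datasetFeatures <- function(ds, featStd, featManip) {
  mf <- ds@manifest
  out <- featStd[mf$image_id, , drop = FALSE]
  if (any(mf$manipulated)) {
    ids <- mf$image_id[mf$manipulated]
    out[ids, ] <- featManip[ids, , drop = FALSE]
  }
  out
}

# Grad-CAM maps for every test image of a run, reusing cached activations
.runSaliency <- function(run, testStimuli, testActs) {
  out <- vector("list", length(testStimuli@images))
  names(out) <- names(testStimuli@images)
  for (id in names(testStimuli@images)) {
    out[[id]] <- .gradcamFromActs(run, testActs[[id]],
                                  testStimuli@images[[id]]@category, id)
  }
  out
}

# per-run mean Fisher-Z over the "all"-window records
.runMeanZ <- function(records) {
  sub <- records[records$window == "all", ]
  agg <- tapply(sub$z, sub$run_id, mean)
  data.frame(run_id = names(agg), mean_z = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Run the guided-attention experiment on a synthetic cohort
#'
#' The full pipeline at desk scale: generates disjoint training and test
#' stimulus sets, simulates a gaze cohort over each (the training cohort's
#' pooled full-presentation heatmaps drive the spotlight manipulation; the
#' test cohort provides windowed and pooled comparison maps), fine-tunes
#' `nRuns` seeded head-only runs per manipulation mode, extracts Grad-CAM
#' maps for the true class of every test image, and assembles tidy
#' similarity, accuracy, face-index and blur-extent tables.
#'
#' Defaults mirror the reference study conditions at reduced resolution:
#' 12 categories x 30 training images, independent test exemplars, 23
#' simulated participants, face bias 0.85, 10 runs per mode, a "small"
#' 3-conv backbone at 64 px.
#'
#' @param masterSeed master seed; every stage derives named sub-seeds.
#' @param imageSize stimulus side length in px (multiple of 8).
#' @param nCategories,nImagesPerCategory training-set layout.
#' @param nTestPerCategory test exemplars per category.
#' @param nParticipants simulated cohort size.
#' @param faceBias probability a saccade targets the face region.
#' @param modes manipulation modes to train (subset of STD/HS/AS).
#' @param nRuns fine-tuning runs per mode.
#' @param architecture backbone preset.
#' @param verbose emit progress messages.
#' @return A list with tidy result tables (`similarity`, `runSummary`,
#'   `faceIndexModel`, `faceIndexHuman`, `blur`, `summary`) and the reusable
#'   context (`stimuli`, `testStimuli`, `trainMaps`, `testMaps`,
#'   `manipulated`, `backbone`, cached features) for follow-up sweeps.
#' @seealso [runTradeoffSweep()]
#' @export
runSpotlightExperiment <- function(masterSeed = 1L, imageSize = 64L,
                                   nCategories = 12L, nImagesPerCategory = 30L,
                                   nTestPerCategory = 15L, nParticipants = 23L,
                                   faceBias = 0.85,
                                   modes = c("STD", "HS", "AS"), nRuns = 10L,
                                   architecture = "small", verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  modes <- match.arg(modes, several.ok = TRUE)

  say("generating stimuli (%d + %d images)...",
      nCategories * nImagesPerCategory, nCategories * nTestPerCategory)
  trainStimuli <- generateStimulusSet(
    stimulusSpec(nCategories, nImagesPerCategory, imageSize,
                 seed = deriveSeed(masterSeed, "stimTrain")), idPrefix = "tr_")
  testStimuli <- generateStimulusSet(
    stimulusSpec(nCategories, nTestPerCategory, imageSize,
                 seed = deriveSeed(masterSeed, "stimTest")), idPrefix = "te_")

  geometry <- displayGeometry(imageSize)
  params <- scaledGazeModelParams(imageSize, faceBias = faceBias)
  hmFull <- scaledHeatmapConfig(imageSize, fullPresentation = TRUE)
  hmWin <- scaledHeatmapConfig(imageSize)

  say("simulating gaze cohorts (%d participants)...", nParticipants)
  trainMaps <- cohortDensityMaps(trainStimuli, nParticipants, params, geometry,
                                 hmFull, deriveSeed(masterSeed, "cohortTrain"))
  testMaps <- cohortDensityMaps(testStimuli, nParticipants, params, geometry,
                                hmWin, deriveSeed(masterSeed, "cohortTest"))

  say("deriving spotlight manipulations...")
  manipulated <- list(); blur <- list()
  for (mode in setdiff(modes, "STD")) {
    mv <- manipulateStimulusSet(trainStimuli, trainMaps,
                                scaledManipulationSpec(mode, imageSize))
    manipulated[[mode]] <- mv
    blur[[mode]] <- data.frame(
      mode = mode, image_id = names(mv),
      blur_fraction = vapply(mv, function(x) x$blurFraction, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  blur <- if (length(blur)) do.call(rbind, blur) else NULL
  if (!is.null(blur)) rownames(blur) <- NULL

  say("building backbone and caching features...")
  backbone <- buildBackbone(architecture, imageSize, nCategories,
                            seed = deriveSeed(masterSeed, "backbone"))
  featStd <- convFeatures(backbone, trainStimuli)$features
  featManip <- lapply(manipulated, function(mv)
    convFeatures(backbone, lapply(mv, function(x) x$pixels))$features)
  testFw <- convFeatures(backbone, testStimuli, keepConv = TRUE)

  allRuns <- list(); saliencyMaps <- list()
  for (mode in modes) {
    say("fine-tuning %d %s runs...", nRuns, mode)
    ratio <- if (mode == "STD") 0 else 100
    builder <- local({
      mode_ <- mode; ratio_ <- ratio
      function(seed) buildTrainingSet(trainStimuli, manipulated[[mode_]],
                                      mode_, ratio_, seed)
    })
    featureFun <- local({
      fm <- if (mode == "STD") featStd else featManip[[mode]]
      function(ds) .datasetFeatures(ds, featStd, fm)
    })
    cfg <- trainingConfig(seed = deriveSeed(masterSeed, paste0("train/", mode)))
    rr <- repeatRuns(backbone, builder, cfg, nRuns, testSet = testStimuli,
                     featureFun = featureFun, testFeatures = testFw$features)
    for (run in rr$runs) {
      allRuns[[run@runId]] <- run
      saliencyMaps[[run@runId]] <- .runSaliency(run, testStimuli, testFw$acts)
    }
  }

  say("computing similarity records...")
  similarity <- similarityTable(allRuns, saliencyMaps, testMaps,
                                testStimuli@manifest)

  # face-detection indices: static per model map, time-resolved for humans
  faceIds <- testStimuli@manifest$image_id[testStimuli@manifest$has_face]
  fiModel <- list()
  for (run in allRuns) {
    for (id in faceIds) {
      idx <- faceDetectionIndex(saliencyMaps[[run@runId]][[id]]@values,
                                testStimuli@images[[id]]@faceRoi)
      fiModel[[length(fiModel) + 1L]] <- data.frame(
        source = "model", mode = run@mode, run_id = run@runId, image_id = id,
        window = "all", index = as.numeric(idx), stringsAsFactors = FALSE)
    }
  }
  fiHuman <- list()
  for (id in faceIds) {
    for (k in names(testMaps[[id]])) {
      idx <- faceDetectionIndex(testMaps[[id]][[k]]@values,
                                testStimuli@images[[id]]@faceRoi)
      fiHuman[[length(fiHuman) + 1L]] <- data.frame(
        source = "human", mode = "human", run_id = "human", image_id = id,
        window = k, index = as.numeric(idx), stringsAsFactors = FALSE)
    }
  }
  faceIndexModel <- do.call(rbind, fiModel)
  faceIndexHuman <- do.call(rbind, fiHuman)

  # per-run summary: accuracy + mean Fisher-Z over the pooled window
  meanZ <- .runMeanZ(similarity)
  runSummary <- data.frame(
    mode = vapply(allRuns, function(r) r@mode, character(1)),
    ratio_percent = vapply(allRuns, function(r) r@ratioPercent, numeric(1)),
    run_id = vapply(allRuns, function(r) r@runId, character(1)),
    accuracy = vapply(allRuns, function(r) r@evaluation$overall, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  runSummary$mean_z <- meanZ$mean_z[match(runSummary$run_id, meanZ$run_id)]

  summaryStats <- list()
  for (mode in modes) {
    subAll <- similarity[similarity$mode == mode & similarity$window == "all", ]
    perImageZ <- tapply(subAll$z, subAll$image_id, mean)
    fi <- faceIndexModel[faceIndexModel$mode == mode, ]
    perImageFi <- tapply(fi$index, fi$image_id, mean)
    accs <- runSummary$accuracy[runSummary$mode == mode]
    summaryStats[[mode]] <- data.frame(
      mode = mode, mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs),
      mean_z = mean(perImageZ), median_z = stats::median(perImageZ),
      median_face_index = stats::median(perImageFi),
      mean_blur_fraction = if (mode == "STD") 0 else
        mean(blur$blur_fraction[blur$mode == mode]))
  }
  summaryStats <- do.call(rbind, summaryStats)
  rownames(summaryStats) <- NULL

  list(masterSeed = masterSeed, imageSize = imageSize,
       stimuli = trainStimuli, testStimuli = testStimuli,
       geometry = geometry, params = params,
       trainMaps = trainMaps, testMaps = testMaps,
       manipulated = manipulated, blur = blur,
       backbone = backbone, featStd = featStd, featManip = featManip,
       testFeatures = testFw$features, testActs = testFw$acts,
       runs = allRuns, saliencyMaps = saliencyMaps,
       similarity = similarity, runSummary = runSummary,
       faceIndexModel = faceIndexModel, faceIndexHuman = faceIndexHuman,
       summary = summaryStats)
}

#' Accuracy-versus-similarity sweep across manipulation ratios
#'
#' Reuses the stimuli, gaze maps, manipulated images and cached features of
#' a [runSpotlightExperiment()] result and fine-tunes `nRunsPerRatio` seeded
#' runs per requested manipulation ratio (100 = all images manipulated,
#' 0 = the all-standard baseline).
#'
#' @param experiment result of [runSpotlightExperiment()] (must contain the
#'   manipulated versions for `mode`).
#' @param mode "HS" or "AS".
#' @param ratios manipulation ratios in \{0, 10, ..., 100\}.
#' @param nRunsPerRatio runs per ratio (default 10).
#' @param verbose emit progress messages.
#' @return list with `runSummary` (one row per run) and `curve` (the
#'   [tradeoffCurve()] table).
#' @export
runTradeoffSweep <- function(experiment, mode = "AS",
                             ratios = seq(100, 0, by = -10),
                             nRunsPerRatio = 10L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!mode %in% names(experiment$manipulated))
    stop(sprintf("experiment has no manipulated versions for mode %s", mode))
  featManip <- experiment$featManip[[mode]]
  rows <- list()
  for (ratio in ratios) {
    say("ratio %d%%: %d runs...", ratio, nRunsPerRatio)
    builder <- local({
      r_ <- ratio
      function(seed) buildTrainingSet(experiment$stimuli,
                                      experiment$manipulated[[mode]],
                                      mode, r_, seed)
    })
    cfg <- trainingConfig(seed = deriveSeed(experiment$masterSeed,
                                            sprintf("sweep/%s/%d", mode, ratio)))
    rr <- repeatRuns(experiment$backbone, builder, cfg, nRunsPerRatio,
                     testSet = experiment$testStimuli,
                     featureFun = function(ds)
                       .datasetFeatures(ds, experiment$featStd, featManip),
                     testFeatures = experiment$testFeatures)
    sal <- lapply(rr$runs, function(run)
      .runSaliency(run, experiment$testStimuli, experiment$testActs))
    names(sal) <- vapply(rr$runs, function(r) r@runId, character(1))
    sim <- similarityTable(rr$runs, sal, experiment$testMaps,
                           experiment$testStimuli@manifest, windows = character())
    mz <- .runMeanZ(sim)
    rows[[length(rows) + 1L]] <- data.frame(
      mode = mode, ratio_percent = ratio,
      run_id = vapply(rr$runs, function(r) r@runId, character(1)),
      accuracy = vapply(rr$runs, function(r) r@evaluation$overall, numeric(1)),
      mean_z = mz$mean_z[match(vapply(rr$runs, function(r) r@runId, character(1)),
                               mz$run_id)],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  runSummary <- do.call(rbind, rows)
  list(runSummary = runSummary, curve = tradeoffCurve(runSummary))
}
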