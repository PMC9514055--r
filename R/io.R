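# Plain-format IO: gaze CSV streams, float-binary maps with JSON sidecars,
# PNG images and ROI masks, manifests.

#' Write and read gaze sample streams as CSV
#'
#' Columns: participant_id, image_id, t_ms, x_px, y_px (0-based screen
#' coordinates, origin top-left, x = column).
#'
#' @param samples data.frame of gaze samples.
#' @param path CSV file path.
#' @return `readGazeCSV` returns the samples data.frame.
#' @export
writeGazeCSV <- function(samples, path) {
  cols <- c("participant_id", "image_id", "t_ms", "x_px", "y_px")
  data.table::fwrite(samples[cols], path)
  invisible(path)
}

#' @rdname writeGazeCSV
#' @export
readGazeCSV <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write a gaze cohort to disk
#'
#' One CSV per participant plus a JSON manifest recording the per-participant
#' parameters and every derived seed.
#'
#' @param cohort a [GazeCohort-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeGazeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in cohort@participants$participant_id) {
    writeGazeCSV(cohort@samples[cohort@samples$participant_id == pid, ],
                 file.path(dir, paste0("gaze_", pid, ".csv")))
  }
  jsonlite::write_json(
    list(master_seed = cohort@masterSeed,
         participants = cohort@participants,
         geometry = list(screen = c(cohort@geometry@screenW, cohort@geometry@screenH),
                         image_size = cohort@geometry@imageSize,
                         image_display_size = cohort@geometry@imageDisplaySize,
                         image_origin = cohort@geometry@imageOrigin,
                         scale_factor = cohort@geometry@scaleFactor)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write and read a density/saliency map as float binary with JSON sidecar
#'
#' Values are stored as little-endian 32-bit floats in column-major order;
#' the sidecar (`<path>.json`) records shape, window and normalization.
#'
#' @param map a [FixationDensityMap-class] or [SaliencyMap-class].
#' @param path output path for the binary payload.
#' @return `readDensityMap` returns a [FixationDensityMap-class].
#' @export
writeDensityMap <- function(map, path) {
  v <- mapValues(map)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  meta <- list(image_id = imageId(map), shape = dim(v), dtype = "float32",
               order = "column-major")
  if (is(map, "FixationDensityMap")) {
    meta$window <- map@windowIndex
    meta$window_onset_ms <- map@windowOnsetMs
    meta$window_offset_ms <- map@windowOffsetMs
    meta$normalization <- map@normalization
  } else {
    meta$run_id <- map@runId
    meta$target_class <- map@targetClass
    meta$source_layer <- map@sourceLayer
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDensityMap
#' @export
readDensityMap <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  new("FixationDensityMap", imageId = meta$image_id %||% "",
      windowIndex = as.character(meta$window %||% "all"),
      windowOnsetMs = meta$window_onset_ms %||% 0,
      windowOffsetMs = meta$window_offset_ms %||% 0,
      values = matrix(v, meta$shape[1L], meta$shape[2L]),
      normalization = meta$normalization %||% "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an experiment configuration file
#'
#' Parses a YAML file with `backbone`, `training` and `data` sections into
#' the corresponding parameter objects. Unknown keys are rejected; missing
#' keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return list with `backbone` (list of [buildBackbone()] arguments),
#'   `training` (a [TrainingConfig-class]), `data` (a
#'   [StimulusSpec-class]) and `gaze` (a [GazeModelParams-class]).
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("backbone", "training", "data", "gaze")
  if (length(setdiff(names(cfg), known)))
    stop("unknown config sections: ",
         paste(setdiff(names(cfg), known), collapse = ", "))
  callWith <- function(fun, args, what) {
    ok <- names(formals(fun))
    if (length(setdiff(names(args), ok)))
      stop(sprintf("unknown %s keys: %s", what,
                   paste(setdiff(names(args), ok), collapse = ", ")))
    do.call(fun, args)
  }
  list(
    backbone = {
      b <- cfg$backbone %||% list()
      ok <- c("architecture", "inputSize", "nClasses", "seed")
      if (length(setdiff(names(b), ok)))
        stop("unknown backbone keys: ",
             paste(setdiff(names(b), ok), collapse = ", "))
      b
    },
    training = callWith(trainingConfig, cfg$training %||% list(), "training"),
    data = callWith(stimulusSpec, cfg$data %||% list(), "data"),
    gaze = callWith(gazeModelParams, cfg$gaze %||% list(), "gaze"))
}

#' Write the tidy result tables of an experiment as CSV
#'
#' Emits `similarity.csv` (one row per run, image and window),
#' `accuracy.csv` (one row per run), `face_index.csv` (model and human
#' records), `blur.csv` and `summary.csv`, keyed so external statistics
#' tools can consume them directly.
#'
#' @param experiment result of [runSpotlightExperiment()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeExperimentTables <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(experiment$similarity, file.path(dir, "similarity.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$runSummary, file.path(dir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(experiment$faceIndexModel, experiment$faceIndexHuman),
                   file.path(dir, "face_index.csv"), row.names = FALSE)
  if (!is.null(experiment$blur))
    utils::write.csv(experiment$blur, file.path(dir, "blur.csv"),
                     row.names = FALSE)
  utils::write.csv(experiment$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a stimulus set as PNGs with a CSV manifest
#'
#' Images as RGB PNG, ROI masks as single-channel 0/255 PNG, labels in
#' `manifest.csv` (image_id, category, animate, has_face).
#'
#' @param stimuli a [StimulusSet-class].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeStimulusSet <- function(stimuli, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in stimuli@images) {
    png::writePNG(img@pixels, file.path(dir, paste0(img@imageId, ".png")))
    png::writePNG(img@objectRoi + 0, file.path(dir, paste0(img@imageId, "_object_roi.png")))
    if (img@hasFace) {
      png::writePNG(img@faceRoi + 0, file.path(dir, paste0(img@imageId, "_face_roi.png")))
    }
  }
  utils::write.csv(stimuli@manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
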