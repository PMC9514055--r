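# Synthetic stimulus and gaze generation.

test_that("default stimulus layout yields 12 categories x 30 images = 360", {
  spec <- stimulusSpec(imageSize = 64, seed = 5)
  set <- generateStimulusSet(spec)
  expect_equal(nrow(manifest(set)), 360L)
  expect_equal(length(unique(manifest(set)$category)), 12L)
  expect_equal(sum(manifest(set)$animate), 180L)
  expect_equal(unname(table(manifest(set)$category))[1], 30L)
})

test_that("face probability zero yields no face regions", {
  set <- generateStimulusSet(stimulusSpec(nCategories = 4,
    nImagesPerCategory = 3, imageSize = 48, faceProbability = 0, seed = 2))
  expect_false(any(manifest(set)$has_face))
  expect_true(all(vapply(set@images, function(i) !any(i@faceRoi), logical(1))))
})

test_that("stimulus generation is bit-identical for a fixed seed", {
  spec <- stimulusSpec(nCategories = 3, nImagesPerCategory = 2,
                       imageSize = 48, seed = 77)
  a <- generateStimulusSet(spec)
  b <- generateStimulusSet(spec)
  expect_identical(lapply(a@images, function(i) i@pixels),
                   lapply(b@images, function(i) i@pixels))
  expect_identical(manifest(a), manifest(b))
})

test_that("stimulus invariants hold: ROIs nest, faces flagged, pixels bounded", {
  set <- tinyStimuli()
  for (img in set@images) {
    expect_true(validObject(img))
    expect_true(any(img@objectRoi))
    expect_false(any(img@faceRoi & !img@objectRoi))
    expect_equal(img@hasFace, any(img@faceRoi))
    expect_true(all(img@pixels >= 0 & img@pixels <= 1))
  }
})

test_that("too-small images are rejected with an explanation", {
  expect_error(stimulusSpec(imageSize = 16), "too small")
})

test_that("scanpath covers the presentation at exact sampling spacing", {
  img <- tinyStimuli()@images[[1]]
  geom <- displayGeometry(48)
  tr <- simulateScanpath(img, gazeModelParams(seed = 31), geom, "p01")
  expect_equal(nrow(tr), 1500L)  # 1500 ms at 1000 Hz
  expect_equal(diff(tr$t_ms), rep(1, 1499))  # strictly increasing, 1/rate
  expect_true(all(c("participant_id", "image_id", "t_ms", "x_px", "y_px")
                  %in% names(tr)))
})

test_that("noise-free full face bias puts all post-latency samples on the face centroid", {
  img <- tinyStimuli()@images[[1]]
  expect_true(img@hasFace)
  geom <- displayGeometry(48)
  p <- gazeModelParams(saccadeNoisePx = 0, fixationJitterPx = 0, faceBias = 1,
                       seed = 12)
  tr <- simulateScanpath(img, p, geom, "p01")
  lat <- attr(tr, "latencyMs")
  ctr <- roiCentroid(img@faceRoi)
  scr <- geom@imageOrigin + (c(ctr[["x"]], ctr[["y"]]) + 0.5) * geom@scaleFactor
  post <- tr[tr$t_ms >= lat, ]
  expect_true(nrow(post) > 0)
  expect_equal(unique(post$x_px), scr[1])
  expect_equal(unique(post$y_px), scr[2])
})

test_that("first-landing face rate matches the configured bias within binomial error", {
  img <- tinyStimuli()@images[[1]]
  geom <- displayGeometry(48)
  p <- gazeModelParams(saccadeNoisePx = 0, fixationJitterPx = 0,
                       faceBias = 0.8)
  ctr <- roiCentroid(img@faceRoi)
  faceScr <- geom@imageOrigin + (c(ctr[["x"]], ctr[["y"]]) + 0.5) * geom@scaleFactor
  set.seed(1234)
  hits <- vapply(seq_len(200), function(i) {
    tr <- simulateScanpath(img, p, geom, "p01")
    land <- attr(tr, "firstLanding")
    isTRUE(all.equal(unname(land), unname(faceScr)))
  }, logical(1))
  # binomial 99.9% band around p = 0.8 at n = 200
  band <- qbinom(c(0.0005, 0.9995), 200, 0.8) / 200
  expect_gte(mean(hits), band[1])
  expect_lte(mean(hits), band[2])
})

test_that("cohorts produce one stream per participant-image pair and reject duplicates", {
  set <- tinyStimuli()
  geom <- displayGeometry(48)
  p <- gazeModelParams(presentationMs = 100)  # short trials keep this light
  cohort <- simulateCohort(set, 23, p, geom, masterSeed = 6)
  expect_equal(nrow(cohort@samples), 23L * length(set@images) * 100L)
  expect_equal(nrow(cohort@participants), 23L)
  expect_error(simulateCohort(set, 2, p, geom, participantIds = c("a", "a")),
               "duplicate")
})

test_that("cohort generation is reproducible from the master seed", {
  set <- tinyStimuli()
  geom <- displayGeometry(48)
  p <- gazeModelParams(presentationMs = 60)
  a <- simulateCohort(set, 3, p, geom, masterSeed = 11)
  b <- simulateCohort(set, 3, p, geom, masterSeed = 11)
  expect_identical(a@samples, b@samples)
  expect_identical(a@participants, b@participants)
})

test_that("single-participant cohort average equals that participant's own maps", {
  set <- tinyStimuli()
  img <- set@images[[1]]
  geom <- displayGeometry(48)
  p <- gazeModelParams()
  cfg <- scaledHeatmapConfig(48, fullPresentation = TRUE)
  maps <- cohortDensityMaps(set, 1, p, geom, cfg, masterSeed = 21)
  # recompute via the public single-trial path with the same manifest seed
  pts <- simulateCohortManifest(1, p, 21)
  tr <- gazeSpotlight:::.simulateTrialFromManifest(img, pts[1, ], geom, p, 21)
  samples <- data.frame(t_ms = tr$t_ms, x_px = tr$x_px, y_px = tr$y_px)
  loc <- selectInImage(samples, geom)
  raw <- accumulateDensity(loc, 48)
  one <- smoothAndNormalize(raw, cfg, imageId = img@imageId)
  expect_equal(maps[[img@imageId]][["all"]]@values, one@values,
               tolerance = 1e-12)
})

test_that("high face bias concentrates cohort attention mass inside the face ROI", {
  set <- tinyStimuli()
  geom <- displayGeometry(48)
  p <- scaledGazeModelParams(48, faceBias = 0.9)
  maps <- cohortDensityMaps(set, 4, p, geom,
                            scaledHeatmapConfig(48, fullPresentation = TRUE),
                            masterSeed = 14)
  for (img in Filter(function(i) i@hasFace, set@images)) {
    m <- maps[[img@imageId]][["all"]]@values
    roi <- img@faceRoi
    massRatio <- sum(m[roi]) / sum(m)
    areaRatio <- mean(roi)
    expect_gt(massRatio, areaRatio)  # far above uniform expectation
  }
})
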