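# Spotlight masks, blurring, and ratio-mixed training sets.

test_that("tertile threshold keeps and blurs the right pixels", {
  spec <- manipulationSpec("HS")
  uni <- gaussianDensityMap(16)
  uni@values[] <- 1  # uniform density at the peak
  m <- tertileMask(uni, spec)
  expect_true(all(m@binaryKeep))
  expect_equal(m@blurFraction, 0)

  v <- gaussianDensityMap(16)
  v@values[] <- 0.5; v@values[1, 1:3] <- c(0.1, 0.5, 0.9)
  v@values[2, 2] <- 1
  hs <- tertileMask(v, manipulationSpec("HS"))
  expect_equal(unname(hs@binaryKeep[1, 1:3]), c(FALSE, TRUE, TRUE))
})

test_that("HS and AS binary masks are exact complements with blur fractions summing to one", {
  d <- gaussianDensityMap(48)
  hs <- tertileMask(d, scaledManipulationSpec("HS", 48))
  as_ <- tertileMask(d, scaledManipulationSpec("AS", 48))
  expect_identical(as_@binaryKeep, !hs@binaryKeep)
  expect_equal(hs@blurFraction + as_@blurFraction, 1)
})

test_that("blur fraction equals the brute-force count below threshold", {
  d <- gaussianDensityMap(48, cx = 25, cy = 25, sd = 8)
  hs <- tertileMask(d, manipulationSpec("HS", threshold = 1 / 3))
  expect_equal(hs@blurFraction, sum(d@values < 1 / 3) / length(d@values))
})

test_that("all-zero density under HS warns and keeps nothing", {
  z <- gaussianDensityMap(16)
  z@values[] <- 0; z@normalization <- "none"
  expect_warning(m <- tertileMask(z, manipulationSpec("HS")), "degenerate")
  expect_false(any(m@binaryKeep))
  expect_equal(m@blurFraction, 1)
})

test_that("spotlight compositing honors the keep matte exactly", {
  img <- tinyStimuli()@images[[1]]
  spec <- scaledManipulationSpec("HS", 48)
  ones <- new("SpotlightMask", imageId = img@imageId, mode = "HS",
              keep = matrix(1, 48, 48), binaryKeep = matrix(TRUE, 48, 48),
              blurFraction = 0)
  expect_identical(applySpotlight(img, ones, spec)@pixels, img@pixels)

  zeros <- new("SpotlightMask", imageId = img@imageId, mode = "HS",
               keep = matrix(0, 48, 48), binaryKeep = matrix(FALSE, 48, 48),
               blurFraction = 1)
  blurred <- gaussianSmooth(img@pixels, spec@blurSd, spec@blurWindow)
  expect_equal(applySpotlight(img, zeros, spec)@pixels,
               gazeSpotlight:::.clamp(blurred, 0, 1), tolerance = 1e-12)

  # STD returns the input bit-exactly
  expect_identical(applySpotlight(img, ones, manipulationSpec("STD")), img)
})

test_that("composited pixels are bounded by the originals and the blurred image", {
  img <- tinyStimuli()@images[[2]]
  d <- gaussianDensityMap(48, imageId = img@imageId)
  spec <- scaledManipulationSpec("AS", 48)
  m <- tertileMask(d, spec)
  out <- applySpotlight(img, m, spec)@pixels
  blurred <- gaussianSmooth(img@pixels, spec@blurSd, spec@blurWindow)
  lo <- pmin(img@pixels, blurred); hi <- pmax(img@pixels, blurred)
  expect_true(all(out >= lo - 1e-12))
  expect_true(all(out <= hi + 1e-12))
})

test_that("increasing the keep matte moves output toward the original", {
  img <- tinyStimuli()@images[[3]]
  spec <- scaledManipulationSpec("HS", 48)
  d <- gaussianDensityMap(48, imageId = img@imageId)
  m <- tertileMask(d, spec)
  stronger <- m
  stronger@keep <- gazeSpotlight:::.clamp(m@keep + 0.3, 0, 1)
  dist <- function(mask) sum(abs(applySpotlight(img, mask, spec)@pixels - img@pixels))
  expect_lte(dist(stronger), dist(m))
})

test_that("ratio-mixed datasets select the right number of images per category", {
  set <- generateStimulusSet(stimulusSpec(nCategories = 2,
    nImagesPerCategory = 30, imageSize = 48, seed = 3))
  maps <- lapply(set@images, function(i) gaussianDensityMap(48, imageId = i@imageId))
  manip <- manipulateStimulusSet(set, maps, scaledManipulationSpec("HS", 48))

  ds90 <- buildTrainingSet(set, manip, "HS", 90, seed = 4)
  perCat <- tapply(!ds90@manifest$manipulated, ds90@manifest$category, sum)
  expect_equal(as.integer(perCat), c(3L, 3L))  # 3 unmanipulated per category

  ds0 <- buildTrainingSet(set, manip, "HS", 0, seed = 4)
  expect_false(any(ds0@manifest$manipulated))
  expect_identical(ds0@images, lapply(set@images, function(i) i@pixels))

  sweep <- lapply(seq(100, 0, by = -10), function(r)
    buildTrainingSet(set, manip, "HS", r, seed = 4))
  expect_length(sweep, 11L)
  expect_equal(vapply(sweep, function(d) mean(d@manifest$manipulated), numeric(1)),
               seq(1, 0, by = -0.1), tolerance = 1e-12)

  expect_error(buildTrainingSet(set, manip[-1], "HS", 100, seed = 1), "missing")
  expect_error(buildTrainingSet(set, manip, "HS", 55, seed = 1), "ratioPercent")
})
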