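# Grad-CAM saliency attribution.

# analytic channel weights vs central finite differences of the class logit
test_that("channel weights match central finite differences on a small network", {
  run <- toyRun8()
  set.seed(65)
  px <- array(runif(8 * 8 * 3), c(8, 8, 3))
  alpha <- saliencyChannelWeights(run, px, "a")

  fw <- gazeSpotlight:::.forwardActs(run@backbone, px, keepActs = TRUE)
  A <- fw$lastConv
  h <- 1e-4
  cls <- match("a", run@classes)
  fd <- vapply(seq_len(dim(A)[3]), function(k) {
    g <- 0
    for (r in seq_len(dim(A)[1])) for (cc in seq_len(dim(A)[2])) {
      Ap <- A; Ap[r, cc, k] <- A[r, cc, k] + h
      Am <- A; Am[r, cc, k] <- A[r, cc, k] - h
      g <- g + (convLogit(run, Ap, cls) - convLogit(run, Am, cls)) / (2 * h)
    }
    g / (dim(A)[1] * dim(A)[2])
  }, numeric(1))
  expect_lt(max(abs(alpha - fd)) / max(abs(fd)), 1e-3)
})

test_that("a single-channel network reduces to its rectified activation map", {
  # hand-built backbone: one 3x3 conv channel, global average pooling,
  # identity fc, identity head
  idx <- gazeSpotlight:::.im2colIdx(8L, 3L, 3L)
  conv <- list(type = "conv", name = "conv1", k = 3L, cin = 3L, cout = 1L,
               H = 8L, W = matrix(rnorm(27), 27, 1), b = 0, idx = idx,
               pool = FALSE)
  fc <- list(type = "fc", name = "fc1", W = matrix(1, 1, 1), b = 0)
  bb <- new("CNNBackbone", architecture = "small", inputSize = 8L,
            nClasses = 1L, seed = 1L, layers = list(conv, fc),
            featureDim = 1L, lastConvShape = c(8L, 8L, 1L), globalPool = TRUE)
  run <- new("ModelRun", runId = "toy", mode = "STD", ratioPercent = 0,
             seed = 1L, backbone = bb, headW = matrix(1, 1, 1), headB = 0,
             featMean = 0, featSd = 1,
             splitManifest = data.frame(), history = data.frame(),
             classes = "c1", evaluation = list())
  set.seed(2)
  px <- array(runif(8 * 8 * 3), c(8, 8, 3))
  sm <- gradcam(run, px, "c1")
  A <- gazeSpotlight:::.forwardActs(bb, px, keepActs = TRUE)$lastConv[, , 1]
  expect_equal(sm@values, A / max(A), tolerance = 1e-12)
})

test_that("degenerate maps normalize as specified", {
  idx <- gazeSpotlight:::.im2colIdx(8L, 3L, 3L)
  mkRun <- function(W, b) {
    conv <- list(type = "conv", name = "conv1", k = 3L, cin = 3L, cout = 1L,
                 H = 8L, W = W, b = b, idx = idx, pool = FALSE)
    fc <- list(type = "fc", name = "fc1", W = matrix(1, 1, 1), b = 0)
    bb <- new("CNNBackbone", architecture = "small", inputSize = 8L,
              nClasses = 1L, seed = 1L, layers = list(conv, fc),
              featureDim = 1L, lastConvShape = c(8L, 8L, 1L), globalPool = TRUE)
    new("ModelRun", runId = "toy", mode = "STD", ratioPercent = 0, seed = 1L,
        backbone = bb, headW = matrix(1, 1, 1), headB = 0, featMean = 0,
        featSd = 1, splitManifest = data.frame(), history = data.frame(),
        classes = "c1", evaluation = list())
  }
  px <- array(0.5, c(8, 8, 3))
  # constant positive activations -> all-ones map
  smPos <- gradcam(mkRun(matrix(0, 27, 1), b = 1), px, "c1")
  expect_false(smPos@flagged)
  expect_equal(smPos@values, matrix(1, 8, 8))
  # identically-zero activations -> all-zero map, flagged (not an error)
  smZero <- gradcam(mkRun(matrix(0, 27, 1), b = 0), px, "c1")
  expect_true(smZero@flagged)
  expect_equal(smZero@values, matrix(0, 8, 8))
})

test_that("saliency maps are valid, normalized and computed for the true class", {
  test <- generateStimulusSet(stimulusSpec(nCategories = 4,
    nImagesPerCategory = 2, imageSize = 64, seed = 911), idPrefix = "te_")
  run <- smallRun()
  for (img in test@images[1:4]) {
    sm <- gradcam(run, img)
    expect_true(validObject(sm))
    expect_equal(sm@targetClass, img@category)
    expect_equal(dim(sm@values), c(64L, 64L))
    expect_gte(min(sm@values), 0)
    expect_equal(max(sm@values), 1)
  }
})

test_that("occluding the top-saliency region hurts the class score more than random occlusion", {
  set <- smallStimuli()
  run <- smallRun()
  set.seed(77)
  dropsSal <- c(); dropsRnd <- c()
  for (img in set@images[seq(1, 40, by = 4)]) {
    sm <- gradcam(run, img)
    cls <- match(img@category, run@classes)
    logit0 <- convLogit(run,
      gazeSpotlight:::.forwardActs(run@backbone, img@pixels, keepActs = TRUE)$lastConv, cls)
    occlude <- function(mask) {
      px <- img@pixels
      for (ch in 1:3) {
        plane <- px[, , ch]; plane[mask] <- mean(plane); px[, , ch] <- plane
      }
      convLogit(run,
        gazeSpotlight:::.forwardActs(run@backbone, px, keepActs = TRUE)$lastConv, cls)
    }
    thr <- quantile(sm@values, 0.9)
    topMask <- sm@values >= thr
    rndMask <- matrix(FALSE, 64, 64)
    rndMask[sample(64 * 64, sum(topMask))] <- TRUE
    dropsSal <- c(dropsSal, logit0 - occlude(topMask))
    dropsRnd <- c(dropsRnd, logit0 - occlude(rndMask))
  }
  expect_gt(mean(dropsSal), mean(dropsRnd))
})
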