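# Similarity, face index, grouped bootstrap summaries, trade-off table.

test_that("pearsonFisher handles identity, anti-correlation, and hand-computed cases", {
  set.seed(1)
  m <- matrix(runif(64), 8, 8)
  self <- pearsonFisher(m, m)
  expect_equal(self$r, 1)
  expect_equal(self$z, atanh(1 - 1e-7))
  anti <- pearsonFisher(m, 1 - m)
  expect_equal(anti$r, -1)
  expect_equal(anti$z, atanh(-(1 - 1e-7)))

  a <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  b <- matrix(c(2, 1, 4, 3, 6, 5, 8, 7, 9), 3, 3)
  av <- as.numeric(a); bv <- as.numeric(b)
  rHand <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  pf <- pearsonFisher(a, b)
  expect_equal(pf$r, rHand, tolerance = 1e-12)
  expect_equal(pf$z, atanh(rHand), tolerance = 1e-12)

  expect_error(pearsonFisher(matrix(1, 3, 3), m[1:3, 1:3]),
               class = "gazeSpotlight_zero_variance")
  expect_error(pearsonFisher(m, m[1:4, 1:4]), "shape")
})

test_that("Fisher transform is monotone and r is invariant to positive affine rescaling", {
  set.seed(2)
  rs <- sort(runif(20, -0.99, 0.99))
  zs <- atanh(rs)
  expect_identical(order(rs), order(zs))
  for (i in 1:10) {
    a <- matrix(runif(36), 6, 6); b <- matrix(runif(36), 6, 6)
    r0 <- pearsonFisher(a, b)$r
    r1 <- pearsonFisher(2.7 * a + 0.3, b)$r
    r2 <- pearsonFisher(a, 0.01 * b + 5)$r
    expect_equal(r1, r0, tolerance = 1e-12)
    expect_equal(r2, r0, tolerance = 1e-12)
  }
})

# build a miniature record set: 3 runs x 4 images x (2 windows + all)
.makeSimFixture <- function() {
  set.seed(33)
  imgIds <- paste0("im", 1:4)
  manifest <- data.frame(image_id = imgIds,
                         category = c("dog", "dog", "car", "car"),
                         animate = c(TRUE, TRUE, FALSE, FALSE),
                         has_face = c(TRUE, TRUE, FALSE, FALSE))
  human <- lapply(imgIds, function(id) {
    ms <- lapply(c("all", "0", "1"), function(k)
      new("FixationDensityMap", imageId = id, windowIndex = k,
          windowOnsetMs = 0, windowOffsetMs = 50,
          values = { v <- matrix(runif(64), 8, 8); v / max(v) },
          normalization = "peak"))
    names(ms) <- c("all", "0", "1")
    ms
  })
  names(human) <- imgIds
  bb <- new("CNNBackbone", architecture = "small", inputSize = 8L,
            nClasses = 2L, seed = 1L, layers = list(), featureDim = 1L,
            lastConvShape = c(1L, 1L, 1L), globalPool = TRUE)
  runs <- lapply(1:3, function(i)
    new("ModelRun", runId = paste0("r", i), mode = "STD", ratioPercent = 0,
        seed = i, backbone = bb, headW = matrix(0, 1, 1), headB = 0,
        featMean = 0, featSd = 1, splitManifest = data.frame(),
        history = data.frame(), classes = c("dog", "car"),
        evaluation = list()))
  names(runs) <- paste0("r", 1:3)
  sal <- lapply(runs, function(r) {
    ms <- lapply(imgIds, function(id) {
      v <- matrix(runif(64), 8, 8); v <- v / max(v)
      new("SaliencyMap", imageId = id, runId = r@runId, targetClass = "dog",
          values = v, sourceLayer = "conv1", flagged = FALSE)
    })
    names(ms) <- imgIds
    ms
  })
  list(runs = runs, sal = sal, human = human, manifest = manifest)
}

test_that("similarity tables have the expected cardinality and brute-force values", {
  fx <- .makeSimFixture()
  tab <- similarityTable(fx$runs, fx$sal, fx$human, fx$manifest,
                         windows = c("0", "1"))
  expect_equal(nrow(tab), 3 * 4 * 3)  # runs x images x (2 windows + all)
  # every record equals a direct pearsonFisher computation
  for (i in sample(nrow(tab), 8)) {
    rec <- tab[i, ]
    direct <- pearsonFisher(fx$sal[[rec$run_id]][[rec$image_id]],
                            fx$human[[rec$image_id]][[rec$window]])
    expect_equal(rec$r, direct$r, tolerance = 1e-12)
    expect_equal(rec$z, direct$z, tolerance = 1e-12)
  }
  # identical saliency across runs gives identical records modulo run id
  sal2 <- fx$sal
  sal2[["r2"]] <- sal2[["r1"]]
  tab2 <- similarityTable(fx$runs[1:2], sal2[1:2], fx$human, fx$manifest,
                          windows = c("0", "1"))
  a <- tab2[tab2$run_id == "r1", setdiff(names(tab2), "run_id")]
  b <- tab2[tab2$run_id == "r2", setdiff(names(tab2), "run_id")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("degenerate maps are skipped with a reason, not recorded as zero", {
  fx <- .makeSimFixture()
  fx$sal[["r1"]][["im1"]]@values <- matrix(0, 8, 8)
  fx$sal[["r1"]][["im1"]]@flagged <- TRUE
  tab <- similarityTable(fx$runs, fx$sal, fx$human, fx$manifest,
                         windows = c("0", "1"))
  expect_equal(nrow(tab), 3 * 4 * 3 - 3)
  skipped <- attr(tab, "skipped")
  expect_true(any(skipped$image_id == "im1" &
                  skipped$reason == "zero-variance saliency map"))
})

test_that("face-detection index matches area ratios, caps, and brute force", {
  roi <- matrix(FALSE, 8, 8); roi[1:4, 1:4] <- TRUE  # 25% of pixels
  uni <- matrix(1, 8, 8)
  expect_equal(as.numeric(faceDetectionIndex(uni, roi)), 1 / 3)

  inside <- matrix(0, 8, 8); inside[2, 2] <- 5
  idx <- faceDetectionIndex(inside, roi)
  expect_true(attr(idx, "capped"))
  expect_gt(as.numeric(idx), 1e6)

  set.seed(4)
  m <- matrix(runif(64), 8, 8)
  expect_equal(as.numeric(faceDetectionIndex(m, roi)),
               sum(m[roi]) / sum(m[!roi]), tolerance = 1e-12)
  expect_error(faceDetectionIndex(m, matrix(FALSE, 8, 8)), "excluded")
})

test_that("group summaries have degenerate and disjoint-cell behavior", {
  rec <- data.frame(mode = rep(c("STD", "AS"), each = 6),
                    image_id = rep(paste0("i", 1:6), 2),
                    z = c(rep(0.5, 6), rep(0.1, 6)))
  gs <- groupSummary(rec, "none", B = 200, seed = 1)
  std <- gs[gs$mode == "STD", ]
  expect_equal(std$mean, 0.5)
  expect_equal(std$median, 0.5)
  expect_equal(std$ci_lo, 0.5)  # identical values: zero-width CI
  expect_equal(std$ci_hi, 0.5)
  as_ <- gs[gs$mode == "AS", ]
  expect_lt(as_$ci_hi, std$ci_lo)  # disjoint ranges: non-overlapping CIs

  set.seed(9)
  rec2 <- data.frame(mode = "STD", image_id = paste0("i", 1:40),
                     z = rnorm(40, 0.3, 0.2))
  gs2 <- groupSummary(rec2, "none", B = 2000, seed = 5)
  # independent percentile bootstrap implementation
  x <- rec2$z
  set.seed(1515)
  bootMeans <- replicate(2000, mean(sample(x, replace = TRUE)))
  ci <- quantile(bootMeans, c(0.025, 0.975), names = FALSE)
  expect_equal(gs2$ci_lo, ci[1], tolerance = 0.02)
  expect_equal(gs2$ci_hi, ci[2], tolerance = 0.02)
  expect_true(gs2$ci_lo < gs2$mean && gs2$mean < gs2$ci_hi)
})

test_that("trade-off curves emit one bracketing point per mode-ratio cell", {
  set.seed(6)
  rs <- expand.grid(mode = "AS", ratio_percent = seq(0, 100, 10),
                    rep = 1:5, stringsAsFactors = FALSE)
  rs$run_id <- paste0(rs$ratio_percent, "-", rs$rep)
  rs$accuracy <- 80 - 0.1 * rs$ratio_percent + rnorm(nrow(rs), 0, 1)
  rs$mean_z <- 0.5 - 0.002 * rs$ratio_percent + rnorm(nrow(rs), 0, 0.02)
  curve <- tradeoffCurve(rs, B = 500, seed = 2)
  expect_equal(nrow(curve), 11L)
  expect_equal(curve$ratio_percent, seq(0, 100, 10))
  expect_true(all(curve$accuracy_lo <= curve$accuracy &
                  curve$accuracy <= curve$accuracy_hi))
  expect_true(all(curve$mean_z_lo <= curve$mean_z &
                  curve$mean_z <= curve$mean_z_hi))
})

test_that("ROI preparation averages raters, smooths, and binarizes", {
  a <- matrix(FALSE, 20, 20); a[5:12, 5:12] <- TRUE
  b <- matrix(FALSE, 20, 20); b[6:13, 6:13] <- TRUE
  roi <- prepareRoi(list(a, b))
  expect_equal(max(roi$weights), 1)
  expect_true(all(roi$weights >= 0))
  # interior of the agreed region survives binarization, far corners do not
  expect_true(roi$mask[9, 9])
  expect_false(roi$mask[1, 20])
  # a single exact mask keeps its interior after smoothing
  one <- prepareRoi(a)
  expect_true(one$mask[8, 8])
})
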