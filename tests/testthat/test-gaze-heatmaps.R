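# Fixation-density heatmap pipeline.

test_that("in-image selection maps the origin to (0,0) and excludes the far edge", {
  geom <- displayGeometry(227)  # displayed at 454 px
  ox <- geom@imageOrigin[1]; oy <- geom@imageOrigin[2]
  s <- data.frame(t_ms = c(0, 1), x_px = c(ox, ox + 454), y_px = c(oy, oy + 454))
  out <- selectInImage(s, geom)
  expect_equal(nrow(out), 1L)  # half-open bound excludes origin + 454
  expect_equal(out$x_img, 0L)
  expect_equal(out$y_img, 0L)
})

test_that("in-image selection equals a brute-force rectangle test", {
  geom <- displayGeometry(64)
  set.seed(42)
  s <- data.frame(t_ms = seq_len(1000),
                  x_px = runif(1000, 0, 1920), y_px = runif(1000, 0, 1080))
  out <- selectInImage(s, geom)
  ox <- geom@imageOrigin[1]; oy <- geom@imageOrigin[2]; d <- 128
  keep <- s$x_px >= ox & s$x_px < ox + d & s$y_px >= oy & s$y_px < oy + d
  expect_equal(out$t_ms, s$t_ms[keep])
  expect_equal(out$x_img, as.integer(floor((s$x_px[keep] - ox) / 2)))
  expect_equal(out$y_img, as.integer(floor((s$y_px[keep] - oy) / 2)))
})

test_that("windowing yields exactly horizon/window groups with brute-force membership", {
  cfg <- heatmapConfig()  # 50 ms windows over 1000 ms
  set.seed(7)
  s <- data.frame(t_ms = sort(c(runif(300, 0, 1400), seq(0, 1000, by = 50))))
  s$t_ms <- s$t_ms  # includes exact boundary values
  groups <- windowSamples(s, cfg)
  expect_length(groups, 20L)
  for (k in seq_along(groups) - 1L) {
    expect_equal(groups[[as.character(k)]]$t_ms,
                 s$t_ms[s$t_ms >= k * 50 & s$t_ms < (k + 1) * 50])
  }
  expect_length(windowSamples(s, heatmapConfig(horizonMs = 50)), 1L)
  expect_error(windowSamples(s, new("HeatmapConfig", windowMs = 30,
                                    horizonMs = 1000, smoothingSdPx = 20,
                                    cumulative = FALSE,
                                    fullPresentation = FALSE)),
               "multiple")
})

test_that("density accumulation equals a brute-force tally and rejects bad coords", {
  expect_equal(accumulateDensity(data.frame(x_img = integer(), y_img = integer()), 8),
               matrix(0L, 8, 8))
  g <- data.frame(x_img = c(3L, 3L, 3L), y_img = c(5L, 5L, 5L))
  m <- accumulateDensity(g, 8)
  expect_equal(m[6, 4], 3L)
  expect_equal(sum(m), 3L)
  set.seed(9)
  g2 <- data.frame(x_img = sample(0:15, 200, TRUE), y_img = sample(0:15, 200, TRUE))
  m2 <- accumulateDensity(g2, 16)
  brute <- matrix(0L, 16, 16)
  for (i in seq_len(200)) {
    brute[g2$y_img[i] + 1, g2$x_img[i] + 1] <-
      brute[g2$y_img[i] + 1, g2$x_img[i] + 1] + 1L
  }
  expect_equal(m2, brute)
  expect_error(accumulateDensity(data.frame(x_img = 16L, y_img = 0L), 16),
               "out of range")
})

test_that("smoothing conserves mass, normalizes to peak 1 and keeps zeros zero", {
  cfg <- heatmapConfig(smoothingSdPx = 3)
  z <- smoothAndNormalize(matrix(0, 32, 32), cfg)
  expect_equal(z@values, matrix(0, 32, 32))
  expect_equal(z@normalization, "none")

  # impulse response: truncated Gaussian with max 1 at the impulse
  raw <- matrix(0, 33, 33); raw[17, 17] <- 1
  m <- smoothAndNormalize(raw, cfg)
  expect_equal(m@normalization, "peak")
  expect_equal(which(m@values == 1, arr.ind = TRUE)[1, ], c(row = 17, col = 17))
  k <- gazeSpotlight:::gaussianKernel1D(3)
  expected <- outer(k, k); expected <- expected / max(expected)
  half <- (length(k) - 1) / 2
  expect_equal(m@values[17 + (-half:half), 17 + (-half:half)], expected,
               tolerance = 1e-10, ignore_attr = TRUE)

  # mass conservation before normalization (reflective borders)
  set.seed(3)
  raw2 <- matrix(rpois(32 * 32, 0.5), 32, 32)
  sm <- gaussianSmooth(raw2 + 0, 5)
  expect_lt(abs(sum(sm) - sum(raw2)) / sum(raw2), 1e-6)
})

test_that("participant averaging matches brute force and is idempotent for one map", {
  cfg <- heatmapConfig(smoothingSdPx = 2)
  set.seed(5)
  mk <- function() smoothAndNormalize(matrix(rpois(256, 0.3), 16, 16), cfg,
                                      imageId = "img", windowIndex = "3",
                                      onsetMs = 150, offsetMs = 200)
  maps <- replicate(5, mk(), simplify = FALSE)
  avg <- averageParticipants(maps)
  brute <- Reduce(`+`, lapply(maps, mapValues)) / 5
  brute <- brute / max(brute)
  expect_equal(mapValues(avg), brute, tolerance = 1e-12)
  expect_equal(mapValues(averageParticipants(maps[1])), mapValues(maps[[1]]))
  expect_equal(mapValues(averageParticipants(maps[c(1, 1)])), mapValues(maps[[1]]))
  m2 <- maps[[2]]
  m2@imageId <- "other"
  expect_error(averageParticipants(list(maps[[1]], m2)), "same image")
})

test_that("peak normalization is idempotent", {
  set.seed(8)
  cfg <- heatmapConfig(smoothingSdPx = 2)
  m <- smoothAndNormalize(matrix(rpois(256, 1), 16, 16), cfg)
  twice <- m@values / max(m@values)
  expect_identical(twice, m@values)
})

test_that("streamed per-window cohort maps equal the public per-window operations", {
  set <- tinyStimuli()
  img <- set@images[[2]]
  geom <- displayGeometry(48)
  p <- gazeModelParams()
  cfg <- scaledHeatmapConfig(48)
  seed <- 33
  maps <- cohortDensityMaps(set, 2, p, geom, cfg, masterSeed = seed)
  pts <- simulateCohortManifest(2, p, seed)
  perP <- lapply(seq_len(2), function(pi) {
    tr <- gazeSpotlight:::.simulateTrialFromManifest(img, pts[pi, ], geom, p, seed)
    loc <- selectInImage(data.frame(t_ms = tr$t_ms, x_px = tr$x_px,
                                    y_px = tr$y_px), geom)
    groups <- windowSamples(loc, cfg)
    lapply(groups, function(g)
      smoothAndNormalize(accumulateDensity(g, 48), cfg, imageId = img@imageId))
  })
  for (k in as.character(0:19)) {
    pub <- averageParticipants(lapply(perP, function(x) x[[k]]))
    expect_equal(maps[[img@imageId]][[k]]@values, pub@values, tolerance = 1e-12)
  }
})
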