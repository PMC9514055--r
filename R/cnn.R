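# Native CNN machinery: seeded backbone construction, im2col forward pass,
# head-only SGDM fine-tuning (transfer-learning discipline: every backbone
# layer frozen, the classification head replaced and trained), evaluation,
# and repeated seeded runs.

# im2col gather-index matrix for a k x k "same" convolution on an
# H x H x C input with zero padding p = (k-1)/2. Column order (dr, dc, ch)
# matches the column-major flattening of a (k, k, cin, cout) weight array.
.im2colIdx <- function(H, C, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  rr <- rep(seq_len(H), H)
  cc <- rep(seq_len(H), each = H)
  idx <- matrix(0L, H * H, k * k * C)
  j <- 0L
  for (ch in 0:(C - 1L)) {
    for (dc in 0:(k - 1L)) {
      for (dr in 0:(k - 1L)) {
        j <- j + 1L
        idx[, j] <- ch * Hp * Hp + (cc + dc - 1L) * Hp + (rr + dr)
      }
    }
  }
  attr(idx, "Hp") <- Hp
  attr(idx, "p") <- p
  idx
}

.maxPool2 <- function(a) {
  H <- dim(a)[1L]
  o <- seq(1L, H, 2L); e <- seq(2L, H, 2L)
  pmax(a[o, o, , drop = FALSE], a[e, o, , drop = FALSE],
       a[o, e, , drop = FALSE], a[e, e, , drop = FALSE])
}

# architecture presets: conv = (kernel, channels, pool-after?), fc widths.
# "small" ends in global average pooling before its fully connected stage,
# so class evidence reaching the head stays tied to last-conv channels (the
# layout Grad-CAM attributes most faithfully); "alexnet-like" flattens.
.architectures <- list(
  "small" = list(conv = list(c(5, 12, 1), c(5, 24, 1), c(3, 64, 0)), fc = 128,
                 globalPool = TRUE),
  "alexnet-like" = list(conv = list(c(5, 16, 1), c(5, 16, 1), c(3, 32, 0),
                                    c(3, 32, 0), c(3, 32, 1)),
                        fc = c(256, 128), globalPool = FALSE))

#' Build a seeded convolutional backbone
#'
#' Constructs a frozen feature extractor with He-initialized weights drawn
#' from the given seed. "small" is 3 conv + 2 fully connected layers (the
#' second being the classification head added at fine-tuning time);
#' "alexnet-like" is 5 conv + 3 fully connected. The last convolutional
#' layer is identifiable by name for Grad-CAM.
#'
#' @param architecture "small" or "alexnet-like".
#' @param inputSize input side length in px; must be a multiple of 8.
#' @param nClasses number of classes the replaced head will output.
#' @param seed init seed.
#' @return A [CNNBackbone-class].
#' @export
buildBackbone <- function(architecture = c("small", "alexnet-like"),
                          inputSize, nClasses, seed = 1L) {
  architecture <- match.arg(architecture)
  inputSize <- as.integer(inputSize)
  if (inputSize %% 8L != 0L) stop("inputSize must be a multiple of 8")
  arch <- .architectures[[architecture]]
  withSeed(deriveSeed(seed, "backboneInit"), {
    layers <- list()
    H <- inputSize; C <- 3L
    ci <- 0L
    for (cv in arch$conv) {
      k <- cv[1L]; cout <- cv[2L]; pool <- cv[3L] == 1
      ci <- ci + 1L
      fanIn <- k * k * C
      W <- matrix(stats::rnorm(fanIn * cout, 0, sqrt(2 / fanIn)), fanIn, cout)
      # zero-mean filters: units respond to local structure (edges, texture,
      # color opponency) rather than absolute luminance, so activation maps
      # localize on image content instead of flat background
      W <- W - rep(colMeans(W), each = fanIn)
      layers[[length(layers) + 1L]] <- list(
        type = "conv", name = sprintf("conv%d", ci), k = k, cin = C,
        cout = cout, H = H, W = W, b = numeric(cout),
        idx = .im2colIdx(H, C, k), pool = pool)
      C <- cout
      if (pool) H <- H %/% 2L
    }
    lastConvShape <- {
      lc <- layers[[length(layers)]]
      c(lc$H, lc$H, lc$cout)
    }
    fin <- if (isTRUE(arch$globalPool)) C else H * H * C
    fi <- 0L
    for (width in arch$fc) {
      fi <- fi + 1L
      W <- matrix(stats::rnorm(width * fin, 0, sqrt(2 / fin)), width, fin)
      # small positive bias keeps frozen random ReLU units alive
      layers[[length(layers) + 1L]] <- list(
        type = "fc", name = sprintf("fc%d", fi), W = W,
        b = rep(0.1, width))
      fin <- width
    }
    new("CNNBackbone", architecture = architecture, inputSize = inputSize,
        nClasses = as.integer(nClasses), seed = as.integer(seed),
        layers = layers, featureDim = as.integer(fin),
        lastConvShape = as.integer(lastConvShape),
        globalPool = isTRUE(arch$globalPool))
  })
}

# full forward pass through the frozen backbone; returns the feature vector
# and, optionally, the activations Grad-CAM needs (last conv output
# post-ReLU pre-pool, and post-ReLU outputs of every frozen fc layer)
.forwardActs <- function(backbone, px, keepActs = FALSE) {
  x <- px
  lastConv <- NULL
  convLayers <- Filter(function(l) l$type == "conv", backbone@layers)
  nConv <- length(convLayers)
  ci <- 0L
  for (layer in backbone@layers) {
    if (layer$type == "conv") {
      ci <- ci + 1L
      Hp <- attr(layer$idx, "Hp"); p <- attr(layer$idx, "p")
      H <- layer$H
      xp <- array(0, c(Hp, Hp, layer$cin))
      xp[p + seq_len(H), p + seq_len(H), ] <- x
      A <- matrix(xp[layer$idx], nrow = H * H) %*% layer$W
      A <- A + rep(layer$b, each = H * H)
      A[A < 0] <- 0
      arr <- array(A, c(H, H, layer$cout))
      if (ci == nConv) lastConv <- arr
      x <- if (layer$pool) .maxPool2(arr) else arr
    } else {
      if (is.array(x)) {
        x <- if (backbone@globalPool) apply(x, 3L, mean) else as.vector(x)
      }
      x <- pmax(layer$W %*% x + layer$b, 0)
    }
  }
  features <- as.numeric(x)
  if (keepActs) {
    # recompute fc chain activations for the backward pass
    fcActs <- list()
    convOut <- lastConv
    lastLayer <- convLayers[[nConv]]
    pooled <- if (lastLayer$pool) .maxPool2(convOut) else convOut
    v <- if (backbone@globalPool) apply(pooled, 3L, mean) else as.vector(pooled)
    for (layer in backbone@layers) {
      if (layer$type == "fc") {
        v <- pmax(layer$W %*% v + layer$b, 0)
        fcActs[[length(fcActs) + 1L]] <- as.numeric(v)
      }
    }
    list(features = features, lastConv = lastConv,
         lastConvName = lastLayer$name, lastPool = lastLayer$pool,
         fcActs = fcActs)
  } else {
    list(features = features)
  }
}

#' Frozen-backbone features for a set of images
#'
#' Runs the forward pass once per image and returns the penultimate-layer
#' feature matrix (and optionally the last-conv activations Grad-CAM
#' needs). Because the backbone is frozen during fine-tuning, these can be
#' cached and reused across runs and ratio datasets.
#'
#' @param backbone a [CNNBackbone-class].
#' @param images named list of H x W x 3 pixel arrays, or a
#'   [StimulusSet-class] / [TrainingSet-class].
#' @param keepConv also return the per-image last-conv activations (memory
#'   scales with image count).
#' @return list with `features` (n x featureDim matrix, rownames = image
#'   ids) and, if requested, `acts` (named list of forward records).
#' @export
convFeatures <- function(backbone, images, keepConv = FALSE) {
  if (is(images, "StimulusSet")) {
    images <- lapply(images@images, function(im) im@pixels)
  } else if (is(images, "TrainingSet")) {
    images <- images@images
  }
  n <- length(images)
  feats <- matrix(0, n, backbone@featureDim)
  rownames(feats) <- names(images)
  acts <- if (keepConv) vector("list", n) else NULL
  if (keepConv) names(acts) <- names(images)
  for (i in seq_len(n)) {
    fw <- .forwardActs(backbone, images[[i]], keepActs = keepConv)
    feats[i, ] <- fw$features
    if (keepConv) acts[[i]] <- fw
  }
  list(features = feats, acts = acts)
}

.softmaxLoss <- function(W, b, Phi, yIdx) {
  # Phi: d x m, yIdx: integer class per column
  Z <- W %*% Phi + b
  Z <- sweep(Z, 2L, apply(Z, 2L, max))
  E <- exp(Z)
  P <- sweep(E, 2L, colSums(E), "/")
  m <- ncol(Phi)
  loss <- -mean(log(pmax(P[cbind(yIdx, seq_len(m))], 1e-300)))
  list(loss = loss, P = P)
}

#' Fine-tune a classification head on a frozen backbone
#'
#' Implements the transfer-learning recipe: every backbone layer is frozen,
#' a fresh softmax classification head is attached and trained with SGDM
#' (momentum 0.9), mini-batch 42, learning rate 1e-4 times a head factor of
#' 20, for at most 30 epochs with early stopping once validation loss fails
#' to improve for 5 consecutive epochs; the best-validation weights are
#' kept. The validation split is stratified by category. Features are
#' standardized with training-split statistics before the head (standard
#' practice when training a linear probe on fixed features; the
#' standardization is part of the trained model and is undone nowhere).
#' No data augmentation is applied.
#'
#' @param backbone a [CNNBackbone-class] (never modified).
#' @param trainSet a [TrainingSet-class].
#' @param config a [TrainingConfig-class]; its seed drives head init and
#'   the train/validation shuffle.
#' @param features optional precomputed feature matrix from
#'   [convFeatures()] (rows matching the training-set image ids); computed
#'   on the fly otherwise.
#' @return A [ModelRun-class].
#' @export
fineTune <- function(backbone, trainSet, config, features = NULL) {
  validObject(config)
  mf <- trainSet@manifest
  classes <- sort(unique(mf$category))
  if (length(classes) != backbone@nClasses)
    stop(sprintf("dataset has %d classes but backbone head expects %d",
                 length(classes), backbone@nClasses))
  if (is.null(features)) {
    features <- convFeatures(backbone, trainSet)$features
  }
  features <- features[mf$image_id, , drop = FALSE]
  yIdx <- match(mf$category, classes)

  # stratified train/validation split
  role <- rep("train", nrow(mf))
  withSeed(deriveSeed(config@seed, "split"), {
    for (cl in classes) {
      ids <- which(mf$category == cl)
      nVal <- max(1L, round(config@valFraction * length(ids)))
      if (nVal >= length(ids))
        stop(sprintf("class '%s' would have no training examples", cl))
      role[sample(ids, nVal)] <- "val"
    }
  })
  tr <- which(role == "train"); va <- which(role == "val")
  if (length(setdiff(seq_along(classes), unique(yIdx[tr]))))
    stop("a class is absent from the training split")

  mu <- colMeans(features[tr, , drop = FALSE])
  sdv <- pmax(apply(features[tr, , drop = FALSE], 2L, stats::sd), 1e-6)
  Phi <- t((features - rep(mu, each = nrow(features))) /
             rep(sdv, each = nrow(features)))  # d x n

  d <- backbone@featureDim; K <- length(classes)
  W <- withSeed(deriveSeed(config@seed, "headInit"),
                matrix(stats::rnorm(K * d, 0, sqrt(2 / (d + K))), K, d))
  b <- numeric(K)
  lr <- config@learnRate * config@headLrFactor

  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric(), valAcc = numeric())
  bestW <- W; bestB <- b; bestVal <- Inf; badEpochs <- 0L
  if (config@maxEpochs > 0L) {
    vW <- matrix(0, K, d); vb <- numeric(K)
    withSeed(deriveSeed(config@seed, "sgd"), {
      for (epoch in seq_len(config@maxEpochs)) {
        ord <- sample(tr)
        epochLoss <- 0; nb <- 0L
        for (start in seq(1L, length(ord), by = config@batchSize)) {
          bi <- ord[start:min(start + config@batchSize - 1L, length(ord))]
          m <- length(bi)
          sl <- .softmaxLoss(W, b, Phi[, bi, drop = FALSE], yIdx[bi])
          Ymat <- matrix(0, K, m); Ymat[cbind(yIdx[bi], seq_len(m))] <- 1
          G <- (sl$P - Ymat) / m
          gW <- G %*% t(Phi[, bi, drop = FALSE])
          gb <- rowSums(G)
          vW <- config@momentum * vW - lr * gW
          vb <- config@momentum * vb - lr * gb
          W <- W + vW; b <- b + vb
          epochLoss <- epochLoss + sl$loss; nb <- nb + 1L
        }
        vl <- .softmaxLoss(W, b, Phi[, va, drop = FALSE], yIdx[va])
        if (!is.finite(vl$loss) || !is.finite(epochLoss))
          stop(sprintf("non-finite loss at epoch %d (train %.4g, val %.4g); check feature scale",
                       epoch, epochLoss / max(nb, 1L), vl$loss))
        valAcc <- mean(apply(vl$P, 2L, which.max) == yIdx[va]) * 100
        history[nrow(history) + 1L, ] <- list(epoch, epochLoss / nb, vl$loss, valAcc)
        if (vl$loss < bestVal - 1e-9) {
          bestVal <- vl$loss; bestW <- W; bestB <- b; badEpochs <- 0L
        } else {
          badEpochs <- badEpochs + 1L
          if (badEpochs >= config@validationPatience) break
        }
      }
    })
  }

  split <- data.frame(image_id = mf$image_id, category = mf$category,
                      role = role, manipulated = mf$manipulated,
                      stringsAsFactors = FALSE)
  new("ModelRun",
      runId = sprintf("%s-%03d-s%d", trainSet@mode, trainSet@ratioPercent,
                      config@seed),
      mode = trainSet@mode, ratioPercent = trainSet@ratioPercent,
      seed = config@seed, backbone = backbone, headW = bestW, headB = bestB,
      featMean = mu, featSd = sdv, splitManifest = split, history = history,
      classes = classes, evaluation = list())
}

# logits of a run for a feature matrix (n x d)
.runLogits <- function(run, features) {
  Phi <- t((features - rep(run@featMean, each = nrow(features))) /
             rep(run@featSd, each = nrow(features)))
  Z <- run@headW %*% Phi + run@headB
  dimnames(Z) <- list(run@classes, rownames(features))
  Z
}

#' Evaluate a fine-tuned run on a held-out test set
#'
#' Computes top-1 accuracy overall, per category and per animacy/face
#' split, the confusion matrix (rows = true category, columns = predicted;
#' rows sum to per-category test counts) and per-image correctness for the
#' joint analysis with similarity. Test images must be unseen during
#' training (checked at manifest level).
#'
#' @param run a [ModelRun-class].
#' @param testSet a [StimulusSet-class].
#' @param features optional precomputed features of the test images.
#' @return The run with its `evaluation` slot filled.
#' @export
evaluateAccuracy <- function(run, testSet, features = NULL) {
  mf <- testSet@manifest
  if (length(intersect(mf$image_id, run@splitManifest$image_id)))
    stop("test set overlaps the training manifest")
  if (length(setdiff(unique(mf$category), run@classes)))
    stop("unknown label in test manifest")
  if (is.null(features)) features <- convFeatures(run@backbone, testSet)$features
  features <- features[mf$image_id, , drop = FALSE]
  Z <- .runLogits(run, features)
  pred <- run@classes[apply(Z, 2L, which.max)]
  correct <- pred == mf$category
  perImage <- data.frame(image_id = mf$image_id, category = mf$category,
                         animate = mf$animate, has_face = mf$has_face,
                         predicted = pred, correct = correct,
                         stringsAsFactors = FALSE)
  acc <- function(sel) if (any(sel)) 100 * mean(correct[sel]) else NA_real_
  perCategory <- data.frame(
    category = run@classes,
    accuracy = vapply(run@classes, function(cl) acc(mf$category == cl), numeric(1)),
    n = vapply(run@classes, function(cl) sum(mf$category == cl), numeric(1)))
  bySplit <- data.frame(
    split = c("animate", "inanimate", "face", "non-face"),
    accuracy = c(acc(mf$animate), acc(!mf$animate), acc(mf$has_face), acc(!mf$has_face)))
  confusion <- table(factor(mf$category, levels = run@classes),
                     factor(pred, levels = run@classes))
  run@evaluation <- list(overall = 100 * mean(correct),
                         perCategory = perCategory, bySplit = bySplit,
                         confusion = unclass(confusion), perImage = perImage)
  run
}

#' Repeat fine-tuning across seeded runs
#'
#' Each run receives a distinct derived seed controlling head
#' initialization, the train/validation shuffle and the dataset draw, then
#' is optionally evaluated on the test set. Mirrors the repeated-runs
#' estimation strategy (23 runs for the main comparison, 10 per ratio in
#' the trade-off sweep).
#'
#' @param backbone a [CNNBackbone-class].
#' @param datasetBuilder function(seed) returning a [TrainingSet-class].
#' @param config base [TrainingConfig-class]; per-run seeds derive from its
#'   seed.
#' @param nRuns number of runs (>= 1).
#' @param testSet optional [StimulusSet-class] for evaluation.
#' @param featureFun optional function(trainSet) returning the cached
#'   feature matrix for that dataset.
#' @param testFeatures optional cached test feature matrix.
#' @return list with `runs` (list of [ModelRun-class]) and `summary`
#'   (data.frame of per-run accuracy plus mean/SD attributes).
#' @export
repeatRuns <- function(backbone, datasetBuilder, config, nRuns,
                       testSet = NULL, featureFun = NULL, testFeatures = NULL) {
  stopifnot(nRuns >= 1L)
  runs <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    seed_r <- deriveSeed(config@seed, paste0("run", r))
    cfg <- initialize(config, seed = seed_r)
    ds <- datasetBuilder(seed_r)
    feats <- if (!is.null(featureFun)) featureFun(ds) else NULL
    run <- fineTune(backbone, ds, cfg, features = feats)
    if (!is.null(testSet)) run <- evaluateAccuracy(run, testSet, testFeatures)
    runs[[r]] <- run
  }
  summary <- data.frame(
    run_id = vapply(runs, function(r) r@runId, character(1)),
    seed = vapply(runs, function(r) r@seed, integer(1)),
    accuracy = vapply(runs, function(r)
      if (length(r@evaluation)) r@evaluation$overall else NA_real_, numeric(1)))
  attr(summary, "meanAccuracy") <- mean(summary$accuracy)
  attr(summary, "sdAccuracy") <- stats::sd(summary$accuracy)
  list(runs = runs, summary = summary)
}
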