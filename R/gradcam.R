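# Grad-CAM: channel weights are the spatial mean of the gradient of the
# true-class pre-softmax logit with respect to the last convolutional
# layer's activations; the map is the rectified weighted sum of activation
# channels, bilinearly upsampled to image resolution and min-max
# normalized. The logit (not the softmax probability) is the gradient
# target for stability; Pearson similarity downstream is invariant to the
# map's affine rescaling, so the normalization choice is inert there.

# gradient of the class logit w.r.t. the last-conv activations (post-ReLU,
# pre-pool), given a forward record from .forwardActs(keepActs = TRUE)
.convActGradient <- function(run, fw, classIdx) {
  backbone <- run@backbone
  fcLayers <- Filter(function(l) l$type == "fc", backbone@layers)
  # head: logit = headW %*% ((a_L - mu)/sd) + headB
  g <- as.numeric(run@headW[classIdx, ] / run@featSd)
  for (li in rev(seq_along(fcLayers))) {
    g <- g * (fw$fcActs[[li]] > 0)        # ReLU mask of layer li's output
    g <- as.numeric(crossprod(fcLayers[[li]]$W, g))
  }
  A <- fw$lastConv
  pdim <- if (fw$lastPool) c(dim(A)[1L] %/% 2L, dim(A)[2L] %/% 2L, dim(A)[3L])
          else dim(A)
  # gradient w.r.t. the tensor feeding the fc stage
  Gp <- if (backbone@globalPool) {
    array(rep(as.numeric(g) / (pdim[1L] * pdim[2L]), each = pdim[1L] * pdim[2L]),
          pdim)
  } else {
    array(g, pdim)
  }
  if (fw$lastPool) {
    H <- dim(A)[1L]
    o <- seq(1L, H, 2L); e <- seq(2L, H, 2L)
    P <- .maxPool2(A)
    G <- array(0, dim(A))
    assigned <- array(FALSE, dim(P))
    blocks <- list(list(o, o), list(e, o), list(o, e), list(e, e))
    for (bl in blocks) {
      m <- (A[bl[[1L]], bl[[2L]], , drop = FALSE] == P) & !assigned
      G[bl[[1L]], bl[[2L]], ] <- Gp * m
      assigned <- assigned | m
    }
    G
  } else {
    Gp
  }
}

#' Class logit from injected last-conv activations
#'
#' Recomputes the head pathway (pooling, frozen fully connected layers,
#' feature standardization, trained head) from a given last-conv activation
#' tensor. Useful for gradient checking and occlusion diagnostics.
#'
#' @param run a [ModelRun-class].
#' @param convAct H x W x C activation array for the last conv layer
#'   (post-ReLU, pre-pool).
#' @param class class label or index.
#' @return The pre-softmax logit (numeric scalar).
#' @export
convLogit <- function(run, convAct, class) {
  backbone <- run@backbone
  classIdx <- if (is.character(class)) match(class, run@classes) else as.integer(class)
  if (is.na(classIdx)) stop("unknown class label")
  convLayers <- Filter(function(l) l$type == "conv", backbone@layers)
  lastPool <- convLayers[[length(convLayers)]]$pool
  pooled <- if (lastPool) .maxPool2(convAct) else convAct
  v <- if (backbone@globalPool) apply(pooled, 3L, mean) else as.vector(pooled)
  for (layer in backbone@layers) {
    if (layer$type == "fc") v <- pmax(layer$W %*% v + layer$b, 0)
  }
  s <- (as.numeric(v) - run@featMean) / run@featSd
  as.numeric(run@headW[classIdx, , drop = FALSE] %*% s + run@headB[classIdx])
}

# shared finishing step: weights -> rectified weighted sum -> upsample ->
# min-max normalize with degenerate handling
.finishSaliency <- function(A, alpha, outSize, imageId, runId, targetClass,
                            sourceLayer) {
  C <- dim(A)[3L]
  raw <- matrix(0, dim(A)[1L], dim(A)[2L])
  for (k in seq_len(C)) raw <- raw + alpha[k] * A[, , k]
  raw[raw < 0] <- 0
  flagged <- FALSE
  up <- bilinearUpsample(raw, outSize, outSize)
  mn <- min(up); mx <- max(up)
  if (mx > mn) {
    up <- (up - mn) / (mx - mn)
  } else if (mx > 0) {
    up[] <- 1          # constant positive pre-map
  } else {
    flagged <- TRUE    # identically zero: returned with a flag, not an error
  }
  new("SaliencyMap", imageId = imageId, runId = runId,
      targetClass = targetClass, values = up, sourceLayer = sourceLayer,
      flagged = flagged)
}

#' Grad-CAM channel weights for the true class
#'
#' Spatial mean of the gradient of the class logit with respect to each
#' last-conv activation channel.
#'
#' @param run a [ModelRun-class].
#' @param image a [StimulusImage-class] or H x W x 3 pixel array.
#' @param class class label or index.
#' @return Numeric vector, one weight per channel.
#' @export
saliencyChannelWeights <- function(run, image, class) {
  px <- if (is(image, "StimulusImage")) image@pixels else image
  classIdx <- if (is.character(class)) match(class, run@classes) else as.integer(class)
  if (is.na(classIdx)) stop("unknown class label")
  fw <- .forwardActs(run@backbone, px, keepActs = TRUE)
  G <- .convActGradient(run, fw, classIdx)
  apply(G, 3L, mean)
}

# internal fast path reusing a cached forward record
.gradcamFromActs <- function(run, fw, trueClass, imageId) {
  classIdx <- if (is.character(trueClass)) match(trueClass, run@classes)
              else as.integer(trueClass)
  if (is.na(classIdx)) stop("unknown class label")
  G <- .convActGradient(run, fw, classIdx)
  alpha <- apply(G, 3L, mean)
  .finishSaliency(fw$lastConv, alpha, run@backbone@inputSize, imageId,
                  run@runId, run@classes[classIdx], fw$lastConvName)
}

#' Grad-CAM saliency map for the true class
#'
#' Always computed for the true class label, including misclassified
#' images, from the model's last convolutional layer. The map is static per
#' image (saliency does not vary across time for static inputs).
#'
#' @param run a fine-tuned [ModelRun-class].
#' @param image a [StimulusImage-class] or H x W x 3 pixel array.
#' @param trueClass the true class label (or index); defaults to the
#'   image's category when a [StimulusImage-class] is given.
#' @return A [SaliencyMap-class] at input resolution, values in [0, 1];
#'   an identically-zero pre-normalization map is returned flagged.
#' @export
gradcam <- function(run, image, trueClass = NULL) {
  px <- if (is(image, "StimulusImage")) image@pixels else image
  id <- if (is(image, "StimulusImage")) image@imageId else ""
  if (is.null(trueClass)) {
    if (!is(image, "StimulusImage")) stop("trueClass required for raw pixel input")
    trueClass <- image@category
  }
  fw <- .forwardActs(run@backbone, px, keepActs = TRUE)
  .gradcamFromActs(run, fw, trueClass, id)
}
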