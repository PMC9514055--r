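# Internal numerical and RNG helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state, so package functions never
#' clobber the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' sub-streams (e.g. "images", "participants", "runs"), so that stages can
#' be re-run independently yet reproducibly. The derivation is a simple
#' polynomial string hash combined with a Lehmer step; results stay inside
#' the 32-bit signed integer range that R seeds require.
#'
#' @param master integer master seed.
#' @param name character stream name (may include indices, e.g. "trial_7_12").
#' @return A positive integer seed < 2^31.
#' @export
deriveSeed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (cc in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 131 + cc) %% m
  }
  s <- (abs(as.numeric(master)) %% m)
  s <- (s * 48271 + h + 1) %% m
  as.integer(s + 1)
}

# cache of smoothing matrices keyed by "n/sd/window"
.smooth_cache <- new.env(parent = emptyenv())

#' Build a 1-D Gaussian kernel
#'
#' @param sd standard deviation in pixels.
#' @param window kernel window size in pixels; `NULL` truncates at 4 SD.
#'   Even windows are rounded up to the next odd size to keep the filter
#'   zero-phase.
#' @return Numeric vector of odd length summing to 1.
#' @keywords internal
#' @noRd
gaussianKernel1D <- function(sd, window = NULL) {
  stopifnot(sd > 0)
  if (is.null(window)) window <- 2L * ceiling(4 * sd) + 1L
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

# Fold an out-of-range index back into 1..n by symmetric reflection
# (edge pixel repeated: ... 2 1 | 1 2 3 ... n | n n-1 ...).
.reflectIndex <- function(i, n) {
  # iterate in case the kernel half-width exceeds n
  repeat {
    bad_lo <- i < 1L
    bad_hi <- i > n
    if (!any(bad_lo) && !any(bad_hi)) return(i)
    i[bad_lo] <- 1L - i[bad_lo]
    i[bad_hi] <- 2L * n + 1L - i[bad_hi]
  }
}

#' 1-D smoothing operator with reflective boundary as a dense matrix
#'
#' The matrix M satisfies: smoothed = M %*% x. Reflection folds every
#' out-of-range kernel tap onto exactly one interior pixel, so columns sum
#' to one and total mass is conserved exactly.
#'
#' @keywords internal
#' @noRd
smoothingMatrix <- function(n, sd, window = NULL) {
  key <- paste(n, sd, if (is.null(window)) "auto" else window, sep = "/")
  hit <- .smooth_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- gaussianKernel1D(sd, window)
  half <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  src <- seq_len(n)
  for (j in seq_along(k)) {
    o <- j - half - 1L
    tgt <- .reflectIndex(src + o, n)
    M[cbind(tgt, src)] <- M[cbind(tgt, src)] + k[j]
  }
  .smooth_cache[[key]] <- M
  M
}

#' Separable Gaussian smoothing of a matrix or 3-channel array
#'
#' Applies a Gaussian filter along rows and columns with reflective
#' (symmetric) borders. The kernel is truncated at 4 SD unless an explicit
#' window is given. Total mass is conserved.
#'
#' @param x numeric matrix (H x W) or array (H x W x C).
#' @param sd Gaussian standard deviation in pixels.
#' @param window optional square kernel window size in pixels.
#' @return Smoothed object of the same shape.
#' @export
gaussianSmooth <- function(x, sd, window = NULL) {
  if (is.matrix(x)) {
    Mr <- smoothingMatrix(nrow(x), sd, window)
    Mc <- smoothingMatrix(ncol(x), sd, window)
    return(Mr %*% x %*% t(Mc))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    out <- x
    for (ch in seq_len(dim(x)[3L])) {
      out[, , ch] <- gaussianSmooth(x[, , ch], sd, window)
    }
    return(out)
  }
  stop("gaussianSmooth() expects a matrix or an H x W x C array")
}

#' Bilinear upsampling of a matrix
#'
#' Output pixel centers are mapped into source pixel-center coordinates
#' (half-pixel convention) and clamped at the borders.
#'
#' @param m numeric matrix.
#' @param outH,outW target dimensions.
#' @return `outH` x `outW` matrix.
#' @keywords internal
#' @noRd
bilinearUpsample <- function(m, outH, outW) {
  H <- nrow(m); W <- ncol(m)
  if (H == outH && W == outW) return(m)
  ry <- (seq_len(outH) - 0.5) * H / outH + 0.5
  rx <- (seq_len(outW) - 0.5) * W / outW + 0.5
  ry <- pmin(pmax(ry, 1), H)
  rx <- pmin(pmax(rx, 1), W)
  y0 <- pmin(floor(ry), H - 1L); y0[H == 1L] <- 1L
  x0 <- pmin(floor(rx), W - 1L); x0[W == 1L] <- 1L
  fy <- ry - y0; fx <- rx - x0
  y1 <- pmin(y0 + 1L, H); x1 <- pmin(x0 + 1L, W)
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, outH, outW); wx <- matrix(fx, outH, outW, byrow = TRUE)
  (1 - wy) * ((1 - wx) * m00 + wx * m01) + wy * ((1 - wx) * m10 + wx * m11)
}

# clamp helper
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# peak-normalize a nonnegative matrix; all-zero input is returned unchanged
.peakNormalize <- function(x) {
  mx <- max(x)
  if (mx > 0) x / mx else x
}
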