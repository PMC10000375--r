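# Internal helpers shared across pipeline stages.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global random stream, so seeded package internals
#' never disturb user-level randomness.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Luminance (Rec. 601 luma) of an RGB array
#' @param img H x W x 3 array in [0, 1], or an H x W matrix (returned as is).
#' @return H x W matrix in [0, 1].
#' @export
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Peak signal-to-noise ratio between two images
#'
#' Both images are expected on the [0, 1] scale; identical images give `Inf`.
#' @param x,y numeric arrays of identical dimension.
#' @return PSNR in dB.
#' @export
psnr <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

# Shift a matrix by (dr, dc) with replicate (Neumann) padding.
shiftPad <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Sobel gradient magnitude of a matrix (replicate boundary).
sobelMagnitude <- function(m) {
  gx <- (shiftPad(m, 0, -1) - shiftPad(m, 0, 1)) * 2 +
    (shiftPad(m, -1, -1) - shiftPad(m, -1, 1)) +
    (shiftPad(m, 1, -1) - shiftPad(m, 1, 1))
  gy <- (shiftPad(m, -1, 0) - shiftPad(m, 1, 0)) * 2 +
    (shiftPad(m, -1, -1) - shiftPad(m, 1, -1)) +
    (shiftPad(m, -1, 1) - shiftPad(m, 1, 1))
  sqrt(gx^2 + gy^2)
}

# Separable Gaussian blur of a matrix; sigma in pixels, replicate boundary.
gaussBlurMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) acc <- acc + k[i] * shiftPad(m, (-r:r)[i], 0)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shiftPad(acc, 0, (-r:r)[i])
  out
}

gaussBlurImage <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (is.matrix(img)) return(gaussBlurMatrix(img, sigma))
  for (ch in seq_len(dim(img)[3])) img[, , ch] <- gaussBlurMatrix(img[, , ch], sigma)
  img
}

# EBImage stores images x-first; our arrays are row (y) first.  These two
# adapters keep the transposition in one place.
asEB <- function(m) EBImage::Image(t(m))
fromEB <- function(im) t(EBImage::imageData(im))

# Connected-component labelling (8-connectivity) of a binary matrix.
# Two-pass union-find over foreground pixels in column-major order.
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask > 0)
  lab <- matrix(0L, h, w)
  if (!length(fg)) return(lab)
  pos <- integer(h * w)
  pos[fg] <- seq_along(fg)
  parent <- seq_along(fg)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(fg)) {
    p <- fg[k]
    r <- ((p - 1L) %% h) + 1L
    nb <- c(if (r > 1L) p - 1L,                       # N (same column)
            if (p > h) c(p - h,                       # W
                         if (r > 1L) p - h - 1L,      # NW
                         if (r < h) p - h + 1L))      # SW
    for (q in nb) {
      if (pos[q] > 0L) {
        ra <- findRoot(k); rb <- findRoot(pos[q])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(fg), findRoot, integer(1))
  lab[fg] <- match(roots, unique(roots))
  lab
}

# Binary dilation with a disc brush of given radius (pixels).
dilateMask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  sz <- 2L * as.integer(radius) + 1L
  br <- EBImage::makeBrush(sz, shape = "disc")
  fromEB(EBImage::dilate(asEB(mask * 1), br)) > 0
}

# Hue/saturation/value planes from an RGB array, each in [0, 1].
rgbToHsv <- function(img) {
  stopifnot(length(dim(img)) == 3L)
  d <- dim(img)
  m <- rgb2hsv(r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
               b = as.vector(img[, , 3]), maxColorValue = 1)
  array(t(m), dim = c(d[1], d[2], 3))
}

# Shannon entropy (bits) of a histogram of values in [0,1] with nbins bins.
histEntropy <- function(v, nbins = 256L) {
  counts <- tabulate(pmin(pmax(floor(v * nbins) + 1L, 1L), nbins), nbins)
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

stopIfNotImage <- function(img, name = "image") {
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop(sprintf("'%s' must be a 2-D matrix or H x W x C array", name))
  }
  if (length(d) == 3L && !(d[3] %in% c(1L, 3L))) {
    stop(sprintf("'%s' must have 1 or 3 channels", name))
  }
  invisible(TRUE)
}
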