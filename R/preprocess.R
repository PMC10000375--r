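#' @include hho.R
NULL

# Local median / MAD maps over a (2r+1)^2 neighbourhood, replicate boundary.
localMedianMad <- function(m, window) {
  r <- (window - 1L) %/% 2L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  stack <- vapply(seq_len(nrow(offs)),
                  function(i) shiftPad(m, offs$dr[i], offs$dc[i]),
                  matrix(0, nrow(m), ncol(m)))
  med <- apply(stack, c(1, 2), median)
  madv <- apply(abs(stack - as.vector(med)), c(1, 2), median)
  list(median = med, mad = madv)
}

# Two-component EM on window values: clean Gaussian + uniform impulse.
# Returns the posterior-mean clean estimate (the fitted Gaussian mean).
emCleanEstimate <- function(v, maxIters, tol) {
  mu <- median(v)
  s <- max(1.4826 * mad(v, constant = 1), 5e-3)
  pi1 <- 0.8
  for (it in seq_len(maxIters)) {
    d1 <- pi1 * dnorm(v, mu, s)
    d0 <- (1 - pi1) * 1          # impulse component: uniform on [0, 1]
    resp <- d1 / (d1 + d0 + 1e-300)
    w <- sum(resp)
    if (w < 1e-8) break
    muN <- sum(resp * v) / w
    sN <- max(sqrt(sum(resp * (v - muN)^2) / w), 5e-3)
    piN <- min(max(w / length(v), 0.05), 0.999)
    delta <- abs(muN - mu) + abs(sN - s) + abs(piN - pi1)
    mu <- muN; s <- sN; pi1 <- piN
    if (delta < tol) break
  }
  mu
}

iemDenoiseChannel <- function(m, window, maxEmIters, tol, thresholdK, madFloor) {
  mm <- localMedianMad(m, window)
  thr <- thresholdK * pmax(mm$mad, madFloor)
  flagged <- abs(m - mm$median) > thr
  if (!any(flagged)) return(list(channel = m, flagged = flagged))
  h <- nrow(m); w <- ncol(m)
  r <- (window - 1L) %/% 2L
  out <- m
  # zig-zag (boustrophedon) traversal: odd rows left-to-right, even rows
  # right-to-left; each replacement sees previously cleaned neighbours.
  for (i in seq_len(h)) {
    cols <- if (i %% 2L == 1L) seq_len(w) else rev(seq_len(w))
    for (j in cols) {
      if (!flagged[i, j]) next
      ri <- max(1L, i - r):min(h, i + r)
      ci <- max(1L, j - r):min(w, j + r)
      win <- out[ri, ci]
      out[i, j] <- clip01(emCleanEstimate(as.vector(win), maxEmIters, tol))
    }
  }
  list(channel = out, flagged = flagged)
}

#' Iterative expectation-maximization impulse denoiser
#'
#' Pixels deviating from their local median by more than a dynamic threshold
#' (`thresholdK` times the local MAD, floored at `madFloor`) are flagged as
#' impulses.  Flagged pixels are revisited in a zig-zag (boustrophedon) scan
#' and replaced by the posterior-mean clean estimate of a two-component
#' mixture - a Gaussian clean component plus a uniform impulse component -
#' fitted by EM inside the pixel's window.  Unflagged pixels are untouched.
#'
#' @param img H x W matrix or H x W x 3 array in [0, 1].
#' @param window odd neighbourhood size in pixels (>= 3).
#' @param maxEmIters EM iteration cap per window.
#' @param tol EM convergence tolerance on the parameter change.
#' @param thresholdK dynamic-threshold multiplier on the local MAD.
#' @param madFloor lower floor on the MAD so flat regions do not flag
#'   ordinary texture.
#' @param details when `TRUE`, return a list with the flagged-pixel mask.
#' @return the denoised image (or a list when `details = TRUE`).
#' @export
iemDenoise <- function(img, window = 5L, maxEmIters = 25L, tol = 1e-4,
                       thresholdK = 6, madFloor = 0.06, details = FALSE) {
  stopIfNotImage(img)
  if (window %% 2L != 1L || window < 3L) stop("'window' must be odd and >= 3")
  if (tol <= 0) stop("'tol' must be > 0")
  if (is.matrix(img)) {
    res <- iemDenoiseChannel(img, window, maxEmIters, tol, thresholdK, madFloor)
    out <- res$channel; flg <- res$flagged
  } else {
    out <- img
    flg <- matrix(FALSE, dim(img)[1], dim(img)[2])
    for (ch in seq_len(dim(img)[3])) {
      res <- iemDenoiseChannel(img[, , ch], window, maxEmIters, tol,
                               thresholdK, madFloor)
      out[, , ch] <- res$channel
      flg <- flg | res$flagged
    }
  }
  if (details) list(image = out, flagged = flg) else out
}

#' Perona-Malik anisotropic diffusion (artifact removal)
#'
#' Explicit 4-neighbour scheme with conductance
#' \eqn{g(|\nabla I|) = \exp(-(|\nabla I|/\kappa)^2)} and Neumann boundaries;
#' smooths flat regions and noise while preserving strong edges.  The scheme
#' conserves mean intensity exactly.
#'
#' @param img matrix or H x W x C array in [0, 1].
#' @param iters number of diffusion steps.
#' @param dt time step; must lie in (0, 0.25] for stability.
#' @param kappa conductance scale in intensity units.
#' @return the diffused image.
#' @export
diffusionFilter <- function(img, iters = 10L, dt = 0.2, kappa = 0.1) {
  stopIfNotImage(img)
  if (dt <= 0 || dt > 0.25) stop("'dt' must be in (0, 0.25] for stability")
  if (kappa <= 0) stop("'kappa' must be > 0")
  diffuse <- function(m) {
    for (it in seq_len(iters)) {
      dN <- shiftPad(m, -1, 0) - m
      dS <- shiftPad(m, 1, 0) - m
      dE <- shiftPad(m, 0, -1) - m
      dW <- shiftPad(m, 0, 1) - m
      m <- m + dt * (exp(-(dN / kappa)^2) * dN + exp(-(dS / kappa)^2) * dS +
                     exp(-(dE / kappa)^2) * dE + exp(-(dW / kappa)^2) * dW)
    }
    m
  }
  if (is.matrix(img)) return(diffuse(img))
  for (ch in seq_len(dim(img)[3])) img[, , ch] <- diffuse(img[, , ch])
  img
}

#' Contrast fitness of a grayscale image
#'
#' Composite of histogram entropy, edge density and edge strength:
#' \deqn{f(I) = H(I) \cdot (E(I)/N) \cdot \log(\log(S(I) + e))}
#' where `H` is the Shannon entropy (bits) of the 256-bin intensity
#' histogram, `E` the number of pixels whose Sobel magnitude exceeds
#' `edgeThreshold`, `N` the pixel count, and `S` the per-pixel edge
#' strength (sum of Sobel magnitudes over edge pixels, divided by `N` so
#' the score is invariant to image size).  Zero for constant images;
#' finite and non-negative otherwise.
#'
#' @param gray H x W matrix in [0, 1] (an RGB array is converted to
#'   luminance).
#' @param edgeThreshold Sobel magnitude threshold defining an edge pixel.
#' @return a non-negative scalar.
#' @export
contrastFitness <- function(gray, edgeThreshold = 0.1) {
  gray <- luminance(gray)
  if (length(gray) == 0) stop("empty image")
  H <- histEntropy(as.vector(gray))
  mag <- sobelMagnitude(gray)
  # border rows/columns carry replicate-padding artefacts; score the interior
  if (nrow(mag) > 2 && ncol(mag) > 2) {
    mag <- mag[2:(nrow(mag) - 1), 2:(ncol(mag) - 1), drop = FALSE]
  }
  edge <- mag > edgeThreshold
  E <- sum(edge)
  S <- sum(mag[edge]) / length(mag)
  H * (E / length(mag)) * log(log(S + exp(1)))
}

# The sigmoid-gamma mapping; monotone non-decreasing on [0,1] for any
# alpha >= 0, m > 0, gamma > 0.
contrastMap <- function(v, alpha, m, gam, eps = 1e-6) {
  tf <- function(x) (1 / (1 + (m / (x + eps))^alpha))^gam
  t0 <- tf(0); t1 <- tf(1)
  if (t1 - t0 < 1e-12) return(v)
  (tf(v) - t0) / (t1 - t0)
}

#' Contrast enhancement by Harris hawks optimization
#'
#' Maximizes [contrastFitness] over the three parameters (gain `alpha`,
#' cutoff `m`, gamma) of the monotone sigmoid-gamma mapping
#' \eqn{T(v) = [1/(1+(m/(v+\epsilon))^\alpha)]^\gamma} (min-max rescaled),
#' applied to the luminance channel; chroma ratios are preserved on RGB
#' input.  If no sampled transform beats the input's fitness, the identity
#' transform is returned, so enhancement never lowers fitness.
#'
#' @param img matrix or RGB array in [0, 1].
#' @param config an [HHOConfig-class] for a 3-dimensional search; its bounds
#'   are overridden by `bounds`.
#' @param bounds 2 x 3 matrix (rows: lower, upper) over (alpha, m, gamma).
#' @return list with `image` (enhanced) and `transform`
#'   ([ContrastTransform-class]).
#' @export
hhoEnhance <- function(img, config = NULL,
                       bounds = rbind(c(1, 0.05, 0.3), c(20, 0.95, 3))) {
  stopIfNotImage(img)
  if (is.null(config)) config <- hhoConfig(15L, 50L, bounds[1, ], bounds[2, ], 0L)
  cfg <- hhoConfig(config@PS, config@Tm, bounds[1, ], bounds[2, ], config@seed)
  gray <- luminance(img)
  f0 <- contrastFitness(gray)
  objective <- function(p) -contrastFitness(contrastMap(gray, p[1], p[2], p[3]))
  res <- hhoOptimize(objective, cfg)
  fBest <- -bestFitness(res)
  if (fBest <= f0) {
    tr <- new("ContrastTransform", params = c(alpha = NA_real_, m = NA_real_,
              gamma = NA_real_), fitness = f0, bounds = bounds, identity = TRUE)
    return(list(image = img, transform = tr))
  }
  p <- bestPosition(res)
  newGray <- contrastMap(gray, p[1], p[2], p[3])
  if (is.matrix(img)) {
    out <- newGray
  } else {
    ratio <- newGray / (gray + 1e-6)
    out <- img
    for (ch in 1:3) out[, , ch] <- clip01(img[, , ch] * ratio)
  }
  tr <- new("ContrastTransform",
            params = c(alpha = p[1], m = p[2], gamma = p[3]),
            fitness = fBest, bounds = bounds, identity = FALSE)
  list(image = out, transform = tr)
}

#' Full preprocessing chain
#'
#' Runs impulse denoising, then anisotropic diffusion, then HHO contrast
#' enhancement, each individually switchable; per-stage wall-clock timings
#' are recorded.
#'
#' @param img matrix or RGB array in [0, 1].
#' @param config nested list as produced by [defaultConfig()]`$preprocess`;
#'   recognised fields: `denoise$enabled/window/thresholdK`,
#'   `diffusion$enabled/iters/dt/kappa`,
#'   `enhance$enabled/PS/Tm/seed`.
#' @param details when `TRUE`, return stage timings and the winning
#'   transform alongside the image.
#' @return the preprocessed image, or a list when `details = TRUE`.
#' @export
preprocessFundus <- function(img, config = defaultConfig()$preprocess,
                             details = FALSE) {
  timings <- c(denoise = 0, diffusion = 0, enhance = 0)
  transform <- NULL
  if (isTRUE(config$denoise$enabled)) {
    t0 <- proc.time()[["elapsed"]]
    img <- iemDenoise(img, window = config$denoise$window %||% 5L,
                      thresholdK = config$denoise$thresholdK %||% 6)
    timings[["denoise"]] <- proc.time()[["elapsed"]] - t0
  }
  if (isTRUE(config$diffusion$enabled)) {
    t0 <- proc.time()[["elapsed"]]
    img <- diffusionFilter(img, iters = config$diffusion$iters %||% 10L,
                           dt = config$diffusion$dt %||% 0.2,
                           kappa = config$diffusion$kappa %||% 0.1)
    timings[["diffusion"]] <- proc.time()[["elapsed"]] - t0
  }
  if (isTRUE(config$enhance$enabled)) {
    t0 <- proc.time()[["elapsed"]]
    cfg <- hhoConfig(config$enhance$PS %||% 15L, config$enhance$Tm %||% 50L,
                     rep(0, 3), rep(1, 3), config$enhance$seed %||% 0L)
    res <- hhoEnhance(img, cfg)
    img <- res$image
    transform <- res$transform
    timings[["enhance"]] <- proc.time()[["elapsed"]] - t0
  }
  if (details) list(image = img, timings = timings, transform = transform)
  else img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "ContrastTransform", function(object) {
  if (object@identity) {
    cat(sprintf("ContrastTransform: identity (fitness %.4g)\n", object@fitness))
  } else {
    cat(sprintf("ContrastTransform: alpha=%.3g m=%.3g gamma=%.3g fitness %.4g\n",
        object@params[1], object@params[2], object@params[3], object@fitness))
  }
})
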