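#' @include AllGenerics.R
NULL

#' Create a synthetic fundus specification
#'
#' A [FundusSpec-class] fixes everything about a synthetic fundus image:
#' size, class, lesion counts, vessel-tree depth, corruption levels and seed.
#' Regenerating from the same spec is byte-identical.
#'
#' @param height,width image size in pixels (>= 64); defaults 224 to match the
#'   classifier's native input.
#' @param classLabel `"normal"`, `"DR"` or `"DME"`.
#' @param nMicroaneurysms,nHemorrhages,nExudates lesion counts; a `normal`
#'   image must have all zero, a `DME` image at least one exudate, a `DR`
#'   image at least one lesion in total.
#' @param vesselDepth recursion depth of the binary vessel tree (default 4).
#' @param noiseDensity fraction of salt-and-pepper pixels in [0, 1].
#' @param illuminationStrength slope of the multiplicative illumination ramp.
#' @param blurSigma Gaussian blur sigma in pixels.
#' @param seed integer generation seed.
#' @return a validated [FundusSpec-class].
#' @examples
#' fundusSpec(64, 64, "DR", nMicroaneurysms = 3, seed = 1)
#' @export
fundusSpec <- function(height = 224L, width = 224L, classLabel = "normal",
                       nMicroaneurysms = 0L, nHemorrhages = 0L, nExudates = 0L,
                       vesselDepth = 4L, noiseDensity = 0,
                       illuminationStrength = 0, blurSigma = 0, seed = 1L) {
  obj <- new("FundusSpec", height = as.integer(height), width = as.integer(width),
    classLabel = as.character(classLabel),
    nMicroaneurysms = as.integer(nMicroaneurysms),
    nHemorrhages = as.integer(nHemorrhages), nExudates = as.integer(nExudates),
    vesselDepth = as.integer(vesselDepth), noiseDensity = as.numeric(noiseDensity),
    illuminationStrength = as.numeric(illuminationStrength),
    blurSigma = as.numeric(blurSigma), seed = as.integer(seed))
  validObject(obj)
  obj
}

# --- geometry -----------------------------------------------------------
# Optic disc at mid-height near the nasal edge; fovea 2.5 disc diameters
# temporal to the disc; macular radius = one disc diameter.
fundusGeometry <- function(h, w) {
  discR <- round(min(h, w) * 0.08)
  discC <- c(row = h / 2, col = discR * 1.6)
  foveaC <- c(row = h / 2, col = discC[["col"]] + 5 * discR)
  list(discRadius = discR, discCenter = discC, foveaCenter = foveaC,
       maculaRadius = 2 * discR)
}

discMaskAt <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - center[["row"]])^2 + (cc - center[["col"]])^2 <= radius^2) * 1
}

# Rasterize a thick line segment into a mask (in place, returns mask).
drawSegment <- function(mask, p1, p2, width) {
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(2L, ceiling(len * 2))
  ts <- seq(0, 1, length.out = n)
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(width / 2)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= (width / 2)^2 + 0.5, , drop = FALSE]
  for (t in ts) {
    p <- p1 + t * (p2 - p1)
    rs <- round(p[1]) + off$dr
    cs <- round(p[2]) + off$dc
    ok <- rs >= 1 & rs <= h & cs >= 1 & cs <= w
    mask[cbind(rs[ok], cs[ok])] <- 1
  }
  mask
}

# Recursive binary vessel tree rooted at the disc centre.  Child width is
# 0.7 x parent width; branch angles jitter uniformly within +/- 25 degrees.
growVesselTree <- function(h, w, root, depth, baseWidth, baseLen) {
  mask <- matrix(0, h, w)
  grow <- function(p, angle, width, len, d) {
    if (d <= 0 || width < 0.6) return()
    q <- p + len * c(sin(angle), cos(angle))
    q <- pmin(pmax(q, 2), c(h - 1, w - 1))  # keep branch nodes inside
    mask <<- drawSegment(mask, p, q, width)
    for (branch in c(-1, 1)) {
      jitter <- runif(1, -25, 25) * pi / 180
      grow(q, angle + branch * (25 * pi / 180) + jitter, width * 0.7,
           len * 0.85, d - 1L)
    }
  }
  nTrunk <- 4L
  trunkAngles <- seq(-60, 60, length.out = nTrunk) * pi / 180 +
    runif(nTrunk, -10, 10) * pi / 180
  for (a in trunkAngles) {
    # angle measured from the temporal direction (increasing column)
    grow(root, pi / 2 - a, baseWidth, baseLen, depth)
  }
  mask
}

blobMask <- function(h, w, center, meanRadius, irregular = FALSE) {
  nv <- if (irregular) 10L else 24L
  ang <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  rad <- if (irregular) meanRadius * runif(nv, 0.5, 1.5) else rep(meanRadius, nv)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  theta <- atan2(dr, dc)
  # radius at each pixel's angle by linear interpolation around the polygon
  idx <- (theta %% (2 * pi)) / (2 * pi) * nv
  i0 <- floor(idx) %% nv + 1L
  i1 <- i0 %% nv + 1L
  fr <- idx - floor(idx)
  rAt <- rad[i0] * (1 - fr) + rad[i1] * fr
  (sqrt(dr^2 + dc^2) <= rAt) * 1
}

# Random centre for a lesion, constrained to the retina, away from the
# vessel tree (lesion and vessel supports must stay disjoint), and
# optionally inside / outside the macula.
sampleCenter <- function(h, w, geom, inMacula = NA, discAvoid = TRUE,
                         avoidMask = NULL) {
  for (i in seq_len(200L)) {
    p <- c(runif(1, h * 0.1, h * 0.9), runif(1, w * 0.1, w * 0.9))
    dDisc <- sqrt(sum((p - geom$discCenter)^2))
    dFov <- sqrt(sum((p - geom$foveaCenter)^2))
    if (discAvoid && dDisc < geom$discRadius * 1.5) next
    if (isTRUE(inMacula) && dFov > geom$maculaRadius * 0.9) next
    if (isFALSE(inMacula) && dFov < geom$maculaRadius * 1.2) next
    if (!is.null(avoidMask) && avoidMask[round(p[1]), round(p[2])] > 0) next
    return(p)
  }
  p
}

severityFromCount <- function(n) {
  if (n <= 0) "none" else if (n <= 3) "mild" else if (n <= 9) "moderate" else "severe"
}

#' Generate a labeled synthetic fundus image
#'
#' Renders a clean retina (reddish-orange gradient background, bright optic
#' disc, darker macula, seeded binary vessel tree), plants the requested
#' lesions (microaneurysms: small sharp dark-red dots; hemorrhages: irregular
#' dark-red blobs; hard exudates: yellowish-white blobs), records ground-truth
#' masks, and only then applies the spec's corruption (blur, illumination
#' ramp, salt-and-pepper noise), so the masks mark true lesion support.
#'
#' @param spec a [FundusSpec-class].
#' @return a [LabeledFundus-class].
#' @examples
#' lf <- generateFundus(fundusSpec(64, 64, "DME", nExudates = 2, seed = 7))
#' classLabel(lf)
#' @export
generateFundus <- function(spec) {
  stopifnot(is(spec, "FundusSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    h <- spec@height; w <- spec@width
    geom <- fundusGeometry(h, w)
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)

    # background: smooth reddish-orange gradient with a mild vignette
    g1 <- (rr / h - 0.5); g2 <- (cc / w - 0.5)
    vign <- 1 - 0.25 * (g1^2 + g2^2) * 4
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- clip01((0.72 + 0.08 * g2) * vign)
    img[, , 2] <- clip01((0.40 + 0.05 * g1) * vign)
    img[, , 3] <- clip01((0.16 + 0.03 * g2) * vign)

    # macula: slightly darker circular region around the fovea
    macula <- discMaskAt(h, w, geom$foveaCenter, geom$maculaRadius)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.18 * macula)

    # vessel tree rooted at the disc centre
    vmask <- growVesselTree(h, w, unname(geom$discCenter), spec@vesselDepth,
                            baseWidth = max(2, round(min(h, w) / 48)),
                            baseLen = min(h, w) * 0.22)
    vcol <- c(0.45, 0.12, 0.10)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - vmask) + vcol[ch] * vmask

    # optic disc drawn on top of the vessels (bright, yellowish white)
    dmask <- discMaskAt(h, w, geom$discCenter, geom$discRadius)
    dcol <- c(0.96, 0.90, 0.70)
    soft <- gaussBlurMatrix(dmask, max(1, geom$discRadius / 6))
    soft <- pmin(soft * 1.2, 1)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - soft) + dcol[ch] * soft

    # lesions; centres kept off the (dilated) vessel tree so lesion and
    # vessel ground-truth supports stay disjoint
    lmask <- list(MA = matrix(0, h, w), HE = matrix(0, h, w), EX = matrix(0, h, w))
    vesselNear <- dilateMask(vmask > 0, max(2L, round(min(h, w) / 24)))
    scalePx <- min(h, w) / 224
    paint <- function(mask, col) {
      for (ch in 1:3) img[, , ch] <<- img[, , ch] * (1 - mask) + col[ch] * mask
    }
    if (spec@nMicroaneurysms > 0) for (i in seq_len(spec@nMicroaneurysms)) {
      p <- sampleCenter(h, w, geom, avoidMask = vesselNear)
      m <- discMaskAt(h, w, c(row = p[1], col = p[2]),
                      max(1, runif(1, 1, 3) * max(scalePx, 0.6)))
      lmask$MA <- pmax(lmask$MA, m)
      paint(m, c(0.40, 0.08, 0.08))
    }
    if (spec@nHemorrhages > 0) for (i in seq_len(spec@nHemorrhages)) {
      p <- sampleCenter(h, w, geom, avoidMask = vesselNear)
      m <- blobMask(h, w, p, max(2, runif(1, 4, 9) * max(scalePx, 0.5)),
                    irregular = TRUE)
      lmask$HE <- pmax(lmask$HE, m)
      paint(m, c(0.34, 0.07, 0.07))
    }
    if (spec@nExudates > 0) for (i in seq_len(spec@nExudates)) {
      inMac <- if (spec@classLabel == "DME") (i == 1L || runif(1) < 0.6)
               else if (spec@classLabel == "DR") FALSE else NA
      p <- sampleCenter(h, w, geom, inMacula = inMac, avoidMask = vesselNear)
      m <- blobMask(h, w, p, max(1.5, runif(1, 2.5, 6) * max(scalePx, 0.5)))
      lmask$EX <- pmax(lmask$EX, m)
      paint(m, c(0.95, 0.85, 0.30))
    }

    img <- corruptImage(img, spec@noiseDensity, spec@illuminationStrength,
                        spec@blurSigma, seed = spec@seed + 101L)

    total <- spec@nMicroaneurysms + spec@nHemorrhages + spec@nExudates
    new("LabeledFundus", image = img, vesselMask = vmask, discMask = dmask,
        maculaMask = macula, lesionMasks = lmask, classLabel = spec@classLabel,
        severityLabel = severityFromCount(total), spec = spec)
  })
}

#' Corrupt an image with blur, an illumination ramp, and impulse noise
#'
#' Applied in the order blur, then a multiplicative linear illumination ramp
#' across columns, then salt-and-pepper noise hitting exactly
#' `round(noiseDensity * H * W)` pixels (each set to 0 or 1 with equal
#' probability across all channels).  With all three levels at zero the image
#' is returned unchanged.
#'
#' @param img H x W x 3 array or H x W matrix in [0, 1].
#' @param noiseDensity impulse fraction in [0, 1].
#' @param illuminationStrength ramp slope (0 disables).
#' @param blurSigma Gaussian sigma in pixels (0 disables).
#' @param seed integer seed for the impulse positions/polarities.
#' @return corrupted image of the same shape.
#' @export
corruptImage <- function(img, noiseDensity, illuminationStrength, blurSigma,
                         seed = 1L) {
  stopIfNotImage(img)
  if (noiseDensity < 0 || noiseDensity > 1) stop("noiseDensity must be in [0, 1]")
  if (blurSigma > 0) img <- gaussBlurImage(img, blurSigma)
  d <- dim(img)
  if (illuminationStrength > 0) {
    ramp <- 1 + illuminationStrength * (seq_len(d[2]) / d[2] - 0.5)
    if (length(d) == 2L) img <- clip01(sweep(img, 2, ramp, `*`))
    else for (ch in seq_len(d[3])) img[, , ch] <- clip01(sweep(img[, , ch], 2, ramp, `*`))
  }
  nImp <- round(noiseDensity * d[1] * d[2])
  if (nImp > 0) {
    withSeed(seed, {
      pix <- sample.int(d[1] * d[2], nImp)
      val <- sample(c(0, 1), nImp, replace = TRUE)
      if (length(d) == 2L) img[pix] <- val
      else for (ch in seq_len(d[3])) img[pix + (ch - 1L) * d[1] * d[2]] <- val
    })
  }
  img
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `nPerClass` images per class (normal, DR, DME) as PNG, one PNG per
#' ground-truth mask, and a CSV manifest
#' (`filename,class_label,severity,ma_count,he_count,ex_count,seed`).
#' Lesion counts per class are drawn deterministically from the per-image
#' seed: DR images carry 1-10 microaneurysms, 0-4 hemorrhages and 0-2
#' extramacular exudates; DME images carry 1-8 exudates (at least one
#' macular), 0-4 microaneurysms and 0-2 hemorrhages.
#'
#' @param nPerClass images per class (>= 1).
#' @param baseSeed integer base seed; the i-th image uses `baseSeed + i`.
#' @param outDir output directory (created if needed); `NULL` skips writing
#'   and only returns the in-memory records.
#' @param height,width image size in pixels.
#' @param noiseDensity,illuminationStrength,blurSigma corruption levels
#'   applied to every image.
#' @param writeMasks also write the ground-truth masks as PNGs.
#' @return invisibly, a list with `manifest` (data.frame) and `images`
#'   (list of [LabeledFundus-class]).
#' @export
generateDataset <- function(nPerClass, baseSeed = 0L, outDir = NULL,
                            height = 224L, width = 224L, noiseDensity = 0,
                            illuminationStrength = 0, blurSigma = 0,
                            writeMasks = TRUE) {
  if (nPerClass < 1L) stop("'nPerClass' must be >= 1")
  if (!is.null(outDir) && !dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  }
  rows <- list(); imgs <- list(); k <- 0L
  for (cls in VALID_CLASSES) {
    for (i in seq_len(nPerClass)) {
      k <- k + 1L
      seed <- as.integer(baseSeed + k)
      spec <- randomFundusSpec(cls, seed, height, width, noiseDensity,
                               illuminationStrength, blurSigma)
      lf <- generateFundus(spec)
      fn <- sprintf("img_%04d_%s.png", k, cls)
      if (!is.null(outDir)) {
        writeFundusPNG(lf, file.path(outDir, fn), writeMasks = writeMasks)
      }
      rows[[k]] <- data.frame(filename = fn, class_label = cls,
        severity = severityLabel(lf), ma_count = spec@nMicroaneurysms,
        he_count = spec@nHemorrhages, ex_count = spec@nExudates,
        seed = seed, stringsAsFactors = FALSE)
      imgs[[k]] <- lf
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  }
  invisible(list(manifest = manifest, images = imgs))
}

# Deterministic per-seed draw of a class-consistent FundusSpec.
randomFundusSpec <- function(classLabel, seed, height = 224L, width = 224L,
                             noiseDensity = 0, illuminationStrength = 0,
                             blurSigma = 0) {
  counts <- withSeed(seed + 7L, {
    switch(classLabel,
      normal = c(0L, 0L, 0L),
      DR = c(sample(1:10, 1L), sample(0:4, 1L), sample(0:2, 1L)),
      DME = c(sample(0:4, 1L), sample(0:2, 1L), sample(1:8, 1L)),
      stop("unknown class label: ", classLabel))
  })
  fundusSpec(height, width, classLabel, nMicroaneurysms = counts[1],
             nHemorrhages = counts[2], nExudates = counts[3],
             noiseDensity = noiseDensity,
             illuminationStrength = illuminationStrength,
             blurSigma = blurSigma, seed = seed)
}

#' Write a labeled fundus and its masks as PNG files
#' @param lf a [LabeledFundus-class].
#' @param path output path for the image PNG; masks are written next to it
#'   with `_vessel`, `_disc`, `_macula`, `_MA`, `_HE`, `_EX` suffixes.
#' @param writeMasks whether to write the masks.
#' @return invisibly, the image path.
#' @export
writeFundusPNG <- function(lf, path, writeMasks = TRUE) {
  png::writePNG(lf@image, path)
  if (writeMasks) {
    base <- sub("\\.png$", "", path)
    png::writePNG(lf@vesselMask, paste0(base, "_vessel.png"))
    png::writePNG(lf@discMask, paste0(base, "_disc.png"))
    png::writePNG(lf@maculaMask, paste0(base, "_macula.png"))
    for (ty in names(lf@lesionMasks)) {
      png::writePNG(lf@lesionMasks[[ty]], paste0(base, "_", ty, ".png"))
    }
  }
  invisible(path)
}

# --- accessors ----------------------------------------------------------

#' @rdname LabeledFundus-class
#' @aliases fundusImage,LabeledFundus-method
setMethod("fundusImage", "LabeledFundus", function(object) object@image)
#' @rdname LabeledFundus-class
setMethod("vesselMask", "LabeledFundus", function(object) object@vesselMask)
#' @rdname LabeledFundus-class
setMethod("discMask", "LabeledFundus", function(object) object@discMask)
#' @rdname LabeledFundus-class
setMethod("maculaMask", "LabeledFundus", function(object) object@maculaMask)
#' @rdname LabeledFundus-class
setMethod("lesionMasks", "LabeledFundus", function(object) object@lesionMasks)
#' @rdname LabeledFundus-class
setMethod("classLabel", "LabeledFundus", function(object) object@classLabel)
#' @rdname LabeledFundus-class
setMethod("severityLabel", "LabeledFundus", function(object) object@severityLabel)
#' @rdname LabeledFundus-class
setMethod("fundusSpecOf", "LabeledFundus", function(object) object@spec)

setMethod("show", "FundusSpec", function(object) {
  cat(sprintf("FundusSpec %dx%d class=%s MA=%d HE=%d EX=%d seed=%d\n",
    object@height, object@width, object@classLabel, object@nMicroaneurysms,
    object@nHemorrhages, object@nExudates, object@seed))
})

setMethod("show", "LabeledFundus", function(object) {
  d <- dim(object@image)
  cat(sprintf("LabeledFundus %dx%d class=%s severity=%s vessels=%d px\n",
    d[1], d[2], object@classLabel, object@severityLabel,
    sum(object@vesselMask)))
})
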