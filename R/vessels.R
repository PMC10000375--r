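#' @include optics.R preprocess.R
NULL

#' Locate and remove the optic disc
#'
#' The disc is the brightest compact region: pixels above the
#' `percentile`-quantile of luminance are labelled (8-connectivity) and the
#' largest sufficiently circular component is taken as the disc.  Disc pixels
#' are inpainted with the median background colour.
#'
#' @param img RGB array or matrix in [0, 1].
#' @param percentile luminance quantile defining bright candidates.
#' @param minCircularity minimum circularity (4 pi A / P^2) for a component
#'   to qualify as the disc.
#' @param minAreaFraction minimum component area as a fraction of the image.
#' @param dilateRadius extra dilation of the detected disc before inpainting
#'   (1 px default keeps the mask tight at small image sizes).
#' @return list with `image` (disc inpainted) and `discMask` (0/1 matrix;
#'   all-zero with a warning when no candidate qualifies).
#' @export
removeOpticDisc <- function(img, percentile = 0.98, minCircularity = 0.35,
                            minAreaFraction = 5e-4, dilateRadius = 1L) {
  stopIfNotImage(img)
  gray <- luminance(img)
  h <- nrow(gray); w <- ncol(gray)
  bw <- gray > quantile(gray, percentile)
  lab <- labelComponents(bw)
  nlab <- max(lab)
  best <- 0L; bestArea <- 0
  if (nlab > 0) {
    shp <- EBImage::computeFeatures.shape(EBImage::Image(t(lab)))
    for (k in seq_len(nlab)) {
      area <- shp[k, "s.area"]
      per <- max(shp[k, "s.perimeter"], 1)
      circ <- 4 * pi * area / per^2
      if (area >= minAreaFraction * h * w && circ >= minCircularity &&
          area > bestArea) {
        best <- k; bestArea <- area
      }
    }
  }
  if (best == 0L) {
    warning("no optic-disc candidate found; returning an empty mask")
    return(list(image = img, discMask = matrix(0, h, w)))
  }
  mask <- dilateMask(lab == best, dilateRadius)
  out <- img
  if (is.matrix(img)) {
    out[mask] <- median(img[!mask])
  } else {
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[mask] <- median(pl[!mask])
      out[, , ch] <- pl
    }
  }
  list(image = out, discMask = mask * 1)
}

#' Vesselness (thin dark structure) response
#'
#' White top-hat of the inverted green channel with a disc brush: high for
#' thin dark curvilinear structures such as vessels, near zero on smooth
#' background.
#'
#' @param img RGB array or matrix in [0, 1].
#' @param brushRadius top-hat brush radius in pixels.
#' @return H x W matrix of non-negative responses.
#' @export
vesselnessResponse <- function(img, brushRadius = 3L) {
  g <- if (is.matrix(img)) img else img[, , 2]
  inv <- 1 - g
  sz <- 2L * as.integer(brushRadius) + 1L
  br <- EBImage::makeBrush(sz, shape = "disc")
  open <- EBImage::opening(asEB(inv), br)
  resp <- inv - fromEB(open)
  pmax(resp, 0)
}

#' Per-pixel clustering features
#'
#' For pixels whose vesselness exceeds `threshold` (disc pixels excluded),
#' builds the 4-vector (row/H, col/W, inverted green intensity, vesselness);
#' when more than `maxSamples` qualify, the strongest responses are kept.
#'
#' @param img RGB array or matrix in [0, 1].
#' @param discMask 0/1 matrix of disc pixels to exclude (optional).
#' @param threshold vesselness threshold for sampling.
#' @param maxSamples cap on the number of sampled pixels.
#' @param brushRadius passed to [vesselnessResponse].
#' @return list with `features` (n x 4 matrix), `pixels` (n x 2 matrix of
#'   row/col coordinates) and `vesselness` (full response map).
#' @export
pixelFeatures <- function(img, discMask = NULL, threshold = 0.08,
                          maxSamples = 3000L, brushRadius = 3L) {
  stopIfNotImage(img)
  g <- if (is.matrix(img)) img else img[, , 2]
  h <- nrow(g); w <- ncol(g)
  resp <- vesselnessResponse(img, brushRadius)
  if (!is.null(discMask)) resp[dilateMask(discMask > 0, 2L)] <- 0
  sel <- which(resp > threshold)
  if (length(sel) > maxSamples) {
    sel <- sel[order(resp[sel], decreasing = TRUE)[seq_len(maxSamples)]]
  }
  rows <- ((sel - 1L) %% h) + 1L
  cols <- ((sel - 1L) %/% h) + 1L
  feats <- cbind(row = (rows - 1) / h, col = (cols - 1) / w,
                 intensity = 1 - g[sel], vesselness = resp[sel])
  list(features = feats, pixels = cbind(row = rows, col = cols),
       vesselness = resp)
}

# Elongation of a pixel set: squared spatial diameter over area; large for
# thin curvilinear structures, near 1 for compact blobs.
clusterElongation <- function(px) {
  if (nrow(px) < 2L) return(0)
  rr <- range(px[, 1]); cr <- range(px[, 2])
  diam2 <- (rr[2] - rr[1])^2 + (cr[2] - cr[1])^2
  diam2 / nrow(px)
}

#' Segment blood vessels by density-based clustering
#'
#' Pipeline: optic-disc removal, vesselness-guided pixel sampling, OPTICS
#' ordering, reachability-cut cluster extraction, merging of clusters whose
#' dilated pixel footprints are close in Jaccard distance, and an elongation
#' filter that keeps curvilinear clusters only; kept clusters are rasterized
#' into the vessel mask.
#'
#' @param img RGB array or matrix in [0, 1] (ideally preprocessed).
#' @param MinPts,eps OPTICS parameters (feature space: spatial coordinates
#'   normalized to [0, 1], inverted green, vesselness).
#' @param extractionThreshold reachability cut for cluster extraction.
#' @param maxSamples cap on clustered pixel samples.
#' @param vesselnessThreshold sampling threshold on the top-hat response.
#' @param mergeJaccard clusters with Jaccard distance below this (on
#'   footprints dilated by 1 px) are merged.
#' @param minElongation minimum [clusterElongation] to count as vessel.
#' @param discMask optional known disc mask; when `NULL` the disc is
#'   detected and removed first.
#' @return a [VesselSegmentation-class].
#' @export
segmentVessels <- function(img, MinPts = 5L, eps = 0.08,
                           extractionThreshold = 0.06, maxSamples = 3000L,
                           vesselnessThreshold = 0.08, mergeJaccard = 0.3,
                           minElongation = 3.5, discMask = NULL) {
  stopIfNotImage(img)
  if (is.null(discMask)) {
    dr <- suppressWarnings(removeOpticDisc(img))
    img <- dr$image
    discMask <- dr$discMask
  }
  h <- if (is.matrix(img)) nrow(img) else dim(img)[1]
  w <- if (is.matrix(img)) ncol(img) else dim(img)[2]
  pf <- pixelFeatures(img, discMask, threshold = vesselnessThreshold,
                      maxSamples = maxSamples)
  n <- nrow(pf$features)
  vmask <- matrix(0, h, w)
  if (n == 0L) {
    return(new("VesselSegmentation", vesselMask = vmask,
               clusterLabels = integer(0), discMask = discMask,
               samples = pf$features))
  }
  prof <- opticsOrder(pf$features, MinPts = MinPts, eps = eps)
  labels <- extractClusters(prof, extractionThreshold)

  # merge clusters whose dilated spatial footprints overlap heavily
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) > 1L) {
    foot <- lapply(ids, function(k) {
      m <- matrix(0, h, w)
      m[pf$pixels[labels == k, , drop = FALSE]] <- 1
      which(dilateMask(m > 0, 1L))
    })
    parent <- seq_along(ids)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
      if (jaccardDistance(foot[[a]], foot[[b]]) < mergeJaccard) {
        parent[findRoot(a)] <- findRoot(b)
      }
    }
    remap <- vapply(seq_along(ids), findRoot, integer(1))
    labels[labels > 0] <- match(remap, sort(unique(remap)))[
      match(labels[labels > 0], ids)]
  }

  for (k in sort(unique(labels[labels > 0]))) {
    px <- pf$pixels[labels == k, , drop = FALSE]
    if (clusterElongation(px) >= minElongation) vmask[px] <- 1
  }
  vmask[discMask > 0] <- 0
  new("VesselSegmentation", vesselMask = vmask,
      clusterLabels = as.integer(labels), discMask = discMask,
      samples = pf$features)
}

setMethod("show", "VesselSegmentation", function(object) {
  nc <- length(unique(object@clusterLabels[object@clusterLabels > 0]))
  cat(sprintf("VesselSegmentation: %d vessel px, %d clusters, %d samples\n",
      sum(object@vesselMask), nc, nrow(object@samples)))
})
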