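#' @include vessels.R
NULL

#' Detect lesion candidates
#'
#' Dark-red candidates (microaneurysms, hemorrhages) are pixels both below
#' the `darkPercentile` quantile of the green channel and below the absolute
#' level `darkAbs`; bright candidates (hard exudates) are pixels above the
#' `brightPercentile` quantile of luminance and above `brightAbs` with a
#' yellowish hue.  Vessel and disc pixels (dilated by `excludeDilate`) are
#' excluded before 8-connectivity labelling.  Dark components of area at
#' most `maSizeGate` px^2 are typed `MA`, larger ones `HE`; bright
#' components are `EX`.
#'
#' @param img RGB array in [0, 1].
#' @param segmentation a [VesselSegmentation-class] (or `NULL` to segment
#'   internally).
#' @param darkPercentile,darkAbs gates for dark lesions.
#' @param brightPercentile,brightAbs gates for bright lesions.
#' @param maSizeGate area gate separating MA from HE, in px^2.
#' @param minArea discard components smaller than this (noise specks).
#' @param excludeDilate dilation radius applied to vessel/disc masks before
#'   exclusion.
#' @return list with `regions` (data.frame: type, row, col, area,
#'   eccentricity, theta, meanR, meanG, meanB) and `pixels` (list of pixel
#'   index vectors, one per region).
#' @export
detectCandidates <- function(img, segmentation = NULL, darkPercentile = 0.1,
                             darkAbs = 0.1, brightPercentile = 0.97,
                             brightAbs = 0.72, maSizeGate = 30,
                             minArea = 2, excludeDilate = 1L) {
  stopIfNotImage(img)
  if (is.null(segmentation)) segmentation <- segmentVessels(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  excl <- dilateMask(segmentation@vesselMask > 0, excludeDilate) |
          dilateMask(segmentation@discMask > 0, excludeDilate + 1L)
  g <- img[, , 2]
  lum <- luminance(img)
  dark <- (g < quantile(g, darkPercentile)) & (g < darkAbs) & !excl
  bright <- (lum > quantile(lum, brightPercentile)) & (lum > brightAbs) & !excl
  # yellow hue: red and green high, blue clearly lower
  yellow <- bright & (img[, , 3] < 0.6 * (img[, , 1] + img[, , 2]) / 2)

  regions <- list(); pixels <- list(); k <- 0L
  harvest <- function(mask, kindOfDark) {
    lab <- labelComponents(mask)
    nlab <- max(lab)
    if (nlab == 0) return()
    mom <- EBImage::computeFeatures.moment(EBImage::Image(t(lab)))
    if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                         dimnames = list(NULL, names(mom)))
    for (j in seq_len(nlab)) {
      px <- which(lab == j)
      area <- length(px)
      if (area < minArea) next
      k <<- k + 1L
      type <- if (!kindOfDark) "EX" else if (area <= maSizeGate) "MA" else "HE"
      regions[[k]] <<- data.frame(type = type,
        row = mom[j, "m.cy"], col = mom[j, "m.cx"], area = area,
        eccentricity = mom[j, "m.eccentricity"], theta = mom[j, "m.theta"],
        meanR = mean(img[, , 1][px]), meanG = mean(img[, , 2][px]),
        meanB = mean(img[, , 3][px]), stringsAsFactors = FALSE)
      pixels[[k]] <<- px
    }
  }
  harvest(dark, TRUE)
  harvest(yellow, FALSE)
  regions <- if (k > 0) do.call(rbind, regions) else
    data.frame(type = character(), row = numeric(), col = numeric(),
               area = numeric(), eccentricity = numeric(), theta = numeric(),
               meanR = numeric(), meanG = numeric(), meanB = numeric())
  list(regions = regions, pixels = pixels, imageDim = c(h, w))
}

#' Names of the lesion feature vector entries
#'
#' Fixed schema (version 1): counts, area fractions, shape statistics, an
#' 8-bin orientation histogram, colour statistics and vessel density.
#' @return character vector of length 40.
#' @export
featureSchema <- function() {
  c("ma_count", "he_count", "ex_count", "lesion_area_fraction",
    "macular_lesion_count", "mean_eccentricity", "mean_circularity",
    paste0("orient_bin_", 1:8),
    paste0("lesion_", c("R", "G", "B", "H", "S", "V"), "_mean"),
    paste0("lesion_", c("R", "G", "B", "H", "S", "V"), "_sd"),
    paste0("background_", c("R", "G", "B", "H", "S", "V"), "_mean"),
    paste0("background_", c("R", "G", "B", "H", "S", "V"), "_sd"),
    "vessel_density")
}

#' Lesion feature vector
#'
#' Fixed-schema vector of structural (per-type counts, total lesion area
#' fraction, macular lesion count), shape (mean eccentricity and
#' circularity), orientation (8-bin histogram of region major-axis angles)
#' and colour (mean/sd of RGB and HSV channels inside lesions and in the
#' background) features, plus the vessel density.  Deterministic and
#' invariant to candidate ordering.
#'
#' @param img RGB array in [0, 1].
#' @param candidates result of [detectCandidates()].
#' @param segmentation a [VesselSegmentation-class].
#' @param maculaMask optional ground-truth macula mask; when `NULL` the
#'   macula is estimated 2.5 disc-diameters temporal to the detected disc.
#' @return named numeric vector of length `length(featureSchema())` (40).
#' @export
lesionFeatures <- function(img, candidates, segmentation, maculaMask = NULL) {
  h <- dim(img)[1]; w <- dim(img)[2]
  reg <- candidates$regions
  schema <- featureSchema()
  out <- setNames(numeric(length(schema)), schema)
  n <- nrow(reg)
  out["ma_count"] <- sum(reg$type == "MA")
  out["he_count"] <- sum(reg$type == "HE")
  out["ex_count"] <- sum(reg$type == "EX")
  out["lesion_area_fraction"] <- sum(reg$area) / (h * w)
  if (is.null(maculaMask)) maculaMask <- estimateMacula(segmentation@discMask, h, w)
  if (n > 0) {
    inMac <- maculaMask[cbind(pmin(pmax(round(reg$row), 1), h),
                              pmin(pmax(round(reg$col), 1), w))] > 0
    out["macular_lesion_count"] <- sum(inMac)
    out["mean_eccentricity"] <- mean(reg$eccentricity)
    # circularity from moments: 1 for a disc, -> 0 with elongation
    out["mean_circularity"] <- mean(sqrt(1 - reg$eccentricity^2))
    ang <- (reg$theta %% pi) / pi             # axis angle folded to [0, 1)
    bins <- pmin(floor(ang * 8) + 1L, 8L)
    out[paste0("orient_bin_", 1:8)] <- tabulate(bins, 8L)
  }
  hsv <- rgbToHsv(img)
  lesionPx <- unlist(candidates$pixels)
  chans <- list(R = img[, , 1], G = img[, , 2], B = img[, , 3],
                H = hsv[, , 1], S = hsv[, , 2], V = hsv[, , 3])
  bgMask <- rep(TRUE, h * w)
  bgMask[lesionPx] <- FALSE
  for (nm in names(chans)) {
    v <- as.vector(chans[[nm]])
    if (length(lesionPx) > 0) {
      out[paste0("lesion_", nm, "_mean")] <- mean(v[lesionPx])
      out[paste0("lesion_", nm, "_sd")] <- if (length(lesionPx) > 1) sd(v[lesionPx]) else 0
    }
    out[paste0("background_", nm, "_mean")] <- mean(v[bgMask])
    out[paste0("background_", nm, "_sd")] <- sd(v[bgMask])
  }
  out["vessel_density"] <- mean(segmentation@vesselMask)
  out
}

# Fovea assumed 2.5 disc-diameters temporal (toward the image centre) to the
# detected disc; macular radius = one disc diameter.
estimateMacula <- function(discMask, h, w) {
  px <- which(discMask > 0)
  if (!length(px)) return(matrix(0, h, w))
  rows <- ((px - 1L) %% h) + 1L
  cols <- ((px - 1L) %/% h) + 1L
  ctr <- c(mean(rows), mean(cols))
  diam <- 2 * sqrt(length(px) / pi)
  dir <- if (ctr[2] <= w / 2) 1 else -1
  fovea <- c(row = ctr[1], col = ctr[2] + dir * 2.5 * diam)
  discMaskAt(h, w, fovea, diam)
}

#' Cosine similarity between two feature vectors
#'
#' @param i,j numeric vectors of equal length with nonzero norms.
#' @return dot(i, j) / (||i|| ||j||), in [-1, 1].
#' @examples
#' cosineSimilarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(i, j) {
  if (length(i) != length(j)) stop("vectors must have equal dimension")
  ni <- sqrt(sum(i^2)); nj <- sqrt(sum(j^2))
  if (ni == 0 || nj == 0) stop("zero-norm input")
  sum(i * j) / (ni * nj)
}
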