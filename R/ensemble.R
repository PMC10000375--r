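#' @include architecture.R features.R
NULL

PLANE_NAMES <- c("R", "G", "B", "vesselness", "lesionprob")

#' Derived input planes for the classifier
#'
#' Stacks the three colour channels with two derived cue maps: the
#' vesselness (thin-dark-structure) response and a lesion-probability cue
#' combining yellow-deposit evidence (exudates) with dark-red evidence
#' (microaneurysms/hemorrhages).  These are the `R` input planes the random
#' subspaces sample from.
#'
#' @param img RGB array in [0, 1].
#' @return H x W x 5 array; plane names in `attr(, "planes")`.
#' @export
fundusPlanes <- function(img) {
  stopIfNotImage(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- array(0, dim = c(h, w, 5))
  out[, , 1:3] <- img
  out[, , 4] <- clip01(3 * vesselnessResponse(img, brushRadius = 2L))
  yellow <- clip01(2 * ((img[, , 1] + img[, , 2]) / 2 - img[, , 3] - 0.25))
  darkred <- clip01(3 * (0.25 - img[, , 2]))
  out[, , 5] <- pmax(yellow, darkred)
  attr(out, "planes") <- PLANE_NAMES
  out
}

#' Stack images into a training tensor
#' @param images list of [LabeledFundus-class] or RGB arrays.
#' @param planes when `TRUE` (default) expand each image to its 5 input
#'   planes via [fundusPlanes()].
#' @return H x W x C x N array.
#' @export
stackPlanes <- function(images, planes = TRUE) {
  arrs <- lapply(images, function(im) {
    a <- if (is(im, "LabeledFundus")) fundusImage(im) else im
    if (planes) fundusPlanes(a) else a
  })
  d <- dim(arrs[[1]])
  x <- array(0, dim = c(d, length(arrs)))
  for (i in seq_along(arrs)) x[, , , i] <- arrs[[i]]
  x
}

#' Sample random input subspaces
#'
#' Each of the `L` members receives a uniform random subset of
#' `ceiling(rFraction * R)` of the `R` input planes; planes outside a
#' member's mask are zeroed at its input.
#'
#' @param R number of input planes.
#' @param rFraction fraction of planes per member, in (0, 1].
#' @param L ensemble size.
#' @param seed integer seed.
#' @return list of `L` sorted integer vectors.
#' @export
sampleSubspaces <- function(R, rFraction, L, seed = 0L) {
  if (R < 1L) stop("'R' must be >= 1")
  if (rFraction <= 0 || rFraction > 1) stop("'rFraction' must be in (0, 1]")
  k <- ceiling(rFraction * R)
  withSeed(seed, lapply(seq_len(L), function(i) sort(sample.int(R, k))))
}

#' Label-preserving geometric augmentation
#'
#' Random rotation, width/height shift, shear, zoom, and horizontal flip,
#' each drawn within the configured ranges; with all ranges zero (and
#' `hflip = FALSE`) the image is returned unchanged.  Bilinear resampling
#' with edge clamping.
#'
#' @param img RGB array or matrix in [0, 1].
#' @param rotation max |rotation| in degrees.
#' @param widthShift,heightShift max |shift| as a fraction of size.
#' @param shear max |shear| in degrees.
#' @param zoom max |log-zoom| deviation (0.1 = up to +/-10 percent).
#' @param hflip allow a fair-coin horizontal flip.
#' @param seed optional seed for the draws.
#' @return augmented image of the same shape.
#' @export
augmentImage <- function(img, rotation = 0, widthShift = 0, heightShift = 0,
                         shear = 0, zoom = 0, hflip = FALSE, seed = NULL) {
  stopIfNotImage(img)
  doDraw <- function() {
    th <- runif(1, -rotation, rotation) * pi / 180
    sh <- runif(1, -shear, shear) * pi / 180
    zx <- exp(runif(1, -zoom, zoom))
    dx <- runif(1, -widthShift, widthShift)
    dy <- runif(1, -heightShift, heightShift)
    fl <- hflip && runif(1) < 0.5
    list(th = th, sh = sh, zx = zx, dx = dx, dy = dy, fl = fl)
  }
  pars <- if (is.null(seed)) doDraw() else withSeed(seed, doDraw())
  if (pars$th == 0 && pars$sh == 0 && pars$zx == 1 && pars$dx == 0 &&
      pars$dy == 0 && !pars$fl) {
    return(img)
  }
  h <- if (is.matrix(img)) nrow(img) else dim(img)[1]
  w <- if (is.matrix(img)) ncol(img) else dim(img)[2]
  # inverse map output (r, c) -> input coordinates, about the image centre
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w) - cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  if (pars$fl) cc <- -cc
  # inverse of rotate(th) . shear(sh) . zoom is applied as combined matrix
  a11 <- cos(-pars$th) / pars$zx
  a12 <- -sin(-pars$th) / pars$zx + tan(-pars$sh)
  a21 <- sin(-pars$th) / pars$zx
  a22 <- cos(-pars$th) / pars$zx
  srcR <- a11 * rr + a12 * cc + cy - pars$dy * h
  srcC <- a21 * rr + a22 * cc + cx - pars$dx * w
  sampleBilinear <- function(m) {
    r0 <- pmin(pmax(floor(srcR), 1), h); r1 <- pmin(r0 + 1, h)
    c0 <- pmin(pmax(floor(srcC), 1), w); c1 <- pmin(c0 + 1, w)
    fr <- pmin(pmax(srcR - r0, 0), 1); fc <- pmin(pmax(srcC - c0, 0), 1)
    m[cbind(c(r0), c(c0))] * (1 - fr) * (1 - fc) +
      m[cbind(c(r1), c(c0))] * fr * (1 - fc) +
      m[cbind(c(r0), c(c1))] * (1 - fr) * fc +
      m[cbind(c(r1), c(c1))] * fr * fc
  }
  if (is.matrix(img)) {
    return(matrix(sampleBilinear(img), h, w))
  }
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- matrix(sampleBilinear(img[, , ch]), h, w)
  }
  out
}

maskPlanes <- function(x, mask) {
  drop <- setdiff(seq_len(dim(x)[3]), mask)
  if (length(drop)) x[, , drop, ] <- 0
  x
}

#' Train one ensemble member
#'
#' Zeroes the input planes outside the member's subspace mask and trains
#' the CNN with softmax cross-entropy and Adam (default learning rate 1e-3,
#' batch 32).
#'
#' @param x H x W x R x N array of input planes, values in [0, 1].
#' @param y integer class labels in 1..M.
#' @param arch a `"CNNArchitecture"` built for `c(H, W, R)`.
#' @param mask integer vector of selected planes.
#' @param epochs,batchSize,lr training hyperparameters.
#' @param seed integer seed (weight init + shuffling).
#' @return list with `weights`, `loss` (per-epoch mean), `mask`, `arch`.
#' @export
trainMember <- function(x, y, arch, mask, epochs = 15L, batchSize = 32L,
                        lr = 1e-3, seed = 0L) {
  stopifnot(inherits(arch, "CNNArchitecture"))
  if (min(x) < 0 || max(x) > 1) stop("inputs must be normalized to [0, 1]")
  xm <- maskPlanes(x, mask)
  w0 <- .cnnInit(arch, arch$inputShape, as.integer(seed))
  fit <- .cnnTrain(xm, as.integer(y), arch, arch$inputShape, w0,
                   as.integer(epochs), as.integer(batchSize), lr,
                   as.integer(seed) + 1L)
  list(weights = fit$weights, loss = as.numeric(fit$loss), mask = mask,
       arch = arch)
}

#' Train the random-subspace CNN ensemble
#'
#' Trains `L` members, each on its own random subset of input planes, and
#' sets the fusion weights: uniform `1/L` by default, or proportional to
#' held-out validation accuracy when `weighting = "validation"`.
#'
#' @param x H x W x R x N array of input planes.
#' @param y integer labels in 1..M or a factor.
#' @param classNames class names in label order.
#' @param L ensemble size.
#' @param rFraction fraction of planes per member.
#' @param scale width multiplier for [buildArchitecture()].
#' @param epochs,batchSize,lr training hyperparameters.
#' @param weighting `"uniform"` or `"validation"`.
#' @param valFraction held-out fraction for validation weighting.
#' @param seed integer seed controlling subspaces, member init and shuffling.
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(x, y, classNames = NULL, L = 3L, rFraction = 0.8,
                          scale = 0.125, epochs = 15L, batchSize = 32L,
                          lr = 1e-3, weighting = c("uniform", "validation"),
                          valFraction = 0.2, seed = 0L) {
  weighting <- match.arg(weighting)
  if (is.factor(y)) {
    if (is.null(classNames)) classNames <- levels(y)
    y <- as.integer(y)
  }
  d <- dim(x)
  R <- d[3]
  M <- max(y)
  if (is.null(classNames)) classNames <- paste0("class", seq_len(M))
  arch <- buildArchitecture(c(d[1], d[2], R), M = M, scale = scale)
  masks <- sampleSubspaces(R, rFraction, L, seed = seed)

  trainIdx <- seq_len(d[4]); valIdx <- integer(0)
  if (weighting == "validation") {
    valIdx <- withSeed(seed + 17L,
      sample.int(d[4], max(1L, round(valFraction * d[4]))))
    trainIdx <- setdiff(trainIdx, valIdx)
  }
  xt <- x[, , , trainIdx, drop = FALSE]
  members <- vector("list", L)
  logs <- vector("list", L)
  for (j in seq_len(L)) {
    members[[j]] <- trainMember(xt, y[trainIdx], arch, masks[[j]],
                                epochs = epochs, batchSize = batchSize,
                                lr = lr, seed = seed + 1000L * j)
    logs[[j]] <- members[[j]]$loss
  }
  if (weighting == "validation") {
    acc <- vapply(members, function(mb) {
      s <- memberScores(mb, x[, , , valIdx, drop = FALSE])
      mean(max.col(s, ties.method = "first") == y[valIdx])
    }, numeric(1))
    wts <- if (sum(acc) == 0) rep(1 / L, L) else acc / sum(acc)
  } else {
    wts <- rep(1 / L, L)
  }
  new("EnsembleModel", members = members, subspaceMasks = masks,
      weights = wts, classNames = classNames, planeNames = PLANE_NAMES[
        seq_len(min(R, length(PLANE_NAMES)))], trainingLog = logs)
}

memberScores <- function(member, x, batchSize = 32L) {
  xm <- maskPlanes(x, member$mask)
  .cnnPredict(xm, member$arch, member$arch$inputShape, member$weights,
              as.integer(batchSize))
}

#' Predict with the ensemble
#'
#' Member softmax scores are fused by the weighted average
#' \eqn{G = \sum_j w_j s_j}; the predicted class is `argmax G` with ties
#' broken toward the lowest class index.
#'
#' @param model an [EnsembleModel-class].
#' @param x H x W x R x N array of input planes (or a single H x W x R
#'   image).
#' @return list with `scores` (N x M fused matrix `G`), `memberScores`
#'   (list of per-member N x M matrices), `class` (predicted labels).
#' @export
predictEnsemble <- function(model, x) {
  stopifnot(is(model, "EnsembleModel"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  sj <- lapply(model@members, memberScores, x = x)
  G <- Reduce(`+`, Map(function(s, w) s * w, sj, model@weights))
  cls <- model@classNames[max.col(G, ties.method = "first")]
  colnames(G) <- model@classNames
  list(scores = G, memberScores = sj, class = cls)
}

#' Disagreement (diversity) between two classifiers
#'
#' The fraction of test samples on which the two predicted label sequences
#' differ; 0 for identical classifiers, 1 for total disagreement.
#'
#' @param labelsI,labelsJ predicted labels of the two members on the same
#'   test set.
#' @return a value in [0, 1].
#' @export
classifierDiversity <- function(labelsI, labelsJ) {
  if (length(labelsI) == 0L) stop("empty test set")
  if (length(labelsI) != length(labelsJ)) stop("label vectors differ in length")
  mean(labelsI != labelsJ)
}

#' Ensemble diversity
#'
#' Mean pairwise [classifierDiversity()] over all ordered member pairs
#' `i != j` on a common test set.
#'
#' @param model an [EnsembleModel-class] (L >= 2).
#' @param x H x W x R x N array of input planes.
#' @return a value in [0, 1].
#' @export
ensembleDiversity <- function(model, x) {
  L <- length(model@members)
  if (L < 2L) stop("ensemble diversity needs at least 2 members")
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  labels <- lapply(model@members, function(mb) {
    max.col(memberScores(mb, x), ties.method = "first")
  })
  tot <- 0; np <- 0L
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    tot <- tot + classifierDiversity(labels[[i]], labels[[j]])
    np <- np + 1L
  }
  tot / np
}

#' @rdname EnsembleModel-class
#' @aliases ensembleMembers,EnsembleModel-method
setMethod("ensembleMembers", "EnsembleModel", function(object) object@members)
#' @rdname EnsembleModel-class
setMethod("subspaceMasks", "EnsembleModel", function(object) object@subspaceMasks)
#' @rdname EnsembleModel-class
setMethod("fusionWeights", "EnsembleModel", function(object) object@weights)

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: L=%d members, classes [%s], weights [%s]\n",
      length(object@members), paste(object@classNames, collapse = ", "),
      paste(signif(object@weights, 3), collapse = ", ")))
})
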