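#' @include AllGenerics.R
NULL

#' OPTICS core distance
#'
#' Distance from sample `o` to its `MinPts`-th nearest neighbour (the point
#' itself counts as its own first neighbour, at distance 0), defined only
#' when the epsilon-neighbourhood of `o` holds at least `MinPts` samples;
#' `NA` otherwise.
#'
#' @param samples numeric matrix, one sample per row.
#' @param o sample index (1-based).
#' @param MinPts neighbour count (>= 2).
#' @param eps neighbourhood radius.
#' @return the core distance, or `NA` when undefined.
#' @examples
#' s <- matrix(c(0, 1, 2, 3), ncol = 1)
#' coreDistance(s, 2, MinPts = 2, eps = 5)  # 1
#' @export
coreDistance <- function(samples, o, MinPts, eps) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 1L) stop("'samples' must be nonempty")
  if (o < 1L || o > n) stop("sample index 'o' out of range")
  if (MinPts < 2L) stop("'MinPts' must be >= 2")
  if (eps <= 0) stop("'eps' must be > 0")
  d <- sqrt(colSums((t(samples) - samples[o, ])^2))
  inEps <- d <= eps
  if (sum(inEps) < MinPts) return(NA_real_)
  sort(d)[MinPts]
}

#' OPTICS reachability distance
#'
#' `max(coreDistance(o), D(p, o))`; undefined (`NA`) when `o` is not a core
#' point.
#'
#' @inheritParams coreDistance
#' @param p,o sample indices (1-based): `p` the point being reached, `o` the
#'   core candidate it is reached from.
#' @return the reachability distance, or `NA`.
#' @export
reachabilityDistance <- function(p, o, samples, MinPts, eps) {
  samples <- as.matrix(samples)
  if (p < 1L || p > nrow(samples)) stop("sample index 'p' out of range")
  cd <- coreDistance(samples, o, MinPts, eps)
  if (is.na(cd)) return(NA_real_)
  max(cd, sqrt(sum((samples[p, ] - samples[o, ])^2)))
}

#' OPTICS ordering of a sample set
#'
#' Standard OPTICS: unprocessed points are taken as seeds in index order;
#' while a seed's neighbourhood expands, the pending point with the smallest
#' tentative reachability (ties broken by lowest index) is processed next.
#' Reachability is `NA` for the first point of each connected expansion.
#'
#' @param samples numeric matrix, one sample per row.
#' @param MinPts neighbour count (>= 2).
#' @param eps neighbourhood radius.
#' @return a [ReachabilityProfile-class].
#' @export
opticsOrder <- function(samples, MinPts = 5L, eps = 0.05) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 1L) stop("'samples' must be nonempty")
  if (MinPts < 2L) stop("'MinPts' must be >= 2")
  if (eps <= 0) stop("'eps' must be > 0")
  st <- t(samples)

  distTo <- function(i) sqrt(colSums((st - samples[i, ])^2))
  core <- rep(NA_real_, n)
  processed <- rep(FALSE, n)
  reachTentative <- rep(Inf, n)
  order <- integer(0)
  reach <- numeric(0)

  processPoint <- function(i, rdist) {
    processed[i] <<- TRUE
    order[length(order) + 1L] <<- i
    reach[length(reach) + 1L] <<- rdist
    d <- distTo(i)
    nbr <- which(d <= eps)
    if (length(nbr) >= MinPts) {
      core[i] <<- sort(d[nbr])[MinPts]
      upd <- nbr[!processed[nbr]]
      newReach <- pmax(core[i], d[upd])
      better <- newReach < reachTentative[upd]
      reachTentative[upd[better]] <<- newReach[better]
    }
  }

  for (start in seq_len(n)) {
    if (processed[start]) next
    processPoint(start, NA_real_)
    repeat {
      pend <- which(!processed & is.finite(reachTentative))
      if (!length(pend)) break
      # smallest tentative reachability; ties -> lowest index (which.min
      # already returns the first minimum of the index-sorted vector)
      i <- pend[which.min(reachTentative[pend])]
      processPoint(i, reachTentative[i])
    }
  }
  new("ReachabilityProfile", order = order, reach = reach, core = core)
}

#' Extract clusters from a reachability profile
#'
#' Walks the ordering: a position whose reachability exceeds `threshold` (or
#' is undefined) closes the current cluster; if that position's point is a
#' core point it starts a new cluster, otherwise it is noise (-1).
#'
#' @param profile a [ReachabilityProfile-class].
#' @param threshold reachability cut.
#' @return integer labels per sample (original indexing); -1 marks noise.
#' @export
extractClusters <- function(profile, threshold) {
  stopifnot(is(profile, "ReachabilityProfile"))
  n <- length(profile@order)
  labels <- rep(-1L, n)
  cur <- 0L
  open <- FALSE
  for (pos in seq_len(n)) {
    i <- profile@order[pos]
    r <- profile@reach[pos]
    if (is.na(r) || r > threshold) {
      if (!is.na(profile@core[i]) && profile@core[i] <= threshold) {
        cur <- cur + 1L
        labels[i] <- cur
        open <- TRUE
      } else {
        open <- FALSE
      }
    } else if (open) {
      labels[i] <- cur
    }
  }
  labels
}

#' Jaccard distance between two index sets
#'
#' \eqn{JD(A, B) = 1 - |A \cap B| / |A \cup B|}; two empty sets have
#' distance 0.
#'
#' @param A,B vectors interpreted as finite sets.
#' @return a value in [0, 1].
#' @export
jaccardDistance <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) return(0)
  1 - length(intersect(A, B)) / u
}

#' @rdname ReachabilityProfile-class
#' @aliases opticsOrdering,ReachabilityProfile-method
setMethod("opticsOrdering", "ReachabilityProfile", function(object) object@order)
#' @rdname ReachabilityProfile-class
setMethod("reachDistances", "ReachabilityProfile", function(object) object@reach)
#' @rdname ReachabilityProfile-class
setMethod("coreDistances", "ReachabilityProfile", function(object) object@core)

setMethod("show", "ReachabilityProfile", function(object) {
  cat(sprintf("ReachabilityProfile: %d samples, %d core points\n",
      length(object@order), sum(!is.na(object@core))))
})
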