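#' @include AllGenerics.R
NULL

# Conditional entropy H(label | bin) in bits, with 0 log 0 = 0.
conditionalEntropy <- function(bins, labels) {
  n <- length(labels)
  H <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    p <- table(labels[sel]) / sum(sel)
    p <- p[p > 0]
    H <- H + (sum(sel) / n) * (-sum(p * log2(p)))
  }
  H
}

#' Fit severity thresholds by conditional-entropy minimization
#'
#' Exhaustively searches all cut-point pairs `t1 < t2` over the observed
#' lesion-count values, minimizing the conditional entropy of the severity
#' label given the three-bin discretization (counts <= t1 / (t1, t2] /
#' > t2).  Ties are broken toward the smallest `(t1, t2)`.
#'
#' @param counts integer lesion counts per image.
#' @param labels severity labels (at least two distinct values among at
#'   least three samples).
#' @return a [SeverityThresholds-class].
#' @examples
#' fitSeverityThresholds(c(1, 2, 5, 6, 12, 15),
#'                       c("mild", "mild", "moderate", "moderate",
#'                         "severe", "severe"))
#' @export
fitSeverityThresholds <- function(counts, labels) {
  if (length(counts) != length(labels)) stop("counts and labels must align")
  if (length(counts) < 3L) stop("need at least 3 samples")
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: need at least 2 distinct severity labels")
  }
  cand <- sort(unique(counts))
  best <- NULL
  for (a in seq_along(cand)) {
    for (b in seq_along(cand)) {
      if (b <= a) next
      t1 <- cand[a]; t2 <- cand[b]
      bins <- ifelse(counts <= t1, 1L, ifelse(counts <= t2, 2L, 3L))
      H <- conditionalEntropy(bins, labels)
      if (is.null(best) || H < best$H - 1e-12) {
        best <- list(t1 = t1, t2 = t2, H = H)
      }
    }
  }
  if (is.null(best)) stop("counts are degenerate: need >= 2 distinct values")
  new("SeverityThresholds", t1 = as.numeric(best$t1), t2 = as.numeric(best$t2),
      fittedEntropy = best$H, classNames = SEVERITY_LEVELS)
}

#' Grade severity from a lesion count
#'
#' `count <= t1` is mild, `t1 < count <= t2` moderate, `count > t2` severe;
#' monotone non-decreasing in the count.
#'
#' @param count non-negative integer count(s).
#' @param thresholds a [SeverityThresholds-class].
#' @return character vector of severity labels.
#' @export
gradeSeverity <- function(count, thresholds) {
  stopifnot(is(thresholds, "SeverityThresholds"))
  if (any(count < 0)) stop("'count' must be >= 0")
  ifelse(count <= thresholds@t1, "mild",
         ifelse(count <= thresholds@t2, "moderate", "severe"))
}

#' Simulate lesion-count/severity training data
#'
#' Draws true lesion counts uniformly on 1..15, assigns the generator's
#' severity convention (mild 1-3, moderate 4-9, severe >= 10), and reports
#' counts observed with additive rounded Gaussian noise of standard
#' deviation `sigma` (floored at 0).
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param sigma count-noise standard deviation.
#' @return data.frame with `count` (observed) and `severity` (true label).
#' @export
simulateSeverityCounts <- function(n, seed = 0L, sigma = 1) {
  withSeed(seed, {
    true <- sample(1:15, n, replace = TRUE)
    sev <- ifelse(true <= 3, "mild", ifelse(true <= 9, "moderate", "severe"))
    obs <- pmax(0L, as.integer(round(true + rnorm(n, sd = sigma))))
    data.frame(count = obs, severity = sev, stringsAsFactors = FALSE)
  })
}

setMethod("show", "SeverityThresholds", function(object) {
  cat(sprintf("SeverityThresholds: t1=%g t2=%g (H = %.4f bits)\n",
      object@t1, object@t2, object@fittedEntropy))
})
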