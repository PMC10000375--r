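#' @include AllClasses.R
NULL

#' One-vs-rest confusion counts
#'
#' @param truth,pred label vectors of equal length.
#' @param positive the class treated as positive.
#' @return named list with `T1` (true positives), `T2` (true negatives),
#'   `F1` (false positives), `F2` (false negatives).
#' @export
confusionCounts <- function(truth, pred, positive) {
  if (length(truth) != length(pred)) stop("truth and pred must align")
  tp <- truth == positive; pp <- pred == positive
  list(T1 = sum(tp & pp), T2 = sum(!tp & !pp),
       F1 = sum(!tp & pp), F2 = sum(tp & !pp))
}

#' Classification accuracy
#'
#' `(T1 + T2) / (T1 + T2 + F1 + F2)`.
#' @param c confusion counts (see [confusionCounts()]).
#' @return accuracy in [0, 1].
#' @export
accuracy <- function(c) {
  tot <- c$T1 + c$T2 + c$F1 + c$F2
  if (tot == 0) stop("empty confusion counts")
  (c$T1 + c$T2) / tot
}

#' Precision (positive predictive value)
#'
#' `T1 / (T1 + F1)`; `NA` (not applicable) when nothing was predicted
#' positive, and such classes are excluded from macro averages.
#' @inheritParams accuracy
#' @return precision in [0, 1], or `NA`.
#' @export
precisionScore <- function(c) {
  den <- c$T1 + c$F1
  if (den == 0) return(NA_real_)
  c$T1 / den
}

#' Recall (sensitivity)
#'
#' `T1 / (T1 + F2)`; `NA` when the class has no positive samples.
#' @inheritParams accuracy
#' @return recall in [0, 1], or `NA`.
#' @export
recallScore <- function(c) {
  den <- c$T1 + c$F2
  if (den == 0) return(NA_real_)
  c$T1 / den
}

#' F-score (harmonic mean of precision and recall)
#'
#' `2 p r / (p + r)`; defined as 0 when both are 0.
#' @param p,r precision and recall.
#' @return the F-score.
#' @export
fScore <- function(p, r) {
  if (is.na(p) || is.na(r)) return(NA_real_)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Error rate
#'
#' `nErrors / nSamples`; complements accuracy when errors are
#' misclassifications.
#' @param nErrors number of errors.
#' @param nSamples number of samples (> 0).
#' @return the error rate.
#' @export
errorRate <- function(nErrors, nSamples) {
  if (nSamples <= 0) stop("'nSamples' must be > 0")
  nErrors / nSamples
}

#' Evaluate multi-class predictions
#'
#' One-vs-rest confusion counts per class with macro averaging (unweighted
#' mean over classes whose metric is defined), overall accuracy and error
#' rate, and the confusion matrix.
#'
#' @param truth,pred label vectors.
#' @param classes class order (defaults to the sorted union).
#' @return list of class `"EvalReport"`: `confusion`, `perClass`
#'   (data.frame), `macro`, `accuracy`, `errorRate`, `n`.
#' @export
evaluatePredictions <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(union(unique(truth), unique(pred)))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  per <- lapply(classes, function(cl) {
    cc <- confusionCounts(truth, pred, cl)
    p <- precisionScore(cc); r <- recallScore(cc)
    data.frame(class = cl, accuracy = accuracy(cc), precision = p,
               recall = r, fscore = fScore(p, r), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  macro <- c(accuracy = mean(per$accuracy, na.rm = TRUE),
             precision = mean(per$precision, na.rm = TRUE),
             recall = mean(per$recall, na.rm = TRUE),
             fscore = mean(per$fscore, na.rm = TRUE))
  acc <- mean(as.character(truth) == as.character(pred))
  structure(list(confusion = cm, perClass = per, macro = macro,
                 accuracy = acc, errorRate = 1 - acc, n = length(truth)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: n=%d accuracy=%.4f errorRate=%.4f\n",
              x$n, x$accuracy, x$errorRate))
  print(x$confusion)
  print(x$perClass, row.names = FALSE)
  invisible(x)
}
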