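#' @include utils.R
NULL

VALID_CLASSES <- c("normal", "DR", "DME")
SEVERITY_LEVELS <- c("mild", "moderate", "severe")
LESION_TYPES <- c("MA", "HE", "EX")

#' Specification of a synthetic fundus image
#'
#' Describes everything needed to regenerate a labeled fundus deterministically:
#' geometry, class, lesion counts, vessel-tree depth, and corruption levels.
#'
#' @slot height,width image size in pixels (>= 64).
#' @slot classLabel one of `"normal"`, `"DR"`, `"DME"`.
#' @slot nMicroaneurysms,nHemorrhages,nExudates lesion counts.
#' @slot vesselDepth recursion depth of the binary vessel tree.
#' @slot noiseDensity fraction of impulse (salt-and-pepper) pixels in [0, 1].
#' @slot illuminationStrength strength of the multiplicative illumination ramp.
#' @slot blurSigma Gaussian blur sigma in pixels.
#' @slot seed integer generation seed.
#' @export
setClass("FundusSpec",
  representation(height = "integer", width = "integer", classLabel = "character",
    nMicroaneurysms = "integer", nHemorrhages = "integer", nExudates = "integer",
    vesselDepth = "integer", noiseDensity = "numeric",
    illuminationStrength = "numeric", blurSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@height < 64L) msg <- c(msg, "height must be >= 64")
    if (object@width < 64L) msg <- c(msg, "width must be >= 64")
    if (!object@classLabel %in% VALID_CLASSES)
      msg <- c(msg, "classLabel must be one of normal, DR, DME")
    counts <- c(object@nMicroaneurysms, object@nHemorrhages, object@nExudates)
    if (any(counts < 0L)) msg <- c(msg, "lesion counts must be >= 0")
    if (object@classLabel == "normal" && any(counts > 0L))
      msg <- c(msg, "classLabel 'normal' requires all lesion counts to be 0")
    if (object@classLabel == "DME" && object@nExudates < 1L)
      msg <- c(msg, "classLabel 'DME' requires nExudates >= 1")
    if (object@classLabel == "DR" && sum(counts) < 1L)
      msg <- c(msg, "classLabel 'DR' requires total lesion count >= 1")
    if (object@vesselDepth < 1L) msg <- c(msg, "vesselDepth must be >= 1")
    if (object@noiseDensity < 0 || object@noiseDensity > 1)
      msg <- c(msg, "noiseDensity must be in [0, 1]")
    if (object@illuminationStrength < 0)
      msg <- c(msg, "illuminationStrength must be >= 0")
    if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' A labeled synthetic fundus image
#'
#' The rendered RGB image together with the ground-truth vessel, optic-disc,
#' macula and per-lesion-type masks, the class and severity labels, and the
#' generating [FundusSpec-class].
#'
#' @slot image H x W x 3 array in [0, 1].
#' @slot vesselMask,discMask,maculaMask H x W 0/1 matrices.
#' @slot lesionMasks named list of H x W 0/1 matrices (`MA`, `HE`, `EX`).
#' @slot classLabel,severityLabel character labels; severity is `"none"` for
#'   lesion-free images.
#' @slot spec the generating [FundusSpec-class].
#' @export
setClass("LabeledFundus",
  representation(image = "array", vesselMask = "matrix", discMask = "matrix",
    maculaMask = "matrix", lesionMasks = "list", classLabel = "character",
    severityLabel = "character", spec = "FundusSpec"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "image must be H x W x 3")
    masks <- c(list(object@vesselMask, object@discMask, object@maculaMask),
               object@lesionMasks)
    for (m in masks) {
      if (!all(dim(m) == d[1:2])) msg <- c(msg, "all masks must match image H x W")
      if (!all(m %in% c(0, 1))) msg <- c(msg, "mask values must be 0/1")
    }
    if (!setequal(names(object@lesionMasks), LESION_TYPES))
      msg <- c(msg, "lesionMasks must be named MA, HE, EX")
    if (!object@severityLabel %in% c(SEVERITY_LEVELS, "none"))
      msg <- c(msg, "severityLabel must be mild/moderate/severe/none")
    if (length(msg)) msg else TRUE
  })

#' Harris hawks optimization configuration
#'
#' @slot PS population size (>= 2).
#' @slot Tm maximum number of iterations (>= 1).
#' @slot lb,ub per-dimension lower/upper bounds (`lb < ub` elementwise).
#' @slot seed integer seed for the run.
#' @export
setClass("HHOConfig",
  representation(PS = "integer", Tm = "integer", lb = "numeric",
                 ub = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@PS < 2L) msg <- c(msg, "PS must be >= 2")
    if (object@Tm < 1L) msg <- c(msg, "Tm must be >= 1")
    if (length(object@lb) != length(object@ub))
      msg <- c(msg, "lb and ub must have equal length")
    else if (!all(object@lb < object@ub))
      msg <- c(msg, "lb must be < ub elementwise")
    if (length(msg)) msg else TRUE
  })

#' Result of a Harris hawks optimization run
#'
#' @slot bestPosition best position found.
#' @slot bestFitness its (minimized) objective value.
#' @slot history best-so-far fitness after each iteration (non-increasing).
#' @export
setClass("HHOResult",
  representation(bestPosition = "numeric", bestFitness = "numeric",
                 history = "numeric"),
  validity = function(object) {
    if (length(object@history) > 1L && any(diff(object@history) > 1e-12))
      "history must be non-increasing" else TRUE
  })

#' OPTICS reachability profile
#'
#' The OPTICS processing order with, per sample, its core distance and, per
#' ordered position, its reachability distance.  Undefined values (seed points
#' of the ordering; non-core points) are `NA`.
#'
#' @slot order permutation of sample indices (processing order, 1-based).
#' @slot reach reachability distance at each ordered position.
#' @slot core core distance per sample index.
#' @export
setClass("ReachabilityProfile",
  representation(order = "integer", reach = "numeric", core = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@order)
    if (!setequal(object@order, seq_len(n)))
      msg <- c(msg, "order must be a permutation of 1..n")
    if (length(object@reach) != n) msg <- c(msg, "reach must have length n")
    if (length(object@core) != n) msg <- c(msg, "core must have length n")
    # reach = max(core(predecessor), distance) by construction, hence >= 0;
    # a point's own core distance may exceed its reachability
    if (any(object@reach < 0, na.rm = TRUE))
      msg <- c(msg, "reach distances must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Vessel segmentation result
#'
#' @slot vesselMask H x W 0/1 matrix of vessel pixels.
#' @slot clusterLabels per-sample integer labels (-1 = noise).
#' @slot discMask H x W 0/1 matrix of the removed optic disc.
#' @slot samples matrix of sampled pixel features (row, col, intensity,
#'   vesselness), one row per clustered sample.
#' @export
setClass("VesselSegmentation",
  representation(vesselMask = "matrix", clusterLabels = "integer",
                 discMask = "matrix", samples = "matrix"),
  validity = function(object) {
    if (any(object@vesselMask * object@discMask > 0))
      "vesselMask and discMask must be disjoint" else TRUE
  })

#' Monotone contrast transform found by HHO
#'
#' The sigmoid-gamma intensity mapping
#' \eqn{T(v) = [1 / (1 + (m/(v+\epsilon))^\alpha)]^\gamma}, min-max rescaled to
#' [0, 1]; monotone non-decreasing for any parameters in the search box.
#'
#' @slot params named numeric vector (alpha, m, gamma); `NA` for the identity.
#' @slot fitness contrast fitness achieved on the enhanced image.
#' @slot bounds 2 x 3 matrix of the search bounds used.
#' @slot identity `TRUE` when the identity transform was returned.
#' @export
setClass("ContrastTransform",
  representation(params = "numeric", fitness = "numeric",
                 bounds = "matrix", identity = "logical"))

#' Random-subspace CNN ensemble
#'
#' @slot members list of trained CNN members (weights + architecture).
#' @slot subspaceMasks per-member integer vectors of selected input planes.
#' @slot weights fusion weights (non-negative, summing to 1).
#' @slot classNames class names in score order.
#' @slot planeNames names of the input planes the masks index.
#' @slot trainingLog list of per-member loss histories.
#' @export
setClass("EnsembleModel",
  representation(members = "list", subspaceMasks = "list", weights = "numeric",
    classNames = "character", planeNames = "character", trainingLog = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@members) != length(object@subspaceMasks))
      msg <- c(msg, "one subspace mask per member required")
    if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must be >= 0 and sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Severity grading thresholds
#'
#' Lesion-count cut points `t1 < t2`: counts <= t1 grade mild, counts in
#' (t1, t2] moderate, counts > t2 severe.
#'
#' @slot t1,t2 cut points (0 <= t1 < t2).
#' @slot fittedEntropy conditional entropy H(label | bin) at the optimum, bits.
#' @slot classNames the three severity class names.
#' @export
setClass("SeverityThresholds",
  representation(t1 = "numeric", t2 = "numeric", fittedEntropy = "numeric",
                 classNames = "character"),
  validity = function(object) {
    if (object@t1 < 0 || object@t1 >= object@t2)
      "thresholds must satisfy 0 <= t1 < t2" else TRUE
  })
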