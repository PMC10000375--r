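#' @include AllClasses.R
NULL

#' @describeIn LabeledFundus-class the rendered RGB array.
#' @param object a package object.
#' @export
setGeneric("fundusImage", function(object) standardGeneric("fundusImage"))
#' @describeIn LabeledFundus-class ground-truth vessel mask.
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))
#' @describeIn LabeledFundus-class ground-truth optic-disc mask.
#' @export
setGeneric("discMask", function(object) standardGeneric("discMask"))
#' @describeIn LabeledFundus-class ground-truth macula mask.
#' @export
setGeneric("maculaMask", function(object) standardGeneric("maculaMask"))
#' @describeIn LabeledFundus-class named list of per-lesion-type masks.
#' @export
setGeneric("lesionMasks", function(object) standardGeneric("lesionMasks"))
#' @describeIn LabeledFundus-class class label (normal/DR/DME).
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))
#' @describeIn LabeledFundus-class severity label (mild/moderate/severe/none).
#' @export
setGeneric("severityLabel", function(object) standardGeneric("severityLabel"))
#' @describeIn LabeledFundus-class the generating specification.
#' @export
setGeneric("fundusSpecOf", function(object) standardGeneric("fundusSpecOf"))

#' @describeIn HHOResult-class best position found.
#' @param object a package object.
#' @export
setGeneric("bestPosition", function(object) standardGeneric("bestPosition"))
#' @describeIn HHOResult-class best fitness found.
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))
#' @describeIn HHOResult-class best-so-far fitness per iteration.
#' @export
setGeneric("fitnessHistory", function(object) standardGeneric("fitnessHistory"))

#' @describeIn ReachabilityProfile-class the processing order.
#' @param object a package object.
#' @export
setGeneric("opticsOrdering", function(object) standardGeneric("opticsOrdering"))
#' @describeIn ReachabilityProfile-class reachability distances in order.
#' @export
setGeneric("reachDistances", function(object) standardGeneric("reachDistances"))
#' @describeIn ReachabilityProfile-class core distances per sample.
#' @export
setGeneric("coreDistances", function(object) standardGeneric("coreDistances"))

#' @describeIn EnsembleModel-class the trained members.
#' @param object a package object.
#' @export
setGeneric("ensembleMembers", function(object) standardGeneric("ensembleMembers"))
#' @describeIn EnsembleModel-class the per-member input-plane masks.
#' @export
setGeneric("subspaceMasks", function(object) standardGeneric("subspaceMasks"))
#' @describeIn EnsembleModel-class the fusion weights.
#' @export
setGeneric("fusionWeights", function(object) standardGeneric("fusionWeights"))
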