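#' @rdname PBMCExperiment-class
#' @param x a PBMCExperiment or Log2RatioExperiment.
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))

#' @rdname PBMCExperiment-class
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname PBMCExperiment-class
#' @export
setGeneric("expressionScale", function(x) standardGeneric("expressionScale"))

#' @rdname PBMCExperiment-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname Log2RatioExperiment-class
#' @param x a Log2RatioExperiment.
#' @export
setGeneric("log2Ratios", function(x) standardGeneric("log2Ratios"))

#' @rdname Log2RatioExperiment-class
#' @export
setGeneric("referenceGroup", function(x) standardGeneric("referenceGroup"))

#' @rdname Signature-class
#' @param x a Signature (or other object with probe ids).
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname Signature-class
#' @export
setGeneric("signatureEntries", function(x) standardGeneric("signatureEntries"))

#' @rdname PermutationFDR-class
#' @param x a PermutationFDR.
#' @export
setGeneric("fdrEstimate", function(x) standardGeneric("fdrEstimate"))

#' @rdname PermutationFDR-class
#' @export
setGeneric("nullHitCounts", function(x) standardGeneric("nullHitCounts"))

#' @rdname GeneSetCollection-class
#' @param x a GeneSetCollection.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname ClusteringResult-class
#' @param x a ClusteringResult.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname ClusteringResult-class
#' @export
setGeneric("clusterEnrichment", function(x) standardGeneric("clusterEnrichment"))
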