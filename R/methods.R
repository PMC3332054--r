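#' Construct a PBMCExperiment
#'
#' @param exprs numeric probe x sample matrix with unique rownames (probe ids)
#'   and colnames (sample ids).
#' @param detection optional matrix of detection p-values, same dimensions.
#' @param samples optional data.frame / DataFrame of per-sample annotation with
#'   a `sample_id` column (or rownames) matching `colnames(exprs)`; typically
#'   carries `group`, `age`, `sex` and the five leukocyte fractions.
#' @param scale `"linear"` or `"log2"`, the scale of `exprs`.
#' @return a [PBMCExperiment-class].
#' @examples
#' m <- matrix(2^rnorm(20, 8), 5, 4,
#'             dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
#' pe <- PBMCExperiment(m, scale = "linear")
#' @export
PBMCExperiment <- function(exprs, detection = NULL, samples = NULL,
                           scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("exprs must have probe ids as rownames and sample ids as colnames")
  assays <- list(exprs = exprs)
  if (!is.null(detection)) {
    if (!identical(dim(detection), dim(exprs)))
      stop("detection matrix dimensions must match exprs (probes x samples)")
    dimnames(detection) <- dimnames(exprs)
    assays$detection <- detection
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(exprs))
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    if ("sample_id" %in% colnames(samples)) {
      rownames(samples) <- samples$sample_id
    }
    missing <- setdiff(colnames(exprs), rownames(samples))
    if (length(missing))
      stop("sample sheet is missing samples: ", paste(missing, collapse = ", "))
    cd <- S4Vectors::DataFrame(samples[colnames(exprs), , drop = FALSE])
  }
  se <- SummarizedExperiment(assays = assays, colData = cd)
  metadata(se)$scale <- scale
  new("PBMCExperiment", se)
}

#' @rdname PBMCExperiment-class
#' @export
setMethod("exprs", "PBMCExperiment", function(x) assay(x, "exprs"))

#' @rdname PBMCExperiment-class
#' @export
setMethod("detectionP", "PBMCExperiment", function(x) {
  if (!"detection" %in% assayNames(x))
    stop("no detection p-values in this PBMCExperiment")
  assay(x, "detection")
})

#' @rdname PBMCExperiment-class
#' @export
setMethod("expressionScale", "PBMCExperiment", function(x) metadata(x)$scale)

.groupsOf <- function(x) {
  cd <- colData(x)
  if (!"group" %in% colnames(cd))
    stop("no 'group' column in colData; supply a sample sheet")
  as.character(cd$group)
}

#' @rdname PBMCExperiment-class
#' @export
setMethod("sampleGroups", "PBMCExperiment", function(x) .groupsOf(x))

#' @rdname Log2RatioExperiment-class
#' @export
setMethod("sampleGroups", "Log2RatioExperiment", function(x) .groupsOf(x))

#' Construct a Log2RatioExperiment from a ratio matrix
#'
#' Usually produced by [toLog2Ratio()]; this constructor serves workflows where
#' log2 ratios were computed elsewhere.
#'
#' @param values numeric probe x sample matrix of log2 ratios with dimnames.
#' @param samples per-sample annotation as in [PBMCExperiment()].
#' @param reference name of the reference group the ratios are relative to.
#' @return a [Log2RatioExperiment-class].
#' @export
Log2RatioExperiment <- function(values, samples = NULL, reference = "control") {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe ids as rownames and sample ids as colnames")
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    if ("sample_id" %in% colnames(samples)) rownames(samples) <- samples$sample_id
    cd <- S4Vectors::DataFrame(samples[colnames(values), , drop = FALSE])
  }
  se <- SummarizedExperiment(assays = list(log2ratio = values), colData = cd)
  metadata(se)$reference <- reference
  new("Log2RatioExperiment", se)
}

#' @rdname Log2RatioExperiment-class
#' @export
setMethod("log2Ratios", "Log2RatioExperiment", function(x) assay(x, "log2ratio"))

#' @rdname Log2RatioExperiment-class
#' @export
setMethod("referenceGroup", "Log2RatioExperiment", function(x) metadata(x)$reference)

setMethod("show", "PBMCExperiment", function(object) {
  cat(sprintf("PBMCExperiment: %d probes x %d samples [%s scale%s]\n",
              nrow(object), ncol(object), metadata(object)$scale,
              if ("detection" %in% assayNames(object)) ", detection p-values" else ""))
  if ("group" %in% colnames(colData(object))) {
    tab <- table(colData(object)$group)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "Log2RatioExperiment", function(object) {
  cat(sprintf("Log2RatioExperiment: %d probes x %d samples (reference: %s)\n",
              nrow(object), ncol(object), metadata(object)$reference))
})

#' @rdname Signature-class
#' @export
setMethod("probeIds", "Signature", function(x) x@entries$probe_id)

#' @rdname Signature-class
#' @export
setMethod("signatureEntries", "Signature", function(x) x@entries)

#' @rdname Signature-class
#' @param object a Signature.
#' @export
setMethod("length", "Signature", function(x) nrow(x@entries))

setMethod("show", "Signature", function(object) {
  cat(sprintf("Signature '%s': %s vs %s, %d probes (%d up, %d down)\n",
              object@comparison,
              paste(object@caseGroups, collapse = "+"), object@controlGroup,
              nrow(object@entries),
              sum(object@entries$direction == "up"),
              sum(object@entries$direction == "down")))
})

#' @rdname PermutationFDR-class
#' @export
setMethod("fdrEstimate", "PermutationFDR", function(x) x@fdrEstimate)

#' @rdname PermutationFDR-class
#' @export
setMethod("nullHitCounts", "PermutationFDR", function(x) x@nullHitCounts)

setMethod("show", "PermutationFDR", function(object) {
  cat(sprintf(
    "PermutationFDR '%s': %d observed hits, %d permutations, mean null hits %.3f, FDR estimate %s\n",
    object@comparison, object@nObserved, object@nPermutations,
    mean(object@nullHitCounts),
    if (is.na(object@fdrEstimate)) "n/a (no observed hits)"
    else sprintf("%.4g", object@fdrEstimate)))
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport [%s]: %d -> %d probes kept\n",
              object@step, object@nInput, object@nKept))
  for (nm in names(object@removed))
    cat(sprintf("  removed by %s: %d\n", nm, length(object@removed[[nm]])))
  if (length(object@notes)) cat("  notes:", length(object@notes), "\n")
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection '%s': %d sets over %d-gene universe\n",
              object@name, length(object@sets), length(object@universe)))
})

#' @rdname ClusteringResult-class
#' @export
setMethod("clusterAssignments", "ClusteringResult", function(x) x@assignments)

#' @rdname ClusteringResult-class
#' @export
setMethod("clusterEnrichment", "ClusteringResult", function(x) x@enrichment)

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult: %d samples, %s distance, %s linkage, k=%d\n",
              length(object@assignments), object@distance, object@linkage,
              object@k))
})
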