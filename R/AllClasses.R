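#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.GROUPS <- c("control", "PTPN11", "SOS1", "SHOC2")
.LEUKO_FRACTIONS <- c("neut_frac", "lymph_frac", "mono_frac", "eos_frac", "baso_frac")
.CONFOUNDERS <- c("age", "sex", .LEUKO_FRACTIONS)

#' PBMCExperiment: probe-level expression with detection p-values
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding an `exprs` assay
#' (probe x sample intensities, linear or log2 scale) and optionally a
#' `detection` assay of per-probe, per-sample detection p-values as produced by
#' Illumina BeadStudio-style scanners. Sample annotation (group label, age,
#' sex, differential leukocyte fractions) lives in `colData`. The intensity
#' scale is recorded in `metadata(x)$scale`.
#'
#' @slot ... inherited from SummarizedExperiment.
#' @seealso [PBMCExperiment()], [scaleAndLog()], [detectionFilter()]
#' @export
setClass("PBMCExperiment", contains = "SummarizedExperiment")

setValidity("PBMCExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!"exprs" %in% an)
    msg <- c(msg, "assay 'exprs' is required")
  if ("detection" %in% an) {
    dp <- assay(object, "detection")
    if (anyNA(dp) || any(dp < 0) || any(dp > 1))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
  }
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("linear", "log2"))
    msg <- c(msg, "metadata(x)$scale must be 'linear' or 'log2'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if ("group" %in% colnames(colData(object))) {
    g <- colData(object)$group
    if (anyNA(g) || !all(g %in% .GROUPS))
      msg <- c(msg, sprintf("group labels must be one of: %s",
                            paste(.GROUPS, collapse = ", ")))
  }
  if ("age" %in% colnames(colData(object)) &&
      any(colData(object)$age < 0, na.rm = TRUE))
    msg <- c(msg, "ages must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Log2RatioExperiment: control-referenced log2 ratios
#'
#' Probe x sample matrix of log2 expression ratios relative to the mean of a
#' reference group (assay `log2ratio`). The reference group name is stored in
#' `metadata(x)$reference`. Rows of reference-group samples average to zero by
#' construction.
#'
#' @seealso [toLog2Ratio()], [selectSignature()]
#' @export
setClass("Log2RatioExperiment", contains = "SummarizedExperiment")

setValidity("Log2RatioExperiment", function(object) {
  msg <- character()
  if (!"log2ratio" %in% assayNames(object))
    msg <- c(msg, "assay 'log2ratio' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Thresholds of the triple differential-expression criterion
#'
#' A probe enters a signature only if it passes all three tests strictly:
#' absolute mean log2 ratio above `minAbsLog2Ratio`, two-sample t-test p-value
#' below `maxTP`, and absolute signal-to-noise ratio above `minSNR`.
#'
#' @param minAbsLog2Ratio minimum absolute fold change, log2 units (default 0.5).
#' @param maxTP maximum t-test p-value (default 0.01).
#' @param minSNR minimum absolute signal-to-noise ratio (default 0.5).
#' @return a named list of class `signatureThresholds`.
#' @examples
#' signatureThresholds()
#' signatureThresholds(minAbsLog2Ratio = 1)
#' @export
signatureThresholds <- function(minAbsLog2Ratio = 0.5, maxTP = 0.01, minSNR = 0.5) {
  stopifnot(minAbsLog2Ratio > 0, maxTP > 0, minSNR > 0)
  structure(list(minAbsLog2Ratio = minAbsLog2Ratio, maxTP = maxTP, minSNR = minSNR),
            class = "signatureThresholds")
}

#' Signature: probes passing the triple criterion for one comparison
#'
#' @slot comparison human-readable comparison name (e.g. `"PTPN11"`).
#' @slot caseGroups group labels forming the case arm.
#' @slot controlGroup group label of the control arm.
#' @slot entries data.frame with columns `probe_id`, `mean_log2ratio`, `t_p`,
#'   `snr`, `direction` ("up"/"down"), sorted by decreasing `abs(snr)`.
#' @slot thresholds the `signatureThresholds` used.
#' @export
setClass("Signature", representation(
  comparison = "character",
  caseGroups = "character",
  controlGroup = "character",
  entries = "data.frame",
  thresholds = "list"
))

setValidity("Signature", function(object) {
  msg <- character()
  need <- c("probe_id", "mean_log2ratio", "t_p", "snr", "direction")
  if (!all(need %in% colnames(object@entries)))
    msg <- c(msg, sprintf("entries must have columns: %s", paste(need, collapse = ", ")))
  else {
    e <- object@entries
    if (anyDuplicated(e$probe_id)) msg <- c(msg, "duplicate probe ids in signature")
    if (!all(e$direction %in% c("up", "down")))
      msg <- c(msg, "direction must be 'up' or 'down'")
    if (nrow(e) && !all(e$direction == ifelse(e$mean_log2ratio > 0, "up", "down")))
      msg <- c(msg, "direction inconsistent with sign of mean_log2ratio")
  }
  if (length(msg)) msg else TRUE
})

#' PermutationFDR: Monte Carlo estimate of the false-positive fraction
#'
#' @slot comparison comparison name.
#' @slot nObserved observed signature size at the true labels.
#' @slot nullHitCounts signature sizes over label permutations.
#' @slot nPermutations number of permutations.
#' @slot fdrEstimate mean(nullHitCounts) / nObserved; `NA` when nObserved is 0.
#' @slot seed RNG seed used, or NA.
#' @export
setClass("PermutationFDR", representation(
  comparison = "character",
  nObserved = "integer",
  nullHitCounts = "integer",
  nPermutations = "integer",
  fdrEstimate = "numeric",
  seed = "integer"
))

setValidity("PermutationFDR", function(object) {
  msg <- character()
  if (length(object@nullHitCounts) != object@nPermutations)
    msg <- c(msg, "length(nullHitCounts) must equal nPermutations")
  if (!is.na(object@fdrEstimate) && object@fdrEstimate < 0)
    msg <- c(msg, "fdrEstimate must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FilterReport: bookkeeping of a probe-filtering step
#'
#' @slot step filter name ("detection" or "confound").
#' @slot nInput probes entering the filter.
#' @slot nKept probes surviving.
#' @slot removed named list of removed probe ids keyed by reason (for the
#'   confound filter, one entry per confounder that triggered removal; a probe
#'   may appear under several confounders).
#' @slot thresholds parameters the filter applied.
#' @slot notes character notes (e.g. constant probes whose association with a
#'   confounder was undefined and were retained).
#' @export
setClass("FilterReport", representation(
  step = "character",
  nInput = "integer",
  nKept = "integer",
  removed = "list",
  thresholds = "list",
  notes = "character"
))

setValidity("FilterReport", function(object) {
  if (object@nKept > object@nInput) "nKept cannot exceed nInput" else TRUE
})

#' GeneSetCollection: named gene sets over a gene universe
#'
#' Harmonized container for GMT-style collections (kinase substrates,
#' functional keywords, transcription-factor target lists). Sets are clipped
#' to the universe at construction.
#'
#' @slot name collection name.
#' @slot sets named list of character vectors of gene ids.
#' @slot universe character vector of gene ids.
#' @seealso [readGMT()], [hypergeomEnrich()], [circuitDetect()]
#' @export
setClass("GeneSetCollection", representation(
  name = "character",
  sets = "list",
  universe = "character"
))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (anyDuplicated(object@universe)) msg <- c(msg, "universe has duplicate ids")
  if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
    msg <- c(msg, "all sets must be named")
  if (any(vapply(object@sets, length, 1L) < 1L))
    msg <- c(msg, "set sizes must be >= 1")
  if (!all(unlist(object@sets) %in% object@universe))
    msg <- c(msg, "every set must be a subset of the universe")
  if (length(msg)) msg else TRUE
})

#' ClusteringResult: unsupervised sample clustering
#'
#' @slot tree the `hclust` object (merge order and heights).
#' @slot assignments named integer vector of k-cut cluster memberships.
#' @slot k number of clusters cut.
#' @slot enrichment data.frame of one-sided Fisher exact enrichment of each
#'   cluster in each group label (columns `cluster`, `group`, `overlap`,
#'   `cluster_size`, `group_size`, `p`).
#' @slot distance,linkage the metric and agglomeration method used.
#' @export
setClass("ClusteringResult", representation(
  tree = "ANY",
  assignments = "integer",
  k = "integer",
  enrichment = "data.frame",
  distance = "character",
  linkage = "character"
))

setValidity("ClusteringResult", function(object) {
  msg <- character()
  if (!inherits(object@tree, "hclust")) msg <- c(msg, "tree must be an hclust object")
  else {
    if (length(object@tree$order) != length(object@assignments))
      msg <- c(msg, "leaf count must equal sample count")
    if (is.unsorted(object@tree$height))
      msg <- c(msg, "merge heights must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})
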