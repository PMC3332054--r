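#' Scale sample columns to a common mean and log2-transform
#'
#' Each sample column of a linear-scale intensity matrix is rescaled so its
#' mean equals `targetMean` (default: the global mean intensity), then values
#' are log2-transformed. Intensities are floored at `floorValue` first so the
#' logarithm is defined.
#'
#' @param x a linear-scale [PBMCExperiment-class].
#' @param targetMean common column mean after scaling; default `mean(exprs(x))`.
#' @param floorValue lower clip applied before scaling (default 1).
#' @return a log2-scale PBMCExperiment.
#' @export
scaleAndLog <- function(x, targetMean = NULL, floorValue = 1) {
  stopifnot(is(x, "PBMCExperiment"))
  if (expressionScale(x) != "linear")
    stop("scaleAndLog expects linear-scale intensities")
  m <- pmax(exprs(x), floorValue)
  if (any(m <= 0))
    stop("non-positive intensities remain after floor clipping")
  if (is.null(targetMean)) targetMean <- mean(m)
  scaled <- sweep(m, 2, targetMean / colMeans(m), `*`)
  assay(x, "exprs") <- log2(scaled)
  metadata(x)$scale <- "log2"
  metadata(x)$targetMean <- targetMean
  x
}

#' Filter probes for reliable signal detection
#'
#' Keeps probes whose detection p-value is below `pThreshold` in at least
#' `minFraction` of samples — within at least one sample group when `byGroup`
#' is set (the default), so that probes expressed in only one small mutation
#' group are not lost to the majority.
#'
#' @param x a [PBMCExperiment-class] with a detection assay.
#' @param pThreshold detection p-value cutoff (default 0.01).
#' @param minFraction minimum fraction of samples detected (default 0.5).
#' @param byGroup evaluate the fraction within each group (requires a `group`
#'   column in `colData`).
#' @return a list with `experiment` (the subset PBMCExperiment) and `report`
#'   (a [FilterReport-class]).
#' @export
detectionFilter <- function(x, pThreshold = 0.01, minFraction = 0.5,
                            byGroup = TRUE) {
  stopifnot(is(x, "PBMCExperiment"))
  dp <- detectionP(x)
  hit <- dp < pThreshold
  if (byGroup) {
    groups <- sampleGroups(x)
    keep <- Reduce(`|`, lapply(unique(groups), function(g)
      rowMeans(hit[, groups == g, drop = FALSE]) >= minFraction))
  } else {
    keep <- rowMeans(hit) >= minFraction
  }
  if (!any(keep))
    warning("no probes pass the detection filter")
  report <- new("FilterReport", step = "detection",
                nInput = nrow(x), nKept = sum(keep),
                removed = list(detection = rownames(x)[!keep]),
                thresholds = list(pThreshold = pThreshold,
                                  minFraction = minFraction, byGroup = byGroup),
                notes = character())
  list(experiment = x[keep, ], report = report)
}

# Vectorised Pearson correlation p-values of every probe row against one
# covariate (point-biserial when the covariate is binary). Constant rows give
# NA. Matches cor.test(..., method = "pearson").
.rowCorP <- function(m, v) {
  n <- ncol(m)
  v <- as.numeric(v)
  vc <- v - mean(v)
  sv <- sqrt(sum(vc^2))
  mc <- m - rowMeans(m)
  sm <- sqrt(rowSums(mc^2))
  r <- as.vector(mc %*% vc) / (sm * sv)
  r <- pmin(1, pmax(-1, r))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  p[sm == 0 | sv == 0] <- NA_real_
  p
}

#' Remove probes correlated with age, sex or leukocyte composition
#'
#' Tests each probe against each confounder — age (Pearson), sex
#' (point-biserial) and the five differential leukocyte fractions (Pearson) —
#' and removes the probe if any association p-value falls below `alpha`.
#' Probes with constant values (association undefined) are retained and noted.
#'
#' @param x a log2-scale [PBMCExperiment-class] whose `colData` carries `age`,
#'   `sex` and the leukocyte fraction columns.
#' @param alpha per-test significance threshold for removal (default 0.01).
#' @param confounders confounder columns to test; defaults to all seven.
#' @return list with `experiment` and `report` ([FilterReport-class]); the
#'   report's `removed` maps each confounder to the probes it flagged.
#' @export
confoundFilter <- function(x, alpha = 0.01, confounders = .CONFOUNDERS) {
  stopifnot(is(x, "PBMCExperiment"))
  cd <- as.data.frame(colData(x))
  confounders <- intersect(confounders, colnames(cd))
  if (!length(confounders))
    stop("no confounder columns found in colData")
  m <- exprs(x)
  notes <- character()
  removedBy <- list()
  removeAny <- rep(FALSE, nrow(m))
  constantRow <- apply(m, 1, function(r) all(r == r[1]))
  if (any(constantRow))
    notes <- c(notes, sprintf(
      "%d constant probes retained (association undefined): %s",
      sum(constantRow),
      paste(utils::head(rownames(m)[constantRow], 5), collapse = ", ")))
  for (cf in confounders) {
    v <- cd[[cf]]
    if (length(unique(v)) < 2) {
      notes <- c(notes, sprintf("confounder '%s' is constant; test skipped", cf))
      next
    }
    p <- .rowCorP(m, v)
    flag <- !is.na(p) & p < alpha
    removedBy[[cf]] <- rownames(m)[flag]
    removeAny <- removeAny | flag
  }
  keep <- !removeAny
  report <- new("FilterReport", step = "confound",
                nInput = nrow(x), nKept = sum(keep),
                removed = removedBy,
                thresholds = list(alpha = alpha, confounders = confounders),
                notes = notes)
  list(experiment = x[keep, ], report = report)
}

#' Transform to log2 ratios against a reference group
#'
#' Subtracts, per probe, the mean over reference-group samples (default:
#' controls), so reference rows are zero-mean and case values read directly as
#' log2 fold changes versus the control average.
#'
#' @param x a log2-scale [PBMCExperiment-class].
#' @param reference reference group label (default `"control"`).
#' @return a [Log2RatioExperiment-class].
#' @export
toLog2Ratio <- function(x, reference = "control") {
  stopifnot(is(x, "PBMCExperiment"))
  if (expressionScale(x) != "log2")
    stop("toLog2Ratio expects log2-scale intensities; run scaleAndLog first")
  groups <- sampleGroups(x)
  refIdx <- which(groups == reference)
  if (!length(refIdx))
    stop("configuration error: reference group '", reference, "' is absent")
  m <- exprs(x)
  lr <- m - rowMeans(m[, refIdx, drop = FALSE])
  se <- SummarizedExperiment(assays = list(log2ratio = lr),
                             colData = colData(x))
  metadata(se)$reference <- reference
  new("Log2RatioExperiment", se)
}
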