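#' Configure an end-to-end pipeline run
#'
#' Collects every path and parameter of the full analysis: detection and
#' confounder filtering, log2-ratio transformation, triple-criterion signature
#' selection for the four comparisons, Monte Carlo permutation FDR, full
#' leave-one-out classification, optional gene-set enrichment and TF/target
#' circuit detection, and hierarchical clustering.
#'
#' @param matrix,detection,samples paths to the matrix TSV, detection TSV and
#'   sample sheet TSV (dialects of [writeFixture()]).
#' @param outdir output directory for all artifacts.
#' @param gmt optional named character vector of GMT paths for enrichment.
#' @param tfGmt optional GMT path of TF target sets for circuit detection.
#' @param matrixScale `"log2"` (default; [scaleAndLog()] is skipped) or
#'   `"linear"`.
#' @param targetMean target column mean for linear-scale scaling (NULL = global
#'   mean).
#' @param detectionPThreshold,detectionMinFraction,detectionByGroup detection
#'   filter parameters, see [detectionFilter()].
#' @param confoundAlpha per-test removal threshold, see [confoundFilter()].
#' @param thresholds [signatureThresholds()] of the triple criterion.
#' @param nPermutations label permutations per comparison (default 2000).
#' @param seed integer seed governing every stochastic stage.
#' @param clusterDistance,clusterLinkage,clusterK clustering parameters, see
#'   [clusterSamples()].
#' @param tTest t-test variant, `"welch"` or `"student"`.
#' @param heatmap also render the signature heatmap PNG (default FALSE; the
#'   plotted TSV is written either way when signatures are non-empty).
#' @return a validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(matrix, detection, samples, outdir,
                           gmt = NULL, tfGmt = NULL,
                           matrixScale = c("log2", "linear"),
                           targetMean = NULL,
                           detectionPThreshold = 0.01,
                           detectionMinFraction = 0.5,
                           detectionByGroup = TRUE,
                           confoundAlpha = 0.01,
                           thresholds = signatureThresholds(),
                           nPermutations = 2000,
                           seed = 1L,
                           clusterDistance = "correlation",
                           clusterLinkage = "ward.D2",
                           clusterK = 4,
                           tTest = "welch",
                           heatmap = FALSE) {
  matrixScale <- match.arg(matrixScale)
  cfg <- list(matrix = matrix, detection = detection, samples = samples,
              outdir = outdir, gmt = gmt, tfGmt = tfGmt,
              matrixScale = matrixScale, targetMean = targetMean,
              detectionPThreshold = detectionPThreshold,
              detectionMinFraction = detectionMinFraction,
              detectionByGroup = detectionByGroup,
              confoundAlpha = confoundAlpha,
              thresholds = unclass(thresholds),
              nPermutations = as.integer(nPermutations),
              seed = as.integer(seed),
              clusterDistance = clusterDistance,
              clusterLinkage = clusterLinkage,
              clusterK = as.integer(clusterK),
              tTest = tTest, heatmap = isTRUE(heatmap))
  class(cfg) <- "pipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname pipelineConfig
#' @param config a `pipelineConfig` or the path of a YAML file of the same
#'   fields.
#' @export
validatePipelineConfig <- function(config) {
  inputs <- c(matrix = config$matrix, detection = config$detection,
              samples = config$samples, config$gmt, tfGmt = config$tfGmt)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input paths do not exist: ", paste(missing, collapse = ", "))
  if (is.null(config$seed) || is.na(config$seed))
    stop("a seed is required: the permutation stage is stochastic")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [pipelineConfig()]
#'   (thresholds as a mapping `minAbsLog2Ratio/maxTP/minSNR`).
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(signatureThresholds, y$thresholds)
  if (!is.null(y$gmt)) y$gmt <- unlist(y$gmt)
  do.call(pipelineConfig, y)
}

.safeName <- function(x) gsub("^_|_$", "", gsub("[^A-Za-z0-9]+", "_", x))

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.reportToList <- function(r) {
  list(step = r@step, n_input = r@nInput, n_kept = r@nKept,
       removed = r@removed, thresholds = r@thresholds, notes = r@notes)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, signature selection over the four comparisons,
#' permutation FDR, leave-one-out classification with score-separation tests,
#' enrichment/circuits (when GMT collections are configured) and clustering,
#' writing every intermediate artifact plus a machine-readable manifest into
#' `config$outdir`. Re-running with an identical configuration and seed
#' reproduces all outputs byte-identically. A stage failure halts the run with
#' the stage name; artifacts of completed stages persist.
#'
#' @param config a `pipelineConfig`, or the path of a YAML file for
#'   [readPipelineConfig()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  validatePipelineConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  .writeJSON(config[setdiff(names(config), "outdir")],
             file.path(outdir, "config.json"))

  x <- stage("read", readExpression(config$matrix, config$detection,
                                    samples = config$samples,
                                    scale = config$matrixScale))
  say("read: %d probes x %d samples", nrow(x), ncol(x))

  x <- stage("scale_log", {
    if (expressionScale(x) == "linear")
      scaleAndLog(x, targetMean = config$targetMean)
    else x
  })

  det <- stage("detection_filter",
               detectionFilter(x, pThreshold = config$detectionPThreshold,
                               minFraction = config$detectionMinFraction,
                               byGroup = config$detectionByGroup))
  .writeJSON(.reportToList(det$report), file.path(outdir, "filter_detection.json"))
  say("detection filter: %d -> %d probes", det$report@nInput, det$report@nKept)

  conf <- stage("confound_filter",
                confoundFilter(det$experiment, alpha = config$confoundAlpha))
  .writeJSON(.reportToList(conf$report), file.path(outdir, "filter_confound.json"))
  say("confound filter: %d -> %d probes", conf$report@nInput, conf$report@nKept)

  lr <- stage("log2ratio", toLog2Ratio(conf$experiment, reference = "control"))
  thresholds <- do.call(signatureThresholds, config$thresholds)
  comparisons <- defaultComparisons()
  present <- unique(sampleGroups(lr))
  comparisons <- lapply(comparisons, intersect, present)
  comparisons <- comparisons[vapply(comparisons, length, 1L) > 0]

  signatures <- list()
  for (i in seq_along(comparisons)) {
    nm <- names(comparisons)[i]
    sig <- stage(paste0("signature:", nm),
                 selectSignature(lr, comparisons[[nm]], thresholds,
                                 comparison = nm, tTest = config$tTest))
    signatures[[nm]] <- sig
    writeSignature(sig, file.path(outdir,
                                  sprintf("signature_%s.tsv", .safeName(nm))))
    say("signature %s: %d probes", nm, length(sig))

    fdr <- stage(paste0("fdr:", nm),
                 permutationFDR(lr, comparisons[[nm]], thresholds,
                                nPermutations = config$nPermutations,
                                seed = config$seed + i, comparison = nm,
                                tTest = config$tTest))
    .writeJSON(list(comparison = nm, n_observed_hits = fdr@nObserved,
                    n_permutations = fdr@nPermutations, seed = fdr@seed,
                    mean_null_hits = mean(fdr@nullHitCounts),
                    fdr_estimate = fdr@fdrEstimate,
                    null_hit_counts = fdr@nullHitCounts),
               file.path(outdir, sprintf("fdr_%s.json", .safeName(nm))))
    say("fdr %s: estimate %s", nm,
        if (is.na(fdr@fdrEstimate)) "n/a" else sprintf("%.4g", fdr@fdrEstimate))
  }

  loo <- stage("loo", looClassify(lr, thresholds, comparisons = comparisons,
                                  tTest = config$tTest))
  data.table::fwrite(loo$scores, file.path(outdir, "loo_scores.tsv"), sep = "\t")
  seps <- list()
  for (nm in names(comparisons)) {
    for (g in intersect(comparisons[[nm]], present)) {
      sep <- stage(paste0("separation:", nm),
                   scoreSeparation(loo$scores, nm, c(g, "control")))
      seps[[sprintf("%s|%s_vs_control", nm, g)]] <- sep
    }
  }
  .writeJSON(seps, file.path(outdir, "separations.json"))
  say("loo: %d scores, %d separation tests", nrow(loo$scores), length(seps))

  if (!is.null(config$gmt)) {
    universe <- rownames(lr)  # detected-and-unconfounded probes
    gmts <- config$gmt
    if (is.null(names(gmts)))
      names(gmts) <- .safeName(tools::file_path_sans_ext(basename(gmts)))
    for (cn in names(gmts)) {
      gsc <- stage(paste0("enrich:", cn),
                   readGMT(gmts[[cn]], name = cn, universe = universe))
      for (nm in names(signatures)) {
        res <- stage(paste0("enrich:", cn),
                     enrichSignature(signatures[[nm]], gsc))
        data.table::fwrite(res, file.path(
          outdir, sprintf("enrichment_%s_%s.tsv", cn, .safeName(nm))),
          sep = "\t")
      }
    }
  }
  if (!is.null(config$tfGmt)) {
    gsc <- stage("circuits", readGMT(config$tfGmt, name = "tf_targets",
                                     universe = rownames(lr)))
    circuits <- lapply(signatures, function(s)
      stage("circuits", suppressMessages(circuitDetect(s, gsc))))
    .writeJSON(circuits, file.path(outdir, "circuits.json"))
  }

  cl <- stage("cluster", clusterSamples(lr, distance = config$clusterDistance,
                                        linkage = config$clusterLinkage,
                                        k = config$clusterK))
  writeNewick(cl, file.path(outdir, "dendrogram.nwk"))
  .writeJSON(list(assignments = as.list(clusterAssignments(cl)),
                  enrichment = clusterEnrichment(cl),
                  distance = cl@distance, linkage = cl@linkage, k = cl@k),
             file.path(outdir, "clusters.json"))

  nonEmpty <- signatures[vapply(signatures, length, 1L) > 0]
  if (config$heatmap && length(nonEmpty))
    stage("heatmap", exportHeatmap(lr, nonEmpty,
                                   file.path(outdir, "heatmap.png")))

  manifest <- list(
    package = "rasosig",
    version = as.character(utils::packageVersion("rasosig")),
    seed = config$seed,
    parameter_hash = unname(tools::md5sum(file.path(outdir, "config.json"))),
    parameters = config[setdiff(names(config),
                                c("outdir", "matrix", "detection", "samples"))],
    counts = list(
      probes_input = det$report@nInput,
      probes_detected = det$report@nKept,
      probes_after_confound = conf$report@nKept,
      samples = ncol(x),
      signature_sizes = lapply(signatures, length)))
  .writeJSON(manifest, file.path(outdir, "manifest.json"))
  say("done: %s", outdir)
  invisible(outdir)
}
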