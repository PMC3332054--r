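#' Configure a synthetic PBMC expression simulation
#'
#' Defines the statistical structure of a simulated Illumina BeadChip-style
#' probe x sample matrix: planted group-specific differential-expression
#' signatures, confounder-correlated probes (age, sex, differential leukocyte
#' fractions), per-probe baseline intensities, residual noise, and a detection
#' model in which low-expression probes fail detection in a fraction of
#' samples.
#'
#' Defaults emulate the design of a PBMC RASopathy expression study:
#' 20,589 probes; 21 controls, 17 PTPN11, 6 SOS1 and 5 SHOC2 samples; planted
#' per-group signature sizes of 225 (PTPN11), 73 (SOS1) and 1407 (SHOC2)
#' probes; a two-fold (1.0 log2) effect over 0.5 log2 residual noise; and a
#' detection model under which roughly the lowest 70% of probes by baseline
#' intensity drop out of most samples, so that the detected-and-unconfounded
#' probe count lands near the ~5,600-of-20,589 throughput typical of such
#' arrays.
#'
#' Planted signature and confounder probes are disjoint and are drawn from the
#' expressed (reliably detected) pool: differential expression is only
#' observable in detected probes.
#'
#' @param nProbes number of probes on the array.
#' @param groupSizes named integer vector of samples per group; names must be
#'   drawn from control, PTPN11, SOS1, SHOC2.
#' @param signatureSpec named list (one entry per non-control group) of lists
#'   with `n` (planted probes), `effectSize` (log2 units, >= 0) and
#'   `fractionUp` (proportion of planted probes upregulated).
#' @param confoundSpec list with counts `nAge`, `nSex`, `nLeukocyte` of
#'   confounder-correlated probes and `beta`, the slope in log2 units per
#'   confounder standard deviation.
#' @param baselineMean,baselineSd log2-scale mean and sd of per-probe baseline
#'   intensities.
#' @param residualSd per-probe, per-sample residual noise sd (log2 units).
#' @param probeVarShape optional inverse-gamma shape (> 2) for heteroscedastic
#'   per-probe variances with mean `residualSd^2`; `NULL` keeps noise
#'   homoscedastic.
#' @param detection list with `lowExpressionQuantile` (proportion of probes, by
#'   baseline intensity, subject to dropout) and `dropoutP` (per-sample dropout
#'   probability for those probes).
#' @param ageRange range of subject ages, years (uniform).
#' @param leukocyteAlpha Dirichlet concentration over the five leukocyte
#'   fractions (neutrophils, lymphocytes, monocytes, eosinophils, basophils).
#' @param seed integer RNG seed; fixing it fixes every simulated byte.
#' @return a validated list of class `simulationConfig`.
#' @examples
#' cfg <- simulationConfig(nProbes = 500,
#'                         signatureSpec = list(PTPN11 = list(n = 20)))
#' @export
simulationConfig <- function(
    nProbes = 20589,
    groupSizes = c(control = 21, PTPN11 = 17, SOS1 = 6, SHOC2 = 5),
    signatureSpec = list(
      PTPN11 = list(n = 225, effectSize = 1.0, fractionUp = 0.5),
      SOS1   = list(n = 73,  effectSize = 1.0, fractionUp = 0.5),
      SHOC2  = list(n = 1407, effectSize = 1.0, fractionUp = 0.5)),
    confoundSpec = list(nAge = 150, nSex = 150, nLeukocyte = 200, beta = 0.5),
    baselineMean = 8, baselineSd = 1.5,
    residualSd = 0.5,
    probeVarShape = NULL,
    detection = list(lowExpressionQuantile = 0.7, dropoutP = 0.8),
    ageRange = c(2, 18),
    leukocyteAlpha = c(55, 35, 6, 3, 1),
    seed = 1L) {
  stopifnot(nProbes >= 1, all(groupSizes >= 0),
            all(names(groupSizes) %in% .GROUPS))
  signatureSpec <- lapply(signatureSpec, function(s) {
    s <- utils::modifyList(list(effectSize = 1.0, fractionUp = 0.5), s)
    stopifnot(s$n >= 0, s$effectSize >= 0, s$fractionUp >= 0, s$fractionUp <= 1)
    s
  })
  if (!all(names(signatureSpec) %in% setdiff(.GROUPS, "control")))
    stop("signatureSpec groups must be among: ",
         paste(setdiff(.GROUPS, "control"), collapse = ", "))
  confoundSpec <- utils::modifyList(
    list(nAge = 0, nSex = 0, nLeukocyte = 0, beta = 0.5), confoundSpec)
  stopifnot(confoundSpec$nAge >= 0, confoundSpec$nSex >= 0,
            confoundSpec$nLeukocyte >= 0)
  stopifnot(residualSd > 0, baselineSd >= 0,
            detection$lowExpressionQuantile >= 0,
            detection$lowExpressionQuantile <= 1,
            detection$dropoutP >= 0, detection$dropoutP <= 1,
            length(leukocyteAlpha) == 5)
  if (!is.null(probeVarShape) && probeVarShape <= 2)
    stop("probeVarShape must exceed 2 for a finite-variance inverse-gamma")
  nPlanted <- sum(vapply(signatureSpec, function(s) s$n, 1))
  nConf <- confoundSpec$nAge + confoundSpec$nSex + confoundSpec$nLeukocyte
  nExpressed <- nProbes - floor(nProbes * detection$lowExpressionQuantile)
  if (nPlanted + nConf > nExpressed)
    stop(sprintf(
      "configuration error: %d planted + %d confound probes exceed the %d expressed probes",
      nPlanted, nConf, nExpressed))
  structure(list(
    nProbes = as.integer(nProbes), groupSizes = groupSizes,
    signatureSpec = signatureSpec, confoundSpec = confoundSpec,
    baselineMean = baselineMean, baselineSd = baselineSd,
    residualSd = residualSd, probeVarShape = probeVarShape,
    detection = detection, ageRange = ageRange,
    leukocyteAlpha = leukocyteAlpha, seed = as.integer(seed)),
    class = "simulationConfig")
}

.samplePrefix <- c(control = "C", PTPN11 = "PT", SOS1 = "SO", SHOC2 = "SH")

#' Simulate a PBMC expression dataset with planted structure
#'
#' Generates log2-scale intensities
#' \deqn{x_{gs} = \mu_g + \delta_g\,\mathrm{sign}_g\,[s \in \mathrm{group}(g)]
#'   + \beta\, c_s\,[g\ \mathrm{confound\ probe}] + \varepsilon_{gs}}
#' with \eqn{\mu_g \sim N(\mathrm{baselineMean}, \mathrm{baselineSd}^2)} and
#' \eqn{\varepsilon_{gs} \sim N(0, \mathrm{residualSd}^2)}; confounder values
#' \eqn{c_s} are standardized across samples. Detection p-values are drawn
#' Uniform(0, 0.01) for detected probe/sample pairs and Uniform(0.05, 1) for
#' dropouts; only probes in the lowest `lowExpressionQuantile` of baseline
#' intensity are subject to dropout, each with probability `dropoutP` per
#' sample.
#'
#' @param config a [simulationConfig()].
#' @return a [PBMCExperiment-class] (log2 scale) with assays `exprs` and
#'   `detection`; planted-probe ground truth is in `metadata(x)$truth`, a
#'   data.frame with columns `probe_id`, `label` (group or confounder name)
#'   and `direction` ("up"/"down").
#' @examples
#' x <- simulatePBMC(simulationConfig(nProbes = 300, seed = 7,
#'   signatureSpec = list(PTPN11 = list(n = 10)),
#'   confoundSpec = list(nAge = 5, nSex = 0, nLeukocyte = 0)))
#' table(metadata(x)$truth$label)
#' @export
simulatePBMC <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  withSeed(config$seed, {
    gs <- config$groupSizes[config$groupSizes > 0]
    groups <- rep(names(gs), gs)
    sampleIds <- unlist(lapply(names(gs), function(g)
      sprintf("%s-%03d", .samplePrefix[[g]], seq_len(gs[[g]]))),
      use.names = FALSE)
    n <- length(sampleIds)
    p <- config$nProbes
    probeIds <- sprintf("ILMN_%06d", seq_len(p))

    # per-sample confounders
    age <- stats::runif(n, config$ageRange[1], config$ageRange[2])
    sex <- stats::rbinom(n, 1, 0.5)
    leuko <- rdirichlet(n, config$leukocyteAlpha)
    colnames(leuko) <- .LEUKO_FRACTIONS
    samples <- data.frame(sample_id = sampleIds, group = groups,
                          age = age, sex = sex, leuko,
                          stringsAsFactors = FALSE)

    # baseline intensities and the expressed pool
    mu <- stats::rnorm(p, config$baselineMean, config$baselineSd)
    q <- config$detection$lowExpressionQuantile
    nLow <- floor(p * q)
    ord <- order(mu)
    lowIdx <- ord[seq_len(nLow)]
    pool <- setdiff(seq_len(p), lowIdx)

    # planted signature probes (disjoint, from the expressed pool)
    truth <- list()
    effects <- matrix(0, p, n)
    pool <- sample(pool)  # randomize assignment order
    take <- function(k) {
      idx <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      idx
    }
    for (g in names(config$signatureSpec)) {
      spec <- config$signatureSpec[[g]]
      if (spec$n == 0 || !g %in% groups) next
      idx <- take(spec$n)
      signs <- ifelse(seq_len(spec$n) <= round(spec$n * spec$fractionUp), 1, -1)
      effects[idx, groups == g] <- effects[idx, groups == g] +
        spec$effectSize * signs
      truth[[g]] <- data.frame(probe_id = probeIds[idx], label = g,
                               direction = ifelse(signs > 0, "up", "down"),
                               stringsAsFactors = FALSE)
    }

    # confounder-correlated probes
    cs <- config$confoundSpec
    confVars <- c(rep("age", cs$nAge), rep("sex", cs$nSex),
                  rep(.LEUKO_FRACTIONS, length.out = cs$nLeukocyte))
    if (length(confVars)) {
      idx <- take(length(confVars))
      design <- cbind(age = age, sex = sex, leuko)
      for (i in seq_along(idx)) {
        v <- design[, confVars[i]]
        z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
        effects[idx[i], ] <- effects[idx[i], ] + cs$beta * z
      }
      truth$confound <- data.frame(probe_id = probeIds[idx], label = confVars,
                                   direction = "up", stringsAsFactors = FALSE)
    }

    # residual noise (optionally heteroscedastic per probe)
    if (is.null(config$probeVarShape)) {
      sdg <- rep(config$residualSd, p)
    } else {
      a <- config$probeVarShape
      vg <- (config$residualSd^2 * (a - 1)) / stats::rgamma(p, shape = a)
      sdg <- sqrt(vg)
    }
    eps <- matrix(stats::rnorm(p * n, 0, sdg), p, n)  # recycles sdg by row
    values <- mu + effects + eps
    dimnames(values) <- list(probeIds, sampleIds)

    # detection p-values
    dropout <- matrix(FALSE, p, n)
    if (nLow > 0 && config$detection$dropoutP > 0)
      dropout[lowIdx, ] <- matrix(
        stats::runif(nLow * n) < config$detection$dropoutP, nLow, n)
    det <- matrix(stats::runif(p * n, 0, 0.01), p, n)
    det[dropout] <- stats::runif(sum(dropout), 0.05, 1)
    dimnames(det) <- dimnames(values)

    x <- PBMCExperiment(values, detection = det, samples = samples,
                        scale = "log2")
    truthDf <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
               else data.frame(probe_id = character(), label = character(),
                               direction = character(), stringsAsFactors = FALSE)
    metadata(x)$truth <- truthDf
    metadata(x)$config <- config
    x
  })
}

#' Ground truth of a simulated dataset
#'
#' @param x a [PBMCExperiment-class] from [simulatePBMC()] or [readFixture()].
#' @return data.frame with columns `probe_id`, `label`, `direction`.
#' @export
simulationTruth <- function(x) {
  truth <- metadata(x)$truth
  if (is.null(truth)) stop("no simulation truth attached to this object")
  truth
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits `matrix.tsv` (first column `probe_id`, then one column per sample),
#' `detection.tsv` (same shape), `samples.tsv` (sample sheet) and `truth.json`
#' (probe_id to planted label/direction). Values round-trip exactly through
#' [readExpression()] and [readSampleSheet()].
#'
#' @param x a [PBMCExperiment-class], typically from [simulatePBMC()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeFixture <- function(x, dir) {
  stopifnot(is(x, "PBMCExperiment"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory: ", dir)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             detection = file.path(dir, "detection.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  writeMatrixTSV(exprs(x), paths["matrix"])
  if ("detection" %in% assayNames(x))
    writeMatrixTSV(detectionP(x), paths["detection"])
  else paths <- paths[names(paths) != "detection"]
  data.table::fwrite(as.data.frame(colData(x)), paths["samples"], sep = "\t")
  truth <- metadata(x)$truth
  if (is.null(truth))
    truth <- data.frame(probe_id = character(), label = character(),
                        direction = character())
  tl <- lapply(seq_len(nrow(truth)), function(i)
    list(label = truth$label[i], direction = truth$direction[i]))
  names(tl) <- truth$probe_id
  jsonlite::write_json(tl, paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
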