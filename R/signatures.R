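#' Golub-style signal-to-noise ratio
#'
#' `(mean(case) - mean(control)) / (sd(case) + sd(control))` with unbiased
#' (n-1) sample standard deviations. The sign carries the direction of
#' regulation. When both groups are constant the statistic is 0 for equal
#' means and signed infinity otherwise (always passing a magnitude threshold).
#'
#' @param caseValues,controlValues numeric vectors, each of length >= 2.
#' @return a single number.
#' @examples
#' snr(c(3, 1), c(1, -1))  # 2 / (sqrt(2) + sqrt(2)) ~ 0.7071
#' @export
snr <- function(caseValues, controlValues) {
  stopifnot(length(caseValues) >= 2, length(controlValues) >= 2)
  num <- mean(caseValues) - mean(controlValues)
  den <- stats::sd(caseValues) + stats::sd(controlValues)
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

# Row-wise triple-criterion statistics for case vs control column indices on a
# log2(-ratio) matrix. Returns per-probe mean difference, t p-value (Welch or
# pooled Student), SNR and the pass mask under strict inequalities.
.tripleStats <- function(m, caseIdx, ctrlIdx, thresholds,
                         tTest = c("welch", "student")) {
  tTest <- match.arg(tTest)
  a <- rowGroupStats(m, caseIdx)
  b <- rowGroupStats(m, ctrlIdx)
  diff <- a$mean - b$mean
  if (tTest == "welch") {
    se2 <- a$var / a$n + b$var / b$n
    df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  } else {
    vp <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
    se2 <- vp * (1 / a$n + 1 / b$n)
    df <- rep(a$n + b$n - 2, length(diff))
  }
  t <- diff / sqrt(se2)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # both groups constant: p = 1 for equal means, -> 0 otherwise
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  sdSum <- sqrt(a$var) + sqrt(b$var)
  s <- ifelse(sdSum == 0,
              ifelse(diff == 0, 0, sign(diff) * Inf),
              diff / sdSum)
  pass <- abs(diff) > thresholds$minAbsLog2Ratio &
    p < thresholds$maxTP &
    abs(s) > thresholds$minSNR
  list(diff = diff, p = p, snr = s, pass = pass)
}

#' The four case-vs-control comparisons of the study design
#'
#' Comparison (1) pools all three mutation groups (the NS+NS/LAH "RASopathy"
#' signature); (2)-(4) test each mutation group alone against controls.
#'
#' @return named list mapping comparison name to its case group labels.
#' @export
defaultComparisons <- function() {
  list("NS+NS/LAH" = c("PTPN11", "SOS1", "SHOC2"),
       PTPN11 = "PTPN11", SOS1 = "SOS1", SHOC2 = "SHOC2")
}

#' Select a differential-expression signature by the triple criterion
#'
#' A probe enters the signature iff, between the case and control samples, it
#' shows (i) absolute mean log2-ratio difference above `minAbsLog2Ratio`,
#' (ii) two-sample t-test p-value below `maxTP`, and (iii) absolute
#' signal-to-noise ratio above `minSNR` — all strict inequalities. Because the
#' fold change is computed as the case-minus-control mean difference of log2
#' ratios, it equals the mean case Log2Ratio exactly when the ratio reference
#' is the comparison's control group, and remains well defined under label
#' permutation and in cross-validation folds.
#'
#' @param lr a [Log2RatioExperiment-class].
#' @param caseGroups character vector of case group labels.
#' @param thresholds a [signatureThresholds()] list.
#' @param controlGroup control group label (default `"control"`).
#' @param comparison name recorded on the signature; defaults to the case
#'   groups pasted with "+".
#' @param tTest `"welch"` (unequal-variance, default) or `"student"` (pooled).
#' @return a [Signature-class], entries sorted by decreasing `abs(snr)`.
#' @export
selectSignature <- function(lr, caseGroups, thresholds = signatureThresholds(),
                            controlGroup = "control",
                            comparison = paste(caseGroups, collapse = "+"),
                            tTest = c("welch", "student")) {
  stopifnot(is(lr, "Log2RatioExperiment"))
  tTest <- match.arg(tTest)
  groups <- sampleGroups(lr)
  caseIdx <- which(groups %in% caseGroups)
  ctrlIdx <- which(groups == controlGroup)
  if (length(caseIdx) < 2 || length(ctrlIdx) < 2)
    stop("configuration error: case and control arms each need >= 2 samples")
  m <- log2Ratios(lr)
  st <- .tripleStats(m, caseIdx, ctrlIdx, thresholds, tTest)
  idx <- which(st$pass)
  entries <- data.frame(
    probe_id = rownames(m)[idx],
    mean_log2ratio = st$diff[idx],
    t_p = st$p[idx],
    snr = st$snr[idx],
    direction = ifelse(st$diff[idx] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  entries <- entries[order(-abs(entries$snr)), , drop = FALSE]
  rownames(entries) <- NULL
  new("Signature", comparison = comparison, caseGroups = caseGroups,
      controlGroup = controlGroup, entries = entries,
      thresholds = unclass(thresholds))
}

#' Monte Carlo permutation estimate of the false-positive fraction
#'
#' Case/control labels are shuffled (group-size preserving) among the samples
#' participating in the comparison; the full triple criterion is re-run per
#' permutation and the null hit count recorded. The false-positive fraction is
#' estimated as mean(null hits) / observed hits.
#'
#' @inheritParams selectSignature
#' @param nPermutations number of label permutations (default 2000).
#' @param seed integer seed; the caller's RNG state is preserved. `NULL`
#'   consumes the current RNG stream.
#' @return a [PermutationFDR-class]. With zero observed hits the estimate is
#'   `NA` and the null counts are still returned.
#' @export
permutationFDR <- function(lr, caseGroups, thresholds = signatureThresholds(),
                           nPermutations = 2000, seed = NULL,
                           controlGroup = "control",
                           comparison = paste(caseGroups, collapse = "+"),
                           tTest = c("welch", "student")) {
  stopifnot(is(lr, "Log2RatioExperiment"), nPermutations >= 1)
  tTest <- match.arg(tTest)
  groups <- sampleGroups(lr)
  caseIdx <- which(groups %in% caseGroups)
  ctrlIdx <- which(groups == controlGroup)
  if (length(caseIdx) < 2 || length(ctrlIdx) < 2)
    stop("configuration error: case and control arms each need >= 2 samples")
  m <- log2Ratios(lr)
  nObserved <- sum(.tripleStats(m, caseIdx, ctrlIdx, thresholds, tTest)$pass)
  # canonical (sample-id-ordered) pool so the estimate is invariant to the
  # column order of the input matrix
  pool <- c(caseIdx, ctrlIdx)
  pool <- pool[order(colnames(m)[pool])]
  nCase <- length(caseIdx)
  nullCounts <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      perm <- sample(pool)
      sum(.tripleStats(m, perm[seq_len(nCase)], perm[-seq_len(nCase)],
                       thresholds, tTest)$pass)
    }, integer(1))
  })
  est <- if (nObserved == 0) NA_real_ else mean(nullCounts) / nObserved
  new("PermutationFDR", comparison = comparison,
      nObserved = as.integer(nObserved),
      nullHitCounts = as.integer(nullCounts),
      nPermutations = as.integer(nPermutations),
      fdrEstimate = est,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Overlap between two signatures
#'
#' @param a,b [Signature-class] objects.
#' @return list with `shared` (probe ids in both), `concordant` and
#'   `discordant` counts (same / opposite direction among shared probes).
#' @export
signatureOverlap <- function(a, b) {
  stopifnot(is(a, "Signature"), is(b, "Signature"))
  ea <- signatureEntries(a)
  eb <- signatureEntries(b)
  shared <- intersect(ea$probe_id, eb$probe_id)
  da <- ea$direction[match(shared, ea$probe_id)]
  db <- eb$direction[match(shared, eb$probe_id)]
  list(shared = shared,
       concordant = sum(da == db),
       discordant = sum(da != db))
}

#' Write a signature as TSV
#'
#' Columns: `probe_id, mean_log2ratio, t_p, snr, direction`.
#'
#' @param signature a [Signature-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSignature <- function(signature, path) {
  stopifnot(is(signature, "Signature"))
  data.table::fwrite(signatureEntries(signature), path, sep = "\t")
  invisible(path)
}
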