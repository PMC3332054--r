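#' Weighted-average classification score
#'
#' Golub-style weighted vote: `sum(w * (x - b)) / sum(abs(w))`, where the
#' weights `w` are the training-fold SNR values of the signature probes and
#' `b` the midpoints between the two training group means. Positive scores
#' vote for the case group. The normalization makes the score invariant to
#' uniform rescaling of the weights and to probe order.
#'
#' @param sampleValues named numeric vector of the sample's log2 ratios; must
#'   cover all signature probes.
#' @param weights named numeric vector of per-probe weights (fold SNR).
#' @param midpoints named numeric vector of per-probe decision midpoints.
#' @return a single number.
#' @examples
#' weightedScore(c(p1 = 2), c(p1 = 1), c(p1 = 1))               # 1
#' weightedScore(c(p1 = 2, p2 = 1), c(p1 = 1, p2 = -0.5),
#'               c(p1 = 1, p2 = 0))                              # 1/3
#' @export
weightedScore <- function(sampleValues, weights, midpoints) {
  stopifnot(length(weights) > 0, length(weights) == length(midpoints))
  probes <- names(weights)
  missing <- setdiff(probes, names(sampleValues))
  if (length(missing))
    stop("sample is missing values for probes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (any(!is.finite(weights)))
    stop("non-finite weights are not allowed")
  x <- sampleValues[probes]
  b <- midpoints[probes]
  sum(weights * (x - b)) / sum(abs(weights))
}

#' Full leave-one-out weighted-voting classification
#'
#' Each sample is held out in turn; all four signatures are re-derived on the
#' remaining samples by the triple criterion, and the held-out sample receives
#' one weighted-average score per signature, with per-probe weights equal to
#' the training-fold SNR and midpoints halfway between the training case and
#' control means. The held-out sample contributes to no training statistic.
#' Folds whose re-derived signature is empty score 0 with a flag.
#'
#' @param lr a [Log2RatioExperiment-class].
#' @param thresholds a [signatureThresholds()] list.
#' @param comparisons named list mapping signature name to case group labels
#'   (default [defaultComparisons()], restricted to groups present).
#' @param controlGroup control group label.
#' @param tTest t-test variant for the per-fold selection.
#' @return list with `scores`, a data.frame (`sample_id`, `group`,
#'   `signature`, `score`, `fold_signature_size`, `empty_signature`), and
#'   `folds`, a per-sample list of per-signature fold models (`probes`,
#'   `weights`, `midpoints`).
#' @export
looClassify <- function(lr, thresholds = signatureThresholds(),
                        comparisons = NULL, controlGroup = "control",
                        tTest = c("welch", "student")) {
  stopifnot(is(lr, "Log2RatioExperiment"))
  tTest <- match.arg(tTest)
  groups <- sampleGroups(lr)
  if (is.null(comparisons)) {
    comparisons <- defaultComparisons()
    comparisons <- lapply(comparisons, intersect, unique(groups))
    comparisons <- comparisons[vapply(comparisons, length, 1L) > 0]
  }
  sizes <- table(groups)
  if (any(sizes < 3))
    stop("every group needs >= 3 samples so LOO folds retain >= 2: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  m <- log2Ratios(lr)
  sampleIds <- colnames(m)
  rows <- list()
  folds <- vector("list", length(sampleIds))
  names(folds) <- sampleIds
  for (i in seq_along(sampleIds)) {
    foldModels <- list()
    for (sig in names(comparisons)) {
      caseIdx <- setdiff(which(groups %in% comparisons[[sig]]), i)
      ctrlIdx <- setdiff(which(groups == controlGroup), i)
      st <- .tripleStats(m, caseIdx, ctrlIdx, thresholds, tTest)
      sel <- which(st$pass & is.finite(st$snr))
      if (length(sel) == 0) {
        score <- 0
        empty <- TRUE
        foldModels[[sig]] <- list(probes = character(0),
                                  weights = numeric(0), midpoints = numeric(0))
      } else {
        w <- st$snr[sel]
        caseMean <- rowMeans(m[sel, caseIdx, drop = FALSE])
        ctrlMean <- rowMeans(m[sel, ctrlIdx, drop = FALSE])
        b <- (caseMean + ctrlMean) / 2
        names(w) <- names(b) <- rownames(m)[sel]
        score <- weightedScore(m[, i], w, b)
        empty <- FALSE
        foldModels[[sig]] <- list(probes = rownames(m)[sel],
                                  weights = w, midpoints = b)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sampleIds[i], group = groups[i], signature = sig,
        score = score, fold_signature_size = length(sel),
        empty_signature = empty, stringsAsFactors = FALSE)
    }
    folds[[i]] <- foldModels
  }
  list(scores = do.call(rbind, rows), folds = folds)
}

#' Group separation of classification scores
#'
#' Two-sided t-test on the LOO scores of one signature between two sample
#' groups, plus the putative classification threshold maximizing balanced
#' accuracy (ties broken toward the midpoint of the tied threshold interval).
#'
#' @param scores the `scores` data.frame from [looClassify()].
#' @param signature signature name to evaluate.
#' @param groupPair character vector of two group labels; the first is treated
#'   as the case group for threshold orientation.
#' @return list with `signature`, `groups`, `p` (Welch t-test; 1 with
#'   `degenerate = TRUE` when scores are constant), `threshold`,
#'   `balanced_accuracy` and `direction` (">" if cases score above the
#'   threshold).
#' @export
scoreSeparation <- function(scores, signature, groupPair) {
  stopifnot(length(groupPair) == 2)
  s <- scores[scores$signature == signature & scores$group %in% groupPair, ]
  x <- s$score[s$group == groupPair[1]]
  y <- s$score[s$group == groupPair[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need >= 2 scores")
  degenerate <- (stats::var(x) + stats::var(y)) == 0
  p <- if (degenerate) 1 else stats::t.test(x, y)$p.value
  # candidate thresholds: midpoints between adjacent sorted unique scores
  u <- sort(unique(c(x, y)))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  balAcc <- function(thr, op) {
    tpr <- mean(if (op == ">") x > thr else x < thr)
    tnr <- mean(if (op == ">") y <= thr else y >= thr)
    (tpr + tnr) / 2
  }
  best <- list(acc = -Inf, thr = NA_real_, op = ">")
  for (op in c(">", "<")) {
    acc <- vapply(cand, balAcc, numeric(1), op = op)
    mx <- max(acc)
    if (mx > best$acc) {
      tied <- cand[acc == mx]
      best <- list(acc = mx, thr = (min(tied) + max(tied)) / 2, op = op)
    }
  }
  list(signature = signature, groups = groupPair, p = p,
       threshold = best$thr, balanced_accuracy = best$acc,
       direction = best$op, degenerate = degenerate)
}
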