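linearPE <- function(m, groups = rep("control", ncol(m))) {
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  PBMCExperiment(m, samples = data.frame(sample_id = colnames(m), group = groups),
                 scale = "linear")
}

test_that("scaleAndLog rescales each column to the target mean before log2", {
  m <- cbind(s1 = c(50, 150), s2 = c(100, 300))  # means 100 and 200
  rownames(m) <- c("p1", "p2")
  out <- scaleAndLog(linearPE(m), targetMean = 100)
  expect_equal(exprs(out)[, "s2"], log2(m[, "s2"] / 2))
  expect_equal(exprs(out)[, "s1"], log2(m[, "s1"]))
  expect_equal(expressionScale(out), "log2")

  # constants are fixed points of scaling
  k <- matrix(7, 3, 4)
  outk <- scaleAndLog(linearPE(k), targetMean = 7)
  expect_true(all(exprs(outk) == log2(7)))

  # contract: every column mean of 2^output equals the target
  set.seed(31)
  r <- matrix(rexp(500, 1 / 200), 50, 10)
  outr <- scaleAndLog(linearPE(r), targetMean = 150)
  expect_equal(colMeans(2^exprs(outr)), rep(150, 10), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("scaleAndLog refuses log2-scale input", {
  x <- tinySim(seed = 1)
  expect_error(scaleAndLog(x), "linear")
})

test_that("detection filter keeps/removes probes per the counting rule", {
  set.seed(7)
  x <- tinySim(seed = 7, nProbes = 300)
  res <- detectionFilter(x, pThreshold = 0.01, minFraction = 0.5, byGroup = TRUE)
  # brute-force per-probe recount
  dp <- detectionP(x)
  g <- sampleGroups(x)
  oracle <- vapply(seq_len(nrow(dp)), function(i) {
    any(vapply(unique(g), function(gr)
      mean(dp[i, g == gr] < 0.01) >= 0.5, logical(1)))
  }, logical(1))
  expect_setequal(rownames(res$experiment), rownames(x)[oracle])
  expect_equal(res$report@nKept, sum(oracle))

  # ungrouped variant against its own recount
  res2 <- detectionFilter(x, 0.01, 0.5, byGroup = FALSE)
  expect_setequal(rownames(res2$experiment),
                  rownames(x)[rowMeans(dp < 0.01) >= 0.5])

  # fully detected probe kept, fully undetected probe removed
  dp2 <- matrix(1, 2, 4, dimnames = list(c("in", "out"), paste0("s", 1:4)))
  dp2["in", ] <- 0.001
  pe <- PBMCExperiment(matrix(rnorm(8), 2, 4, dimnames = dimnames(dp2)),
                       detection = dp2, scale = "log2",
                       samples = data.frame(sample_id = paste0("s", 1:4),
                                            group = "control"))
  kept <- rownames(detectionFilter(pe)$experiment)
  expect_identical(kept, "in")
})

test_that("confound filter removes an age-tracking probe and keeps constants", {
  x <- tinySim(seed = 3, nProbes = 100,
               confoundSpec = list(nAge = 0, nSex = 0, nLeukocyte = 0))
  m <- exprs(x)
  age <- colData(x)$age
  m["ILMN_000001", ] <- 0.1 * age + rnorm(ncol(x), 0, 1e-4)
  m["ILMN_000002", ] <- 5  # constant: association undefined
  assay(x, "exprs") <- m
  res <- confoundFilter(x, alpha = 0.01)
  expect_true("ILMN_000001" %in% res$report@removed$age)
  expect_false("ILMN_000001" %in% rownames(res$experiment))
  expect_true("ILMN_000002" %in% rownames(res$experiment))
  expect_match(paste(res$report@notes, collapse = " "), "constant")
})

test_that("vectorised correlation p-values match cor.test", {
  set.seed(21)
  m <- matrix(rnorm(200), 10, 20)
  v <- rnorm(20)
  p <- rasosig:::.rowCorP(m, v)
  oracle <- apply(m, 1, function(r) stats::cor.test(r, v)$p.value)
  expect_equal(p, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # binary covariate = point-biserial
  b <- rbinom(20, 1, 0.5)
  expect_equal(rasosig:::.rowCorP(m, b),
               apply(m, 1, function(r) stats::cor.test(r, b)$p.value),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("null probes are removed at about the familywise rate of 7 tests", {
  x <- simulatePBMC(simulationConfig(
    nProbes = 10000, groupSizes = c(control = 10, PTPN11 = 10),
    signatureSpec = list(), confoundSpec = list(nAge = 0),
    detection = list(lowExpressionQuantile = 0, dropoutP = 0), seed = 17))
  res <- confoundFilter(x, alpha = 0.01)
  rate <- 1 - res$report@nKept / res$report@nInput
  # 7 correlated tests at alpha = 0.01: between the single-test rate and the
  # Bonferroni envelope, with binomial slack
  expect_gt(rate, 0.01 - 3 * sqrt(0.01 * 0.99 / 10000))
  expect_lt(rate, 0.07 + 3 * sqrt(0.07 * 0.93 / 10000))
})

test_that("log2-ratio transform centers on the control mean", {
  x <- tinySim(seed = 5, nProbes = 60)
  lr <- toLog2Ratio(x)
  m <- exprs(x)
  ctrl <- sampleGroups(x) == "control"
  expect_equal(log2Ratios(lr), m - rowMeans(m[, ctrl]), ignore_attr = TRUE)
  expect_equal(unname(rowMeans(log2Ratios(lr)[, ctrl])), rep(0, nrow(m)),
               tolerance = 1e-12)
  expect_equal(referenceGroup(lr), "control")

  # direct subtraction example: control mean 5.0, case 5.6 -> ratio 0.6
  mm <- matrix(c(5, 5, 5.6), 1, 3,
               dimnames = list("p1", c("c1", "c2", "k1")))
  pe <- PBMCExperiment(mm, samples = data.frame(
    sample_id = colnames(mm), group = c("control", "control", "PTPN11")),
    scale = "log2")
  expect_equal(log2Ratios(toLog2Ratio(pe))["p1", "k1"], 0.6)

  expect_error(toLog2Ratio(pe, reference = "SOS1"), "configuration error")
})

test_that("detection and confound filters compose order-stably", {
  x <- tinySim(seed = 13, nProbes = 250)
  seq1 <- confoundFilter(detectionFilter(x)$experiment)$experiment
  keepDet <- rownames(detectionFilter(x)$experiment)
  keepConf <- rownames(confoundFilter(x)$experiment)
  expect_setequal(rownames(seq1), intersect(keepDet, keepConf))
})
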