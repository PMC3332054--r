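test_that("snr matches hand computation and degenerate rules", {
  expect_equal(snr(c(3, 1), c(1, -1)), 2 / (sqrt(2) + sqrt(2)))
  expect_equal(snr(c(3, 1), c(1, -1)), 0.70710678, tolerance = 1e-8)
  expect_equal(snr(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_identical(snr(c(2, 2), c(0, 0)), Inf)
  expect_identical(snr(c(0, 0), c(2, 2)), -Inf)
  expect_lt(snr(c(1, 2), c(4, 6)), 0)
  expect_error(snr(1, c(1, 2)))
})

test_that("row-wise triple statistics agree with t.test per probe", {
  set.seed(41)
  m <- matrix(rnorm(30 * 12), 30, 12)
  ci <- 1:5; ki <- 6:12
  th <- signatureThresholds()
  for (variant in c("welch", "student")) {
    st <- rasosig:::.tripleStats(m, ki, ci, th, tTest = variant)
    oracle <- apply(m, 1, function(r)
      stats::t.test(r[ki], r[ci], var.equal = variant == "student")$p.value)
    expect_equal(st$p, oracle, tolerance = 1e-10, ignore_attr = TRUE)
    snrOracle <- apply(m, 1, function(r) snr(r[ki], r[ci]))
    expect_equal(st$snr, snrOracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("any failed criterion vetoes a probe from the signature", {
  # probe 'fc_fail': tiny but ultra-consistent shift (p tiny, SNR big, FC 0.4)
  # probe 'hit': clean two-fold shift passes all three
  # probe 'null': nothing
  set.seed(8)
  ctrl <- matrix(rnorm(3 * 10, 0, c(0.01, 0.3, 0.3)), 3, 10)
  case <- matrix(rnorm(3 * 10, 0, c(0.01, 0.3, 0.3)), 3, 10)
  case[1, ] <- case[1, ] + 0.4
  case[2, ] <- case[2, ] + 1.0
  m <- cbind(ctrl, case)
  rownames(m) <- c("fc_fail", "hit", "null")
  colnames(m) <- paste0("s", 1:20)
  lr <- makeLR(m, groups = rep(c("control", "PTPN11"), each = 10))
  sig <- selectSignature(lr, "PTPN11")
  expect_identical(probeIds(sig), "hit")
  e <- signatureEntries(sig)
  expect_equal(e$direction, "up")
  expect_gt(e$snr, 0.5)
  expect_lt(e$t_p, 0.01)
})

test_that("signature entries are sorted by decreasing absolute SNR", {
  x <- plantedSim(seed = 23)
  lr <- toLog2Ratio(x)
  sig <- selectSignature(lr, "PTPN11")
  expect_gt(length(sig), 0)
  s <- abs(signatureEntries(sig)$snr)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("global-null signatures stay below the t-test bound", {
  hits <- 0; tOnly <- 0; nProbes <- 1000; reps <- 20
  tinyTh <- signatureThresholds(1e-9, 0.01, 1e-9)  # t-test-only criterion
  for (s in 1:reps) {
    x <- nullSim(seed = 300 + s, nProbes = nProbes)
    lr <- toLog2Ratio(x)
    h <- length(selectSignature(lr, "PTPN11"))
    t <- length(selectSignature(lr, "PTPN11", tinyTh))
    expect_lte(h, t)  # extra criteria only remove probes
    hits <- hits + h; tOnly <- tOnly + t
  }
  # pooled t-test-only rate within binomial error of alpha
  expect_lt(tOnly / (nProbes * reps), 0.01 + 3 * sqrt(0.01 * 0.99 / (nProbes * reps)))
  expect_lte(hits, tOnly)
})

test_that("planted probes are recovered with high sensitivity", {
  x <- plantedSim(seed = 71)
  lr <- toLog2Ratio(x)
  sig <- selectSignature(lr, "PTPN11")
  planted <- simulationTruth(x)
  found <- planted$probe_id %in% probeIds(sig)
  expect_gt(mean(found), 0.9)
  # recovered directions match the planted ones
  e <- signatureEntries(sig)
  dir <- e$direction[match(planted$probe_id[found], e$probe_id)]
  expect_equal(dir, planted$direction[found])
})

test_that("permutation FDR is deterministic and invariant to input order", {
  x <- tinySim(seed = 19, nProbes = 250,
               signatureSpec = list(PTPN11 = list(n = 12, effectSize = 1.5)))
  lr <- toLog2Ratio(detectionFilter(x)$experiment)
  f1 <- permutationFDR(lr, "PTPN11", nPermutations = 50, seed = 7)
  f2 <- permutationFDR(lr, "PTPN11", nPermutations = 50, seed = 7)
  expect_identical(nullHitCounts(f1), nullHitCounts(f2))
  expect_equal(fdrEstimate(f1),
               mean(nullHitCounts(f1)) / f1@nObserved)

  # probe- and sample-order invariance
  set.seed(33)
  lrP <- lr[sample(nrow(lr)), sample(ncol(lr))]
  f3 <- permutationFDR(lrP, "PTPN11", nPermutations = 50, seed = 7)
  expect_identical(nullHitCounts(f3), nullHitCounts(f1))
  expect_equal(fdrEstimate(f3), fdrEstimate(f1))
})

test_that("permutation FDR concentrates near 1 under the global null", {
  x <- nullSim(seed = 42, nProbes = 4000)
  lr <- toLog2Ratio(x)
  f <- permutationFDR(lr, "PTPN11", nPermutations = 100, seed = 6)
  expect_gt(f@nObserved, 0)
  expect_gt(fdrEstimate(f), 0.25)
  expect_lt(fdrEstimate(f), 4)
})

test_that("zero observed hits reports a not-applicable estimate", {
  x <- nullSim(seed = 13, nProbes = 100)
  lr <- toLog2Ratio(x)
  strict <- signatureThresholds(10, 1e-8, 10)
  f <- permutationFDR(lr, "PTPN11", strict, nPermutations = 20, seed = 2)
  expect_identical(f@nObserved, 0L)
  expect_true(is.na(fdrEstimate(f)))
  expect_length(nullHitCounts(f), 20)
})

test_that("signature overlap counts shared and concordant probes", {
  a <- makeSignature(c("p1", "p2", "p3", "p4", "p5"), c(1, -1, 2, -2, 1))
  expect_equal(signatureOverlap(a, a),
               list(shared = probeIds(a), concordant = 5L, discordant = 0L))
  b <- makeSignature(c("q1", "q2"), c(1, 1), comparison = "SHOC2")
  expect_equal(signatureOverlap(a, b)$shared, character(0))
  expect_equal(signatureOverlap(a, b)$concordant, 0L)
  # 2 shared, one direction flipped
  c2 <- makeSignature(c("p1", "p2", "x1", "x2", "x3"), c(1, 1, 1, -1, 1),
                      comparison = "SHOC2")
  ov <- signatureOverlap(a, c2)
  expect_setequal(ov$shared, c("p1", "p2"))
  expect_equal(ov$concordant, 1L)
  expect_equal(ov$discordant, 1L)
})
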