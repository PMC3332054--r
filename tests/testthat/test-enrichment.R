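test_that("GMT files parse, deduplicate and round-trip", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg3\tg4\tg4"), path)
  gsc <- readGMT(path)
  expect_length(gsc, 2)
  expect_setequal(geneUniverse(gsc), c("g1", "g2", "g3", "g4"))
  expect_equal(geneSets(gsc)$setB, c("g3", "g4"))  # duplicate g4 removed

  rt <- tempfile(fileext = ".gmt")
  writeGMT(gsc, rt)
  gsc2 <- readGMT(rt)
  expect_equal(geneSets(gsc2), geneSets(gsc))
  expect_setequal(geneUniverse(gsc2), geneUniverse(gsc))

  bad <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1", "broken\tonlytwo"), bad)
  expect_error(readGMT(bad), "line 2")
  empty <- tempfile(fileext = ".gmt")
  file.create(empty)
  expect_error(readGMT(empty), "empty")
})

test_that("hypergeometric enrichment matches the exact tail", {
  # universe 20, set 5, signature 4, overlap 3: p = 155/4845
  gsc <- geneSetCollection(list(A = paste0("g", 1:5)),
                           universe = paste0("g", 1:20))
  res <- hypergeomEnrich(paste0("g", c(1, 2, 3, 6)), gsc)
  expect_equal(res$overlap, 3L)
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$p, 0.03199, tolerance = 1e-4)

  # overlap 0 -> full upper tail = 1; set = universe -> overlap forced, p = 1
  res0 <- hypergeomEnrich(paste0("g", 10:13),
                          geneSetCollection(list(A = paste0("g", 1:5)),
                                            universe = paste0("g", 1:20)))
  expect_equal(res0$p, 1)
  resU <- hypergeomEnrich(paste0("g", 1:4),
                          geneSetCollection(list(A = paste0("g", 1:20)),
                                            universe = paste0("g", 1:20)))
  expect_equal(resU$p, 1)

  expect_error(hypergeomEnrich(c("zz1", "zz2"), gsc), "harmonize")
})

test_that("enrichment p equals brute-force enumeration on small universes", {
  # exact combinatorial oracle, independent of phyper
  tailChoose <- function(k, K, n, N)
    sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
  set.seed(99)
  for (rep in 1:25) {
    N <- sample(5:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- paste0("u", seq_len(N))
    gsc <- geneSetCollection(list(S = universe[1:K]), universe = universe)
    genes <- sample(universe, n)
    res <- hypergeomEnrich(genes, gsc)
    expect_equal(res$p, tailChoose(res$overlap, K, n, N), tolerance = 1e-12)
  }
  # full subset enumeration on a tiny instance
  N <- 9; K <- 4; n <- 4
  universe <- letters[1:N]
  genes <- c("a", "b", "e", "f")  # overlap 2 with {a,b,c,d}
  gsc <- geneSetCollection(list(S = universe[1:K]), universe = universe)
  draws <- combn(N, n)
  exact <- mean(apply(draws, 2, function(d) sum(d <= K) >= 2))
  expect_equal(hypergeomEnrich(genes, gsc)$p, exact, tolerance = 1e-12)
})

test_that("enrichment p is monotone decreasing in overlap", {
  universe <- paste0("u", 1:30)
  gsc <- geneSetCollection(list(S = universe[1:10]), universe = universe)
  ps <- vapply(1:8, function(k) {
    genes <- c(universe[seq_len(k)],
               if (k < 8) universe[11:(11 + 8 - k - 1)])
    hypergeomEnrich(genes, gsc)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("direction-stratified enrichment subsets by regulation sign", {
  sig <- makeSignature(paste0("g", 1:6), c(1, 1, 1, -1, -1, -1))
  universe <- paste0("g", 1:40)
  gsc <- geneSetCollection(list(UP = paste0("g", 1:3)), universe = universe)
  bothP <- enrichSignature(sig, gsc, "both")$p
  upP <- enrichSignature(sig, gsc, "up")$p
  expect_equal(enrichSignature(sig, gsc, "up")$overlap, 3L)
  expect_lt(upP, bothP)  # same overlap from a smaller query list
})

test_that("TF/target circuits use the exact two-sided binomial bias test", {
  # TF down; 10 targets in the signature, 8 down
  probes <- c("TF1", paste0("t", 1:10))
  lfc <- c(-1, rep(-1, 8), 1, 1)
  sig <- makeSignature(probes, lfc)
  gsc <- geneSetCollection(list(TF1 = paste0("t", 1:10)),
                           universe = c("TF1", paste0("t", 1:10)))
  res <- circuitDetect(sig, gsc)
  expect_equal(res$n_targets_in_signature, 10L)
  expect_equal(res$n_targets_down, 8L)
  expect_equal(res$direction_bias_p, 2 * 56 / 1024, tolerance = 1e-12)
  expect_equal(res$tf_direction, "down")
  expect_equal(res$n_targets_concordant, 8L)
  expect_false(res$circuit)

  # 5/5 split: no bias, no circuit
  sig55 <- makeSignature(probes, c(-1, rep(c(-1, 1), 5)))
  res55 <- circuitDetect(sig55, gsc)
  expect_equal(res55$direction_bias_p, 1)
  expect_false(res55$circuit)

  # TF up, all 6 targets down: p = 2/64, circuit flagged, discordant
  probes6 <- c("TF1", paste0("t", 1:6))
  sig6 <- makeSignature(probes6, c(1, rep(-1, 6)))
  gsc6 <- geneSetCollection(list(TF1 = paste0("t", 1:6)), universe = probes6)
  res6 <- circuitDetect(sig6, gsc6)
  expect_equal(res6$direction_bias_p, 2 / 64, tolerance = 1e-12)
  expect_true(res6$circuit)
  expect_equal(res6$n_targets_concordant, 0L)

  # under-populated TF is skipped with a message
  sigSmall <- makeSignature(c("TF1", "t1"), c(1, -1))
  expect_message(out <- circuitDetect(sigSmall, gsc), "skipped")
  expect_equal(nrow(out), 0)
})
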