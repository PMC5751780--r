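test_that("seed scan keeps only pairs with a significant factor", {
  sim <- makeSingleFactorSim(nGenes = 150, perStratum = 6, seed = 51)
  ex <- exprValues(sim$dataset)
  pd <- enumeratePairs(sim$dataset)
  th <- calibrateCT(ex, pd, nRandomPairs = 2000, m = 10, seed = 52)
  seeds <- findSeedPairs(ex, pd, th, splitHalf = FALSE, seed = 53)
  expect_gt(nrow(seeds$pairs), 0)
  ## postcondition: every kept pair has >= 1 factor beyond CT with p < 0.01
  expect_true(all(rowSums(abs(seeds$coef) > th@CT & seeds$pval < 0.01) > 0))
  ## reported statistics agree with direct per-pair fits
  for (r in head(seq_len(nrow(seeds$pairs)), 5)) {
    f <- fitModel(statisticVector(ex, seeds$pairs[r, ], pd), pd)
    expect_equal(unname(coef(f)), unname(seeds$coef[r, ]), tolerance = 1e-8)
    expect_equal(unname(pvalues(f)), unname(seeds$pval[r, ]),
                 tolerance = 1e-8)
  }
  ## a planted set contributes at least one internal seed pair
  hits <- 0L
  for (sd in 1:5) {
    s2 <- makeSingleFactorSim(nGenes = 150, perStratum = 6, seed = 60 + sd)
    ex2 <- exprValues(s2$dataset)
    pd2 <- enumeratePairs(s2$dataset)
    th2 <- calibrateCT(ex2, pd2, nRandomPairs = 2000, m = 10,
                       seed = 70 + sd)
    sp <- findSeedPairs(ex2, pd2, th2, splitHalf = FALSE, seed = 80 + sd)
    pin <- matrix(rownames(ex2)[sp$pairs] %in% s2$planted,
                  ncol = 2)
    if (any(pin[, 1] & pin[, 2])) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("split-half scanning only reports cross-half pairs", {
  sim <- makeSingleFactorSim(nGenes = 120, perStratum = 6, seed = 55)
  ex <- exprValues(sim$dataset)
  pd <- enumeratePairs(sim$dataset)
  th <- calibrateCT(ex, pd, nRandomPairs = 2000, m = 10, seed = 56)
  seeds <- findSeedPairs(ex, pd, th, splitHalf = TRUE, seed = 57)
  ## replicate the seeded split
  set.seed(57)
  perm <- sample.int(nrow(ex))
  h1 <- perm[seq_len(nrow(ex) %/% 2)]
  expect_gt(nrow(seeds$pairs), 0)
  inH1 <- matrix(seeds$pairs %in% h1, ncol = 2)
  expect_true(all(xor(inH1[, 1], inH1[, 2])))
})

test_that("expansion improves the target coefficient monotonically", {
  sim <- makeSingleFactorSim(nGenes = 200, perStratum = 6, seed = 58)
  ex <- exprValues(sim$dataset)
  pd <- enumeratePairs(sim$dataset)
  seedPair <- match(sim$planted[1:2], rownames(ex))
  exp_ <- expandSeed(ex, pd, seedPair, factor = "f1", direction = 1,
                     geneOrderSeed = 59)
  expect_true(all(seedPair %in% exp_$genes))
  ## strictly monotone trajectory in the optimisation direction
  expect_true(all(diff(exp_$trajectory) > 0))
  ## |F_k(J)| never below the seed's
  expect_gte(coef(exp_$fit)[["f1"]], exp_$trajectory[1])
  ## no candidates: the seed is a fixed point
  fx <- expandSeed(ex, pd, seedPair, "f1", 1, geneOrderSeed = 59,
                   candidates = integer())
  expect_identical(sort(fx$genes), sort(seedPair))
  ## recovery: J picks up planted genes at low noise, few outsiders
  rec <- out <- 0
  for (sd in 1:5) {
    s2 <- makeSingleFactorSim(nGenes = 200, perStratum = 8, sigma = 0.2,
                              seed = 300 + sd)
    ex2 <- exprValues(s2$dataset)
    pd2 <- enumeratePairs(s2$dataset)
    e2 <- expandSeed(ex2, pd2, match(s2$planted[1:2], rownames(ex2)),
                     "f1", 1, geneOrderSeed = sd)
    g2 <- rownames(ex2)[e2$genes]
    rec <- rec + sum(g2 %in% s2$planted)
    out <- out + sum(!g2 %in% s2$planted)
  }
  expect_gt(rec, out)  # expansion is enriched for planted genes
})

test_that("augmentation recovers weak members and obeys alpha ordering", {
  sim <- makeSingleFactorSim(nGenes = 250, perStratum = 8, sigma = 0.2,
                             seed = 61)
  ex <- exprValues(sim$dataset)
  pd <- enumeratePairs(sim$dataset)
  th <- calibrateCT(ex, pd, nRandomPairs = 3000, m = 10, seed = 62)
  J <- match(sim$planted[1:6], rownames(ex))
  augStrict <- augmentSet(ex, pd, J, th, alpha = 0)
  augMid <- augmentSet(ex, pd, J, th, alpha = 0.5)
  augLoose <- augmentSet(ex, pd, J, th, alpha = 1)
  ## J is always contained in L
  expect_true(all(J %in% augMid$genes))
  ## alpha = 1 (threshold at T_oi) is the most permissive end
  expect_gte(length(augLoose$genes), length(augMid$genes))
  expect_gte(length(augMid$genes), length(augStrict$genes))
  ## most of the planted set is recovered at mid alpha
  expect_gte(sum(rownames(ex)[augMid$genes] %in% sim$planted), 15)
  ## noise admission is rare
  noise <- setdiff(rownames(ex)[augMid$genes], sim$planted)
  expect_lte(length(noise), ceiling(0.05 * nrow(ex)))
})

test_that("filtering retains planted members over spiked noise", {
  worseNoise <- 0L
  for (sd in 1:5) {
    sim <- makeSingleFactorSim(nGenes = 250, perStratum = 8, sigma = 0.2,
                               seed = 500 + sd)
    ex <- exprValues(sim$dataset)
    pd <- enumeratePairs(sim$dataset)
    th <- calibrateCT(ex, pd, nRandomPairs = 3000, m = 10, seed = 510 + sd)
    spiked <- setdiff(seq_len(nrow(ex)),
                      match(sim$planted, rownames(ex)))[1:5]
    L <- c(match(sim$planted, rownames(ex)), spiked)
    fin <- filterSet(ex, pd, L, th)
    keptPlanted <- mean(match(sim$planted, rownames(ex)) %in% fin$genes)
    keptNoise <- mean(spiked %in% fin$genes)
    if (keptPlanted > keptNoise) worseNoise <- worseNoise + 1L
  }
  expect_gte(worseNoise, 4L)

  ## degenerate sizes pass through untouched
  sim <- makeSingleFactorSim(nGenes = 50, perStratum = 5, seed = 63)
  ex <- exprValues(sim$dataset)
  pd <- enumeratePairs(sim$dataset)
  th <- calibrateCT(ex, pd, nRandomPairs = 1000, m = 10, seed = 64)
  two <- filterSet(ex, pd, c(1L, 2L), th)
  expect_identical(two$genes, c(1L, 2L))
  ## filtering never drops below two genes
  one <- filterSet(ex, pd, match(sim$planted[1:4], rownames(ex)), th)
  expect_gte(length(one$genes), 2L)
})

test_that("the full search is deterministic and finds planted structure", {
  sim <- simulateDCX(nGenes = 600, samplesPerStratum = 5, sigma = 0.2,
                     seed = 71)
  cfg <- dcoxConfig(nRandomPairs = 3000, nPermutations = 200, seed = 71)
  sr1 <- runSearch(sim$dataset, cfg)
  sr2 <- runSearch(sim$dataset, cfg)
  expect_identical(lapply(sr1$sets, geneIds), lapply(sr2$sets, geneIds))
  expect_identical(sr1$thresholds@CT, sr2$thresholds@CT)
  ## seed exclusivity: no later set's seed genes inside an earlier set
  seen <- character()
  for (s in sr1$sets) {
    if (length(s@provenance$seed))
      expect_false(any(s@provenance$seed %in% seen))
    if (length(geneIds(s)) >= 3) seen <- union(seen, geneIds(s))
  }
  ## something matching each planted set is among the candidates
  bestJ <- function(truthSet) max(vapply(sr1$sets, function(s)
    length(intersect(geneIds(s), truthSet)) /
      length(union(geneIds(s), truthSet)), 0))
  expect_gte(bestJ(sim$truth$set1), 0.5)
  expect_gte(bestJ(sim$truth$set2), 0.5)

  ## empty result on data with no usable seeds: noise with a huge CT
  ns <- makeToyDataset(nGenes = 40, perStratum = 3, seed = 72)
  cfg0 <- dcoxConfig(nRandomPairs = 500, seed = 72,
                     minVarianceQuantile = 0)
  sr0 <- runSearch(ns, cfg0)
  ## CT calibrated from the same noise keeps seeds scarce; all reported
  ## candidate sets must at least carry a coherent provenance record
  for (s in sr0$sets) {
    expect_true(all(c("seed", "factor", "direction", "sizes") %in%
                      names(s@provenance)))
  }
})
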