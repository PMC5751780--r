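test_that("pair statistic matches its closed forms", {
  ex <- matrix(c(3, 2, 1, 2), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ## single gene: squared difference
  expect_equal(pairStatistic(ex, "g1", "s1", "s2"), 4)
  ## identical samples
  exEq <- cbind(s1 = c(1, 2), s2 = c(1, 2))
  rownames(exEq) <- c("g1", "g2")
  expect_equal(pairStatistic(exEq, c("g1", "g2"), "s1", "s2"), 0)
  ## anti-correlated changes (+2, -2) cancel: coherence is what scores
  exAnti <- cbind(s1 = c(0, 0), s2 = c(2, -2))
  rownames(exAnti) <- c("g1", "g2")
  expect_equal(pairStatistic(exAnti, c("g1", "g2"), "s1", "s2"), 0)
  expect_error(pairStatistic(ex, character(), "s1", "s2"), "nonempty")
})

test_that("pair statistic equals a brute-force double loop", {
  set.seed(7)
  ex <- matrix(rnorm(5 * 6), 5, 6,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  genes <- sample(rownames(ex), 5)
  for (m in 1:5) for (n in (m + 1):6) {
    acc <- 0
    for (g in genes) acc <- acc + (ex[g, m] - ex[g, n])
    expect_equal(pairStatistic(ex, genes, m, n), (acc / length(genes))^2,
                 tolerance = 1e-12)
    ## symmetry
    expect_equal(pairStatistic(ex, genes, n, m),
                 pairStatistic(ex, genes, m, n), tolerance = 1e-14)
  }
  ## shift invariance: adding a constant leaves every A unchanged
  expect_equal(pairStatistic(ex + 3.7, genes, 1, 2),
               pairStatistic(ex, genes, 1, 2), tolerance = 1e-12)
})

test_that("statistic vector aligns with the design and detects planting", {
  dset <- makeToyDataset(nGenes = 10, perStratum = 2, seed = 3)
  pd <- enumeratePairs(dset)
  A <- statisticVector(exprValues(dset), c("g001", "g002"), pd)
  expect_length(A, nPairs(pd))
  for (i in seq_len(nPairs(pd)))
    expect_equal(A[i], pairStatistic(exprValues(dset), c("g001", "g002"),
                                     pairIndices(pd)[i, 1],
                                     pairIndices(pd)[i, 2]),
                 tolerance = 1e-12)
  expect_true(all(statisticVector(exprValues(dset) * 0, "g001", pd) == 0))

  ## planted co-expression raises A within the co-expressed stratum
  sim <- makeSingleFactorSim(nGenes = 100, perStratum = 10, seed = 5)
  pdp <- enumeratePairs(sim$dataset)
  Ap <- statisticVector(exprValues(sim$dataset), sim$planted, pdp)
  on <- designMatrix(pdp)[, "f1"] == 1
  expect_gt(mean(Ap[on]), mean(Ap[!on]))
})

test_that("model fit matches an independent least-squares oracle", {
  dset <- makeToyDataset(nGenes = 5, perStratum = 6, seed = 11)
  pd <- enumeratePairs(dset)
  X <- designMatrix(pd)
  set.seed(12)
  A <- rexp(nPairs(pd))   # skewed, like a squared statistic

  fit <- fitModel(A, pd)
  ## oracle 1: normal equations
  beta <- solve(t(X) %*% X, t(X) %*% A)
  expect_lt(max(abs(coef(fit) - beta[-1])), 1e-8)
  expect_lt(abs(fit@intercept - beta[1]), 1e-8)
  ## oracle 2: an independent statistics routine (stats::lm summary)
  lmf <- summary(lm(A ~ X[, -1]))$coefficients
  expect_lt(max(abs(pvalues(fit) - lmf[-1, 4])), 1e-8)

  ## closed forms
  cfit <- fitModel(rep(2.5, nPairs(pd)), pd)
  expect_equal(unname(cfit@intercept), 2.5, tolerance = 1e-10)
  expect_lt(max(abs(coef(cfit))), 1e-10)
  expect_true(all(pvalues(cfit) > 0.99))

  ## one binary factor, A = 2 on +1 pairs and 0 on -1 pairs
  ex1 <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  fac1 <- data.frame(f1 = rep(c(-1, 1), each = 5), row.names = colnames(ex1))
  pd1 <- enumeratePairs(DCoxDataSet(ex1, fac1))
  A1 <- ifelse(designMatrix(pd1)[, "f1"] == 1, 2, 0)
  f1 <- fitModel(A1, pd1)
  expect_equal(unname(f1@intercept), 1, tolerance = 1e-10)
  expect_equal(unname(coef(f1)), 1, tolerance = 1e-10)
})

test_that("batch coefficients equal row-wise fits through one QR", {
  dset <- makeToyDataset(nGenes = 5, perStratum = 5, seed = 21)
  pd <- enumeratePairs(dset)
  set.seed(22)
  A <- matrix(rexp(500 * nPairs(pd)), 500)
  co <- batchFitCoefficients(A, pd)
  expect_identical(dim(co), c(500L, 2L))
  rowwise <- t(vapply(seq_len(500),
                      function(i) coef(fitModel(A[i, ], pd)),
                      numeric(2)))
  expect_lt(max(abs(co - rowwise)), 1e-10)

  ## k = 1 equals fitModel exactly
  expect_equal(unname(batchFitCoefficients(A[1, , drop = FALSE], pd)[1, ]),
               unname(coef(fitModel(A[1, ], pd))), tolerance = 1e-12)

  ## an intercept-only design (z = 0) is rejected
  pd0 <- pd
  pd0@design <- pd@design[, 1, drop = FALSE]
  expect_error(batchFitCoefficients(A, pd0), "z >= 1")
})

test_that("rank-deficient designs are rejected naming the columns", {
  dset <- makeToyDataset(nGenes = 5, perStratum = 4, seed = 31)
  pd <- enumeratePairs(dset)
  bad <- pd
  bad@design <- cbind(pd@design, f1copy = pd@design[, "f1"])
  expect_error(fitModel(rexp(nPairs(pd)), bad), "collinear|rank deficient")
})

test_that("single-factor planted sign is recovered across replicates", {
  ## positive-level co-expression must yield a positive fitted coefficient
  hits <- 0L
  reps <- 25L
  for (r in seq_len(reps)) {
    sim <- makeSingleFactorSim(nGenes = 40, perStratum = 6, setSize = 10,
                               sigma = 0.2, seed = 100 + r)
    pd <- enumeratePairs(sim$dataset)
    fit <- fitModel(statisticVector(exprValues(sim$dataset), sim$planted, pd),
                    pd)
    if (coef(fit)[["f1"]] > 0) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})
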