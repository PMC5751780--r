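test_that("DCoxDataSet validates ids, finiteness and factor codes", {
  ex <- matrix(rnorm(12), 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  fac <- data.frame(f1 = c(-1, -1, 1, 1), row.names = colnames(ex))
  dset <- DCoxDataSet(ex, fac)
  expect_s4_class(dset, "DCoxDataSet")
  expect_identical(factorNames(dset), "f1")
  expect_identical(dim(factorTable(dset)), c(4L, 1L))
  expect_identical(exprValues(dset), ex)

  bad <- ex; bad[1, 1] <- NA
  expect_error(DCoxDataSet(bad, fac), "finite")
  dup <- ex; rownames(dup) <- c("g1", "g1", "g3")
  expect_error(DCoxDataSet(dup, fac), "unique")
  expect_error(DCoxDataSet(ex, data.frame(f1 = rep(1, 4),
                                          row.names = colnames(ex))),
               "constant")
  expect_error(DCoxDataSet(ex, fac[1:3, , drop = FALSE]), "one row per")
})

test_that("expression reader round-trips and names offending lines", {
  ex <- matrix(round(rnorm(18), 4), 3, 6,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  f <- writeExprFile(ex, tempfile(fileext = ".tsv"))
  got <- readExpression(f, minVarianceQuantile = 0)
  expect_equal(dim(got), dim(ex))
  expect_equal(got, ex, tolerance = 1e-8)

  lines <- readLines(f)
  dupf <- tempfile(); writeLines(c(lines, lines[2]), dupf)
  expect_error(readExpression(dupf), "duplicated gene id 'g1'")
  ragged <- tempfile(); writeLines(c(lines[1], "g9\t1\t2"), ragged)
  expect_error(readExpression(ragged), "ragged row at line 2")
  alpha <- tempfile()
  writeLines(c(lines[1], sub("\t[^\t]*$", "\tabc", lines[2]), lines[3:4]),
             alpha)
  expect_error(readExpression(alpha), "line 2")
})

test_that("variance filter matches a brute-force variance sort", {
  set.seed(42)
  const <- matrix(rep(rnorm(50), each = 30), 50, 30, byrow = FALSE)
  vary <- matrix(rnorm(50 * 30), 50, 30)
  ex <- rbind(const, vary)
  dimnames(ex) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:30))
  f <- writeExprFile(ex, tempfile(fileext = ".tsv"))
  got <- readExpression(f, minVarianceQuantile = 0.5)
  expect_lte(nrow(got), 50L)
  expect_true(all(apply(got, 1, var) > 1e-12))
  ## oracle: quantile cut on per-gene variances
  v <- apply(ex, 1, var)
  expect_setequal(rownames(got), names(v)[v >= quantile(v, 0.5)])
  expect_identical(nrow(readExpression(f, 0)), 100L)
})

test_that("categorical recoding and discretization produce model codes", {
  rc <- recodeCategorical(c("a", "b", "c", "a"), name = "grp")
  expect_identical(colnames(rc), c("grp.b", "grp.c"))
  expect_true(all(unlist(rc) %in% c(-1, 1)))
  expect_identical(rc$grp.b, c(-1, 1, -1, -1))
  expect_error(recodeCategorical(rep("a", 4)), ">= 2 levels")

  d <- discretizeFactor(c(0.1, 0.5, 0.9), breaks = c(0, 1/3, 2/3, 1))
  expect_identical(d, c(-1, 0, 1))
  expect_error(discretizeFactor(c(0.1, 5), breaks = c(0, 1)), "span")
})

test_that("strata group samples by exact factor-vector equality", {
  ## vectors (1,1),(1,1),(-1,1),(-1,1) -> 2 strata of size 2
  st <- buildStrata(matrix(c(1, 1, -1, -1, 1, 1, 1, 1), ncol = 2))
  expect_length(st, 2L)
  expect_true(all(lengths(lapply(st, `[[`, "samples")) == 2L))
  expect_false(any(vapply(st, `[[`, TRUE, "singleton")))

  st3 <- buildStrata(data.frame(f1 = c(1, 1, -1, -1), f2 = c(1, 1, 1, -1)))
  expect_length(st3, 3L)
  expect_identical(sort(lengths(lapply(st3, `[[`, "samples"))),
                   c(1L, 1L, 2L))
  expect_identical(sum(vapply(st3, `[[`, TRUE, "singleton")), 2L)

  ## the benchmark design: 12 strata of 5
  sim <- simulateDCX(nGenes = 60, samplesPerStratum = 5, seed = 1)
  st12 <- buildStrata(sim$dataset)
  expect_length(st12, 12L)
  expect_true(all(lengths(lapply(st12, `[[`, "samples")) == 5L))
  ## partition: every sample exactly once
  members <- sort(unlist(lapply(st12, `[[`, "samples")))
  expect_identical(members, seq_len(60L))
})

test_that("pair enumeration counts, subsampling and reproducibility", {
  ## one stratum of 5 -> C(5,2) = 10 pairs; need a 2nd non-constant factor,
  ## so use 2 strata of 5 -> 20 pairs
  ex <- matrix(rnorm(100), 10, 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
  fac <- data.frame(f1 = rep(c(-1, 1), each = 5), row.names = colnames(ex))
  pd <- enumeratePairs(DCoxDataSet(ex, fac))
  expect_identical(nPairs(pd), 20L)
  expect_true(all(pairIndices(pd)[, 1] < pairIndices(pd)[, 2]))
  expect_identical(colnames(designMatrix(pd)), c("(Intercept)", "f1"))

  sim <- simulateDCX(nGenes = 60, samplesPerStratum = 5, seed = 1)
  pdAll <- enumeratePairs(sim$dataset)
  expect_identical(nPairs(pdAll), 120L)  # 12 * C(5,2)

  for (sd in 1:3) {
    sub <- enumeratePairs(sim$dataset, maxPairs = 12, seed = sd)
    expect_identical(nPairs(sub), 12L)
    expect_identical(sort(unique(sub@strata)), 1:12)  # >= 1 per stratum
    again <- enumeratePairs(sim$dataset, maxPairs = 12, seed = sd)
    expect_identical(pairIndices(sub), pairIndices(again))
  }

  ## all-distinct factor vectors: no usable pairs
  exd <- ex[, 1:4]
  facd <- data.frame(f1 = c(-1, 0, 1, 2), f2 = c(1, -1, 2, 0),
                     row.names = colnames(exd))
  expect_error(suppressWarnings(enumeratePairs(DCoxDataSet(exd, facd))),
               "no two samples share a stratum")
  ## singleton strata warn but survive
  fac1 <- data.frame(f1 = c(-1, -1, 1, 2), row.names = colnames(exd))
  expect_warning(pd1 <- enumeratePairs(DCoxDataSet(exd, fac1)),
                 "singleton")
  expect_identical(nPairs(pd1), 1L)
})
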