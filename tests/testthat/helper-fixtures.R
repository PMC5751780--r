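## Small in-code fixtures shared across the suite.

## deterministic two-factor noise dataset: 4 strata x perStratum samples
makeToyDataset <- function(nGenes = 30L, perStratum = 3L, sigma = 1,
                           seed = 1L) {
  set.seed(seed)
  fac <- expand.grid(f1 = c(-1, 1), f2 = c(-1, 1))
  fac <- fac[rep(seq_len(4L), each = perStratum), ]
  rownames(fac) <- sprintf("s%02d", seq_len(nrow(fac)))
  E <- matrix(rnorm(nGenes * nrow(fac), sd = sigma), nGenes, nrow(fac),
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              rownames(fac)))
  DCoxDataSet(E, fac)
}

## two binary factors, one planted set co-expressed where f1 = +1
makeSingleFactorSim <- function(nGenes = 300L, perStratum = 5L,
                                setSize = 20L, sigma = 0.2, seed = 1L) {
  set.seed(seed)
  fac <- expand.grid(f1 = c(-1, 1), f2 = c(-1, 1))
  fac <- fac[rep(seq_len(4L), each = perStratum), ]
  rownames(fac) <- sprintf("s%02d", seq_len(nrow(fac)))
  nS <- nrow(fac)
  gid <- sprintf("g%03d", seq_len(nGenes))
  E <- matrix(rnorm(nGenes * nS, sd = sigma), nGenes, nS,
              dimnames = list(gid, rownames(fac)))
  sig <- rnorm(nS)
  on <- fac$f1 == 1
  planted <- gid[seq_len(setSize)]
  E[planted, on] <- E[planted, on] + rep(sig[on], each = setSize)
  list(dataset = DCoxDataSet(E, fac), planted = planted,
       profile = c(f1 = 1L, f2 = 0L))
}

## write a genes x samples matrix as the tab-delimited exchange format
writeExprFile <- function(mat, path) {
  lines <- c(paste(c("gene", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i],
                       format(mat[i, ], digits = 10, trim = TRUE)),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  path
}
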