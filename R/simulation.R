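#' Simulate a microarray-style dataset with planted DCX gene sets
#'
#' Emulates the benchmark design used throughout the package: three
#' co-factors -- two binary (B1, B2 in \{-1, +1\}) and one 3-level ordinal
#' (B3 in \{-1, 0, +1\}) -- giving 12 strata, each with
#' \code{samplesPerStratum} samples. Expression is
#' \deqn{E_{im} = B1_{im} + B2_{im} + B3_{im} + O_{im} + e_{im}}
#' where the signal terms are shared per-sample N(0, 1) draws switched on
#' only for genes of a planted set in samples meeting the set's condition,
#' and \eqn{e_{im} \sim N(0, \sigma^2)} is noise. Three disjoint sets of
#' \code{setSize} genes are planted: set 1 co-expressed only where
#' B1 = -1; set 2 co-expressed where B1 = +1 and B2 = +1 (receiving both
#' shared signals); and an always-co-expressed control set sharing O_m in
#' every sample, which should load on the model intercept and never be
#' reported as differentially co-expressed. B3 drives no set and serves as
#' a null factor. All remaining genes are pure noise.
#'
#' @param nGenes total genes (50000 emulates a full microarray; 5000 is the
#'   desk-scale default).
#' @param samplesPerStratum samples in each of the 12 strata (5, 10 or 20
#'   in the benchmark grid).
#' @param sigma noise standard deviation (benchmark grid 0.2, 0.5, 0.8).
#' @param setSize planted set size, default 20.
#' @param seed RNG seed.
#' @param balancedStrata logical; TRUE (default) assigns exactly
#'   \code{samplesPerStratum} samples to every stratum, FALSE draws each
#'   sample's factor values at random (strata then vary in size).
#' @param planted logical; FALSE generates pure-noise data (no planted
#'   sets, truth sets empty), the null condition for calibrating the
#'   pipeline's false-positive behaviour.
#' @return list with \code{dataset} (a \linkS4class{DCoxDataSet}) and
#'   \code{truth}: gene ids of \code{set1}, \code{set2}, \code{control},
#'   and \code{expectedProfiles} (signed profile each true set should be
#'   reported with)
#' @export
simulateDCX <- function(nGenes = 5000L, samplesPerStratum = 10L,
                        sigma = 0.2, setSize = 20L, seed = 1L,
                        balancedStrata = TRUE, planted = TRUE) {
  stopifnot(nGenes >= 3L * setSize, samplesPerStratum >= 1L, sigma >= 0)
  set.seed(seed)
  grid <- expand.grid(B1 = c(-1, 1), B2 = c(-1, 1), B3 = c(-1, 0, 1))
  if (balancedStrata) {
    fac <- grid[rep(seq_len(nrow(grid)), each = samplesPerStratum), ]
  } else {
    n <- nrow(grid) * samplesPerStratum
    fac <- data.frame(B1 = sample(c(-1, 1), n, replace = TRUE),
                      B2 = sample(c(-1, 1), n, replace = TRUE),
                      B3 = sample(c(-1, 0, 1), n, replace = TRUE))
  }
  nS <- nrow(fac)
  rownames(fac) <- sprintf("S%03d", seq_len(nS))

  b1 <- rnorm(nS)
  b2 <- rnorm(nS)
  o <- rnorm(nS)

  gid <- sprintf("g%05d", seq_len(nGenes))
  E <- matrix(rnorm(nGenes * nS, sd = sigma), nGenes, nS,
              dimnames = list(gid, rownames(fac)))
  if (planted) {
    set1 <- gid[seq_len(setSize)]
    set2 <- gid[setSize + seq_len(setSize)]
    ctrl <- gid[2L * setSize + seq_len(setSize)]
    on1 <- fac$B1 == -1
    on2 <- fac$B1 == 1 & fac$B2 == 1
    E[set1, on1] <- E[set1, on1] + rep(b1[on1], each = setSize)
    E[set2, on2] <- E[set2, on2] + rep((b1 + b2)[on2], each = setSize)
    E[ctrl, ] <- E[ctrl, ] + rep(o, each = setSize)
  } else {
    set1 <- set2 <- ctrl <- character()
  }

  list(dataset = DCoxDataSet(E, fac),
       truth = list(
         set1 = set1, set2 = set2, control = ctrl,
         expectedProfiles = list(
           set1 = c(B1 = -1L, B2 = 0L, B3 = 0L),
           set2 = c(B1 = 1L, B2 = 1L, B3 = 0L))))
}

.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Score a search result against the planted truth
#'
#' A truth set is "identified" when some found set matches it at Jaccard
#' index >= \code{matchThreshold} (best match wins). Per truth set the
#' false-negative rate is the fraction of its planted genes missing from
#' the matching set; the false-discovery rate pools non-planted genes over
#' matched sets; profile failure records an identified set reported with
#' the wrong signed profile; and the set-level false-positive count is the
#' number of found sets matching neither truth set, with matches to the
#' always-co-expressed control flagged separately.
#'
#' @param sets list of \linkS4class{DCXGeneSet}s (or plain character
#'   vectors of gene ids).
#' @param truth the truth component of \code{\link{simulateDCX}}.
#' @param matchThreshold Jaccard fraction for identification, default 0.5.
#' @return list of metrics: per-set \code{identified}, \code{jaccard},
#'   \code{fnr}, \code{profileCorrect}; pooled \code{fdr}; counts
#'   \code{nFound}, \code{nFalseSets}, \code{controlReported}
#' @export
scoreResult <- function(sets, truth, matchThreshold = 0.5) {
  geneLists <- lapply(sets, function(s)
    if (is.character(s)) s else geneIds(s))
  profiles <- lapply(sets, function(s)
    if (is.character(s)) NULL else dcxProfile(s))
  truthSets <- list(set1 = truth$set1, set2 = truth$set2)
  planted <- unlist(truthSets, use.names = FALSE)

  perSet <- lapply(names(truthSets), function(nm) {
    ts <- truthSets[[nm]]
    jac <- vapply(geneLists, .jaccard, 0, b = ts)
    best <- if (length(jac)) which.max(jac) else integer()
    ident <- length(best) > 0 && jac[best] >= matchThreshold
    fnr <- if (ident)
      length(setdiff(ts, geneLists[[best]])) / length(ts) else 1
    pc <- if (ident && !is.null(profiles[[best]]))
      identical(as.integer(profiles[[best]]),
                as.integer(truth$expectedProfiles[[nm]])) else NA
    list(identified = ident, jaccard = if (length(jac)) jac[best] else 0,
         match = if (ident) best else NA_integer_, fnr = fnr,
         profileCorrect = pc)
  })
  names(perSet) <- names(truthSets)

  matched <- stats::na.omit(vapply(perSet, `[[`, 0L, "match"))
  fdr <- if (length(matched)) {
    genes <- unlist(geneLists[matched])
    sum(!genes %in% planted) / length(genes)
  } else 0
  ## a found set is false only if it matches neither planted set
  anyTruthHit <- Reduce(`|`, lapply(truthSets, function(ts)
    vapply(geneLists, .jaccard, 0, b = ts) >= matchThreshold),
    logical(length(geneLists)))
  ctrlHit <- vapply(geneLists, .jaccard, 0, b = truth$control) >=
    matchThreshold
  nFalse <- sum(!anyTruthHit)
  list(perSet = perSet,
       identified = vapply(perSet, `[[`, TRUE, "identified"),
       jaccard = vapply(perSet, `[[`, 0, "jaccard"),
       fnr = vapply(perSet, `[[`, 0, "fnr"),
       profileCorrect = vapply(perSet, `[[`, TRUE, "profileCorrect"),
       fdr = fdr, nFound = length(geneLists), nFalseSets = nFalse,
       controlReported = any(ctrlHit))
}

#' Benchmark the pipeline over a noise / sample-size grid
#'
#' For every combination of \code{sigmas} and \code{samplesPerStratum},
#' simulates \code{replicates} datasets, runs the full search and gating,
#' scores against the planted truth and returns one tidy row per
#' replicate.
#'
#' @param sigmas noise levels, default \code{c(0.2, 0.5, 0.8)}.
#' @param samplesPerStratum per-stratum sample sizes, default 10.
#' @param replicates simulated datasets per cell, default 10.
#' @param nGenes genes per dataset.
#' @param baseSeed base seed; replicate r of cell c uses a deterministic
#'   offset of it.
#' @param config search configuration (\code{\link{dcoxConfig}}); its seed
#'   is re-derived per replicate.
#' @param verbose print progress.
#' @return data.frame with columns sigma, n, replicate, identified1/2,
#'   jaccard1/2, fnr1/2, profileCorrect1/2, fdr, nFound, nFalseSets,
#'   controlReported
#' @export
runBenchmark <- function(sigmas = c(0.2, 0.5, 0.8), samplesPerStratum = 10L,
                         replicates = 10L, nGenes = 5000L, baseSeed = 1L,
                         config = dcoxConfig(), verbose = FALSE) {
  rows <- list()
  cell <- 0L
  for (sg in sigmas) for (n in samplesPerStratum) {
    cell <- cell + 1L
    for (r in seq_len(replicates)) {
      seed <- baseSeed + 1000L * cell + r
      sim <- simulateDCX(nGenes = nGenes, samplesPerStratum = n,
                         sigma = sg, seed = seed)
      cfg <- config
      cfg$seed <- seed + 500L
      res <- gateSets(runSearch(sim$dataset, cfg), sim$dataset, cfg)
      sc <- scoreResult(dcxSets(res), sim$truth,
                        matchThreshold = config$matchThreshold)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sg, n = n, replicate = r,
        identified1 = sc$identified[["set1"]],
        identified2 = sc$identified[["set2"]],
        jaccard1 = sc$jaccard[["set1"]], jaccard2 = sc$jaccard[["set2"]],
        fnr1 = sc$fnr[["set1"]], fnr2 = sc$fnr[["set2"]],
        profileCorrect1 = sc$profileCorrect[["set1"]],
        profileCorrect2 = sc$profileCorrect[["set2"]],
        fdr = sc$fdr, nFound = sc$nFound, nFalseSets = sc$nFalseSets,
        controlReported = sc$controlReported)
      if (verbose)
        message("sigma=", sg, " n=", n, " rep=", r, ": found ",
                sc$nFound, " sets; J1=", round(sc$jaccard[["set1"]], 2),
                " J2=", round(sc$jaccard[["set2"]], 2))
    }
  }
  do.call(rbind, rows)
}
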