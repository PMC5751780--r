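## Internal helpers shared by the search stages. `D` is the genes x pairs
## matrix of per-gene expression differences over the design's sample
## pairs; every stage's statistic rows are built from it, so it is computed
## once per run and threaded through.

## coefficient projector: row k of (X'X)^{-1} X' gives factor k's OLS
## coefficient as an inner product with the response
.coefProjector <- function(ctx) chol2inv(qr.R(ctx$qr)) %*% t(ctx$X)

#' Scan gene pairs for differential co-expression seeds
#'
#' For each gene, searches partner genes whose pair fits the multi-factor
#' model with at least one significant co-factor: absolute coefficient
#' above \code{CT} and partial F-test p-value below \code{pCut}. The scan
#' runs in blocks with one QR factorisation per run; p-values are computed
#' only for pairs surviving the coefficient-magnitude filter. With
#' \code{splitHalf} the genes are randomly split into two halves and only
#' cross-half pairs are scanned, halving the cost; sufficiently large DCX
#' sets are expected to contribute pairs to both halves.
#'
#' @param exprs genes x samples numeric matrix (variance-filtered).
#' @param design a \linkS4class{PairDesign}.
#' @param thresholds a \linkS4class{ThresholdSet} (or a bare CT value).
#' @param splitHalf logical; scan only cross-half pairs (default TRUE).
#' @param seed RNG seed for the split.
#' @param pCut per-factor p-value cutoff, default 0.01.
#' @param chunkSize genes per scan chunk, a memory/speed trade-off.
#' @return list with elements \code{pairs} (k x 2 matrix of gene row
#'   indices), \code{coef} and \code{pval} (k x z matrices), and
#'   \code{candidates} (sorted indices of genes with at least one
#'   significant partner; genes outside it are dropped from expansion)
#' @export
findSeedPairs <- function(exprs, design, thresholds, splitHalf = TRUE,
                          seed = 1L, pCut = 0.01, chunkSize = 1500L) {
  CT <- if (is(thresholds, "ThresholdSet")) thresholds@CT else thresholds
  g <- nrow(exprs)
  ctx <- .designContext(design)
  D <- .geneDiffs(exprs, design)
  z <- length(ctx$factors)

  hits <- list()
  if (splitHalf) {
    set.seed(seed)
    perm <- sample.int(g)
    h1 <- perm[seq_len(g %/% 2L)]
    h2 <- perm[(g %/% 2L + 1L):g]
    for (c1 in .chunks(h1, chunkSize)) for (c2 in .chunks(h2, chunkSize)) {
      hits[[length(hits) + 1L]] <-
        .seedScanCross(D, ctx, c1, c2, self = FALSE, CT = CT, pCut = pCut)
      gc(FALSE)
    }
  } else {
    ch <- .chunks(seq_len(g), chunkSize)
    for (a in seq_along(ch)) for (b in a:length(ch)) {
      hits[[length(hits) + 1L]] <-
        .seedScanCross(D, ctx, ch[[a]], ch[[b]], self = a == b,
                       CT = CT, pCut = pCut)
      gc(FALSE)
    }
  }
  hits <- hits[vapply(hits, function(h) nrow(h$pairs) > 0L, TRUE)]
  if (length(hits)) {
    pairs <- do.call(rbind, lapply(hits, `[[`, "pairs"))
    flip <- pairs[, 1L] > pairs[, 2L]      # canonical i < j
    pairs[flip, ] <- pairs[flip, 2:1]
    out <- list(pairs = pairs,
                coef = do.call(rbind, lapply(hits, `[[`, "coef")),
                pval = do.call(rbind, lapply(hits, `[[`, "pval")),
                candidates = sort(unique(as.vector(pairs))))
  } else {
    out <- list(pairs = matrix(integer(), 0L, 2L),
                coef = matrix(numeric(), 0L, z),
                pval = matrix(numeric(), 0L, z),
                candidates = integer())
  }
  colnames(out$coef) <- colnames(out$pval) <- ctx$factors
  out$CT <- CT
  out$splitHalf <- splitHalf
  out
}

.chunks <- function(idx, size) split(idx, ceiling(seq_along(idx) / size))

## Cross scan of all gene pairs (i in idx1, j in idx2) without forming the
## pair statistic vectors. Each pair's response over the sample pairs is
## a_p = ((d_ip + d_jp)/2)^2, so the sufficient statistics of its OLS fit
## expand into polynomial cross-products of the gene-difference matrix D
## that BLAS evaluates for all pairs at once:
##   X'y  : (X'd_i^2 + X'd_j^2 + 2 (D w_k D')_ij) / 4 per design column k
##   y'y  : binomial expansion of sum_p ((d_ip+d_jp)/2)^4
## Coefficients follow from (X'X)^{-1} X'y and the partial-F p-values from
## the residual sum of squares y'y - coef' X'y.
.seedScanCross <- function(D, ctx, idx1, idx2, self, CT, pCut) {
  X <- ctx$X
  k1 <- length(idx1); k2 <- length(idx2)
  z1 <- ncol(X)
  D1 <- D[idx1, , drop = FALSE]
  D2 <- D[idx2, , drop = FALSE]
  XtD2 <- (D * D) %*% X                     # gene x (z+1): X' d_g^2
  Minv <- chol2inv(qr.R(ctx$qr))            # (X'X)^{-1}

  ## X'y per design column, all pairs at once
  Y <- vector("list", z1)
  for (k in seq_len(z1)) {
    H <- D1 %*% (X[, k] * t(D2))
    Y[[k]] <- (outer(XtD2[idx1, k], XtD2[idx2, k], `+`) + 2 * H) / 4
  }
  ## coefficients: linear combinations of the X'y layers
  co <- vector("list", z1)
  for (k in seq_len(z1)) {
    acc <- Minv[k, 1L] * Y[[1L]]
    for (l in seq_len(z1)[-1L]) acc <- acc + Minv[k, l] * Y[[l]]
    co[[k]] <- acc
  }
  ## survivors of the coefficient-magnitude filter
  pass <- abs(co[[2L]]) > CT
  if (z1 > 2L) for (k in 3:z1) pass <- pass | abs(co[[k]]) > CT
  if (self) pass <- pass & upper.tri(pass)
  sel <- which(pass)
  if (!length(sel))
    return(list(pairs = matrix(integer(), 0L, 2L),
                coef = matrix(numeric(), 0L, z1 - 1L),
                pval = matrix(numeric(), 0L, z1 - 1L)))

  ## residual sum of squares via the quartic expansion of y'y
  S4 <- rowSums(D^4)
  C31 <- (D1^3) %*% t(D2)
  C22 <- (D1^2) %*% t(D2^2)
  C13 <- D1 %*% t(D2^3)
  yy <- (outer(S4[idx1], S4[idx2], `+`) +
           4 * C31 + 6 * C22 + 4 * C13) / 16
  rss <- yy[sel]
  for (k in seq_len(z1)) rss <- rss - co[[k]][sel] * Y[[k]][sel]
  rss[rss < 0] <- 0                         # guard rounding at exact fits
  sigma2 <- rss / ctx$df

  coefSel <- vapply(co[-1L], `[`, numeric(length(sel)), sel)
  coefSel <- matrix(coefSel, ncol = z1 - 1L)
  pv <- matrix(NA_real_, length(sel), z1 - 1L)
  for (k in seq_len(z1 - 1L)) {
    Fst <- coefSel[, k]^2 / (sigma2 * ctx$dvar[k + 1L])
    pv[, k] <- pf(Fst, 1, ctx$df, lower.tail = FALSE)
  }
  ok <- rowSums(abs(coefSel) > CT & pv < pCut) > 0L
  sel <- sel[ok]
  ij <- arrayInd(sel, c(k1, k2))
  list(pairs = cbind(idx1[ij[, 1L]], idx2[ij[, 2L]]),
       coef = coefSel[ok, , drop = FALSE],
       pval = pv[ok, , drop = FALSE])
}

## rank -> (i, j) over unordered pairs of 1..g in row-major order
.pairFromRank <- function(r, g) {
  i <- ceiling((2 * g - 1 - sqrt((2 * g - 1)^2 - 8 * r)) / 2)
  off <- (i - 1) * g - i * (i - 1) / 2
  j <- r - off + i
  bad <- j <= i | j > g
  if (any(bad)) {
    i[bad] <- i[bad] - 1
    off <- (i[bad] - 1) * g - i[bad] * (i[bad] - 1) / 2
    j[bad] <- r[bad] - off + i[bad]
  }
  cbind(as.integer(i), as.integer(j))
}

#' Expand a seed pair into a conservative gene set
#'
#' Starting from a significant seed pair, the remaining genes are visited
#' once in a seeded random order; a gene joins the set iff adding it
#' strictly improves the target factor's coefficient in the optimisation
#' direction (increases it for direction +1, decreases it for -1). The bar
#' therefore rises as the search proceeds, yielding a conservative set J.
#'
#' @param exprs genes x samples numeric matrix.
#' @param design a \linkS4class{PairDesign}.
#' @param seedGenes the two seed gene ids or row indices.
#' @param factor target factor name or index (within the co-factors).
#' @param direction +1 to maximise the coefficient, -1 to minimise.
#' @param geneOrderSeed RNG seed for the visiting order.
#' @param candidates gene row indices eligible for addition (default: all
#'   genes except the seed).
#' @param D precomputed gene-difference matrix (internal reuse).
#' @return list with \code{genes} (row indices of J), \code{fit} (the
#'   \linkS4class{DCoxFit} of J) and \code{trajectory} (coefficient after
#'   each accepted addition, seed first)
#' @export
expandSeed <- function(exprs, design, seedGenes, factor, direction = 1,
                       geneOrderSeed = 1L, candidates = NULL, D = NULL) {
  ctx <- .designContext(design)
  if (is.character(factor)) factor <- match(factor, ctx$factors)
  stopifnot(length(factor) == 1L, !is.na(factor), direction %in% c(-1, 1))
  if (is.character(seedGenes)) seedGenes <- match(seedGenes, rownames(exprs))
  if (is.null(D)) D <- .geneDiffs(exprs, design)
  if (is.null(candidates)) candidates <- seq_len(nrow(exprs))
  candidates <- setdiff(candidates, seedGenes)
  w <- .coefProjector(ctx)[factor + 1L, ]

  s <- colSums(D[seedGenes, , drop = FALSE])
  size <- 2L
  current <- sum(w * (s / size)^2)
  traj <- current
  set.seed(geneOrderSeed)
  remaining <- sample(candidates)
  genes <- seedGenes
  while (length(remaining)) {
    M <- (D[remaining, , drop = FALSE] +
            rep(s, each = length(remaining))) / (size + 1L)
    cand <- as.vector((M * M) %*% w)
    hit <- which(direction * (cand - current) > 0)
    if (!length(hit)) break
    pos <- hit[1L]
    gene <- remaining[pos]
    genes <- c(genes, gene)
    s <- s + D[gene, ]
    size <- size + 1L
    current <- cand[pos]
    traj <- c(traj, current)
    ## genes visited before the accepted one were evaluated against the
    ## same set and rejected; a single pass never revisits them
    remaining <- remaining[-seq_len(pos)]
  }
  gid <- rownames(exprs)[genes]
  list(genes = genes,
       fit = fitModel(statisticVector(exprs, genes, design), design,
                      genes = gid),
       trajectory = traj)
}

#' Augment a conservative set with weaker true constituents
#'
#' Computes the centroid expression profile of J and pairs every candidate
#' gene with it; candidates whose centroid-pair factor profile under the
#' relaxed thresholds T_ni equals the profile of J under T_oi form the
#' augmentation set K, and L = J \eqn{\cup} K is returned. The expansion
#' step only admits genes that improve the coefficient, so genuinely
#' co-expressed but weaker genes are recovered here while the profile of J
#' is preserved.
#'
#' @param exprs genes x samples numeric matrix.
#' @param design a \linkS4class{PairDesign}.
#' @param genes gene ids or row indices of J.
#' @param thresholds a \linkS4class{ThresholdSet} (or bare CT).
#' @param alpha interpolation weight of \code{\link{augmentationThreshold}}
#'   (1 = as stringent as T_oi, 0 = as stringent as F_i(J)); default 0.5.
#' @param candidates gene row indices eligible for augmentation (default:
#'   every gene in \code{exprs}).
#' @param pCut p-value cutoff used in the profiles.
#' @param D precomputed gene-difference matrix (internal reuse).
#' @return list with \code{genes} (row indices of L), \code{added} (K),
#'   \code{fit} (fit of L) and \code{profileJ}
#' @export
augmentSet <- function(exprs, design, genes, thresholds, alpha = 0.5,
                       candidates = NULL, pCut = 0.01, D = NULL) {
  CT <- if (is(thresholds, "ThresholdSet")) thresholds@CT else thresholds
  ctx <- .designContext(design)
  if (is.character(genes)) genes <- match(genes, rownames(exprs))
  if (is.null(D)) D <- .geneDiffs(exprs, design)
  if (is.null(candidates)) candidates <- seq_len(nrow(exprs))

  fitJ <- fitModel(statisticVector(exprs, genes, design), design,
                   genes = rownames(exprs)[genes])
  hJ <- factorProfile(fitJ, threshold = CT, pCut = pCut)
  Tni <- mapply(augmentationThreshold, Toi = CT, FiJ = fitJ@coefficients,
                alpha = alpha, h = hJ)
  if (all(hJ == 0L)) {
    ## no significant factor to preserve; nothing can match a null profile
    ## more informatively, keep J unchanged
    return(list(genes = sort(genes), added = integer(), fit = fitJ,
                profileJ = hJ))
  }
  cent <- colMeans(exprs[genes, , drop = FALSE])
  Dc <- cent[design@pairs[, 1L]] - cent[design@pairs[, 2L]]
  M <- (D[candidates, , drop = FALSE] + rep(Dc, each = length(candidates))) / 2
  A <- M * M
  co <- .batchCoef(ctx, t(A))
  pv <- .batchPvalues(ctx, t(A), co)
  co <- t(co[-1L, , drop = FALSE])
  pv <- t(pv[-1L, , drop = FALSE])
  thr <- matrix(abs(Tni), nrow(co), ncol(co), byrow = TRUE)
  h <- matrix(0L, nrow(co), ncol(co))
  h[co > thr & pv < pCut] <- 1L
  h[co < -thr & pv < pCut] <- -1L
  ## profile preservation is judged on the significant factors, as in the
  ## leave-one-out filter: a candidate must reproduce every |h_i| = 1 call
  ## of J; the h_i = 0 entries are unconstrained, since a chance tilt of an
  ## inactive factor shared by the whole set would otherwise split it on
  ## per-gene noise around the threshold
  sig <- which(hJ != 0L)
  match_ <- rowSums(h[, sig, drop = FALSE] ==
                      matrix(hJ[sig], nrow(h), length(sig), byrow = TRUE)) ==
    length(sig)
  K <- candidates[match_]
  L <- sort(union(genes, K))
  list(genes = L, added = setdiff(K, genes),
       fit = fitModel(statisticVector(exprs, L, design), design,
                      genes = rownames(exprs)[L]),
       profileJ = hJ)
}

#' Filter weak contributors from an augmented set
#'
#' For each gene g in L the pair Q = (g, centroid of L minus g) is fitted,
#' exactly as in the augmentation step; g is retained iff Q's factor
#' profile under the relaxed thresholds T_ni(L) equals the profile of L.
#' The leave-one-out pair coefficient is a clean per-gene membership score
#' -- close to F(L) for genuine members, strongly attenuated for genes the
#' set does not cohere with -- so genes failing the set's own profile at
#' T_ni are the false positives this step removes. The retained genes form
#' the final set R. For transparency the provenance also reports the two
#' alternative retention sets obtained by comparing |F(Q)| directly against
#' |F(L)| in either direction; on a pure set the pair score equals F(L) in
#' expectation, so either direct comparison removes members essentially at
#' random, which is why the threshold form is used. Degenerate cases: sets
#' of one or two genes are returned unchanged, and filtering never goes
#' below two genes.
#'
#' @param exprs genes x samples numeric matrix.
#' @param design a \linkS4class{PairDesign}.
#' @param genes gene ids or row indices of L.
#' @param thresholds a \linkS4class{ThresholdSet} (or bare CT), used for
#'   the significance profile of L.
#' @param alpha interpolation weight of the T_ni thresholds (as in
#'   \code{\link{augmentSet}}).
#' @param pCut p-value cutoff used in the profiles.
#' @param D precomputed gene-difference matrix (internal reuse).
#' @return list with \code{genes} (row indices of R), \code{removed},
#'   \code{fit} (fit of R), and \code{comparisonVariants}: retention sets
#'   under the direct coefficient comparisons (\code{keepIfBelow}:
#'   |F(Q)| < |F(L)| on every significant factor; \code{keepIfAbove}: the
#'   reverse), recorded when they differ from R
#' @export
filterSet <- function(exprs, design, genes, thresholds, alpha = 0.5,
                      pCut = 0.01, D = NULL) {
  CT <- if (is(thresholds, "ThresholdSet")) thresholds@CT else thresholds
  ctx <- .designContext(design)
  if (is.character(genes)) genes <- match(genes, rownames(exprs))
  genes <- sort(genes)
  nL <- length(genes)
  fitL <- fitModel(statisticVector(exprs, genes, design), design,
                   genes = rownames(exprs)[genes])
  if (nL <= 2L)
    return(list(genes = genes, removed = integer(), fit = fitL,
                comparisonVariants = NULL))
  hL <- factorProfile(fitL, threshold = CT, pCut = pCut)
  sig <- which(abs(hL) == 1L)
  if (!length(sig))
    return(list(genes = genes, removed = integer(), fit = fitL,
                comparisonVariants = NULL))
  if (is.null(D)) D <- .geneDiffs(exprs, design)
  Tni <- mapply(augmentationThreshold, Toi = CT, FiJ = fitL@coefficients,
                alpha = alpha, h = hL)
  DL <- D[genes, , drop = FALSE]
  DcL <- colMeans(DL)
  ## pair (g, centroid of L - g): its statistic row is linear in D rows
  M <- (DL * (1 - 1 / (nL - 1)) +
          rep(nL / (nL - 1) * DcL, each = nL)) / 2
  A <- M * M
  coFull <- .batchCoef(ctx, t(A))
  pvQ <- t(.batchPvalues(ctx, t(A), coFull)[-1L, , drop = FALSE])
  coQ <- t(coFull[-1L, , drop = FALSE])
  z <- ncol(coQ)
  thr <- matrix(abs(Tni), nL, z, byrow = TRUE)
  hQ <- matrix(0L, nL, z)
  hQ[coQ > thr & pvQ < pCut] <- 1L
  hQ[coQ < -thr & pvQ < pCut] <- -1L
  ## as in augmentation, only the |h_i| = 1 factors are examined
  keepMask <- rowSums(hQ[, sig, drop = FALSE] ==
                        matrix(hL[sig], nL, length(sig), byrow = TRUE)) ==
    length(sig)
  keep <- genes[keepMask]
  FLs <- matrix(abs(fitL@coefficients)[sig], nL, length(sig), byrow = TRUE)
  if (length(keep) < 2L) {
    ## never filter below two genes: fall back to the strongest members
    margin <- apply(abs(coQ[, sig, drop = FALSE]) / FLs, 1L, min)
    keep <- genes[order(!keepMask, -margin)][seq_len(2L)]
  }
  below <- genes[rowSums(abs(coQ[, sig, drop = FALSE]) < FLs) ==
                   length(sig)]
  above <- genes[rowSums(abs(coQ[, sig, drop = FALSE]) > FLs) ==
                   length(sig)]
  keep <- sort(keep)
  variants <- list()
  if (!identical(keep, sort(below))) variants$keepIfBelow <- sort(below)
  if (!identical(keep, sort(above))) variants$keepIfAbove <- sort(above)
  fitR <- fitModel(statisticVector(exprs, keep, design), design,
                   genes = rownames(exprs)[keep])
  list(genes = keep, removed = setdiff(genes, keep), fit = fitR,
       comparisonVariants = if (length(variants)) variants else NULL)
}

#' Run the full untargeted differential co-expression search
#'
#' Orchestrates the pipeline on a dataset: variance filter, pair
#' enumeration, threshold calibration, seed-pair scan, and then, for every
#' co-factor and direction (maximise, minimise), repeated
#' expand-augment-filter runs starting from the unused seed pair with the
#' largest directional coefficient whose genes are not already part of an
#' identified multi-gene set. All randomness derives from
#' \code{config$seed}, so identical configurations reproduce identical
#' results. Candidate sets are returned ungated; apply
#' \code{\link{gateSets}} for the reported sets.
#'
#' @param dataset a \linkS4class{DCoxDataSet}.
#' @param config a configuration list from \code{\link{dcoxConfig}}.
#' @param verbose print per-stage progress.
#' @return list with \code{sets} (list of \linkS4class{DCXGeneSet}),
#'   \code{thresholds}, \code{design}, \code{seeds} (seed-scan summary),
#'   \code{genes} (gene ids surviving the variance filter) and
#'   \code{config}
#' @export
runSearch <- function(dataset, config = dcoxConfig(), verbose = FALSE) {
  exprs <- filterByVariance(exprValues(dataset), config$minVarianceQuantile)
  design <- enumeratePairs(dataset, maxPairs = config$maxPairs,
                           seed = config$seed + 1L)
  thresholds <- calibrateCT(exprs, design,
                            nRandomPairs = config$nRandomPairs,
                            m = config$m, seed = config$seed + 2L)
  if (verbose)
    message(nrow(exprs), " genes after variance filter; ",
            nPairs(design), " sample pairs; CT = ",
            signif(thresholds@CT, 4))
  seeds <- findSeedPairs(exprs, design, thresholds,
                         splitHalf = config$splitHalf,
                         seed = config$seed + 3L, pCut = config$seedPCut)
  if (verbose) message(nrow(seeds$pairs), " seed pairs")
  ctx <- .designContext(design)
  z <- length(ctx$factors)
  D <- .geneDiffs(exprs, design)
  candidatePool <- if (config$readmitDropped) seq_len(nrow(exprs)) else
    seeds$candidates

  identified <- logical(nrow(exprs))
  sets <- list()
  CT <- thresholds@CT
  gid <- rownames(exprs)
  for (k in seq_len(z)) for (dir in c(1, -1)) {
    sel <- which(sign(seeds$coef[, k]) == dir &
                   abs(seeds$coef[, k]) > CT &
                   seeds$pval[, k] < config$seedPCut)
    if (!length(sel)) next
    ## largest |coefficient| first; ties by gene ids for determinism
    ord <- sel[order(-abs(seeds$coef[sel, k]),
                     gid[seeds$pairs[sel, 1L]],
                     gid[seeds$pairs[sel, 2L]])]
    found <- 0L
    for (sidx in ord) {
      if (found >= config$maxSetsPerDirection) break
      pr <- seeds$pairs[sidx, ]
      if (identified[pr[1L]] || identified[pr[2L]]) next
      exp_ <- expandSeed(exprs, design, pr, k, dir,
                         geneOrderSeed = config$seed + 7L * sidx + k,
                         candidates = seeds$candidates[
                           !identified[seeds$candidates]],
                         D = D)
      aug <- augmentSet(exprs, design, exp_$genes, thresholds,
                        alpha = config$alpha,
                        candidates = candidatePool, pCut = config$seedPCut,
                        D = D)
      fin <- filterSet(exprs, design, aug$genes, thresholds,
                       alpha = config$alpha, pCut = config$seedPCut, D = D)
      prof <- factorProfile(fin$fit, threshold = CT, pCut = config$seedPCut)
      sets[[length(sets) + 1L]] <- new(
        "DCXGeneSet",
        genes = gid[fin$genes], fit = fin$fit, profile = prof,
        provenance = list(
          seed = gid[pr], factor = ctx$factors[k], direction = dir,
          seedCoefficient = seeds$coef[sidx, k],
          sizes = c(J = length(exp_$genes), L = length(aug$genes),
                    R = length(fin$genes)),
          trajectory = exp_$trajectory,
          profileJ = aug$profileJ,
          profileL = factorProfile(aug$fit, threshold = CT,
                                   pCut = config$seedPCut),
          comparisonVariants = if (is.null(fin$comparisonVariants)) NULL
                               else lapply(fin$comparisonVariants,
                                           function(v) gid[v])))
      found <- found + 1L
      if (length(fin$genes) >= 3L) identified[fin$genes] <- TRUE
      if (verbose)
        message(ctx$factors[k], ifelse(dir > 0, "+", "-"), " set ",
                length(sets), ": |J|=", length(exp_$genes),
                " |L|=", length(aug$genes), " |R|=", length(fin$genes))
    }
  }
  list(sets = sets, thresholds = thresholds, design = design,
       seeds = list(n = nrow(seeds$pairs), CT = CT,
                    splitHalf = seeds$splitHalf),
       genes = gid, config = config)
}
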