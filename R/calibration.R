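#' Calibrate the global coefficient-significance threshold C_T
#'
#' Samples random gene pairs, fits the multi-factor model to each pair's
#' statistic vector with one shared QR factorisation, pools the absolute
#' values of all factor coefficients across pairs, and sets
#' \deqn{C_T = \frac{1}{2}\,m\textrm{-th largest pooled value}}
#' (m = 10 by default). Halving avoids a damagingly strict threshold at the
#' start of the search, and m > 1 guards against the sampled pairs
#' themselves containing genuinely differentially co-expressed pairs, which
#' would overestimate the threshold.
#'
#' @param exprs genes x samples numeric matrix.
#' @param design a \linkS4class{PairDesign}.
#' @param nRandomPairs number of gene pairs to sample (without
#'   replacement); default 10000.
#' @param m order-statistic index; default 10.
#' @param seed RNG seed for pair sampling.
#' @return a \linkS4class{ThresholdSet}
#' @export
calibrateCT <- function(exprs, design, nRandomPairs = 10000L, m = 10L,
                        seed = 1L) {
  g <- nrow(exprs)
  z <- ncol(design@design) - 1L
  total <- g * (g - 1) / 2
  nRandomPairs <- as.integer(min(nRandomPairs, total))
  if (nRandomPairs * z < m)
    stop("fewer than m = ", m, " pooled coefficients; ",
         "increase nRandomPairs or reduce m")
  set.seed(seed)
  idx <- .sampleGenePairs(g, nRandomPairs)
  D <- .geneDiffs(exprs, design)
  A <- ((D[idx[, 1L], , drop = FALSE] + D[idx[, 2L], , drop = FALSE]) / 2)^2
  co <- batchFitCoefficients(A, design)
  pooled <- sort(abs(as.vector(co)), decreasing = TRUE)
  new("ThresholdSet", CT = pooled[m] / 2, m = as.integer(m),
      nRandomPairs = nRandomPairs, seed = as.integer(seed))
}

## uniform sample of n unordered gene pairs (i < j) without replacement,
## by decoding pair ranks drawn from 1..C(g,2)
.sampleGenePairs <- function(g, n) {
  total <- g * (g - 1) / 2
  r <- if (total <= 2^31 - 1) sample.int(total, n)
  else unique(ceiling(runif(2 * n) * total))[seq_len(n)]
  ## rank -> (i, j): i is the largest index with offset(i) < r
  i <- ceiling((2 * g - 1 - sqrt((2 * g - 1)^2 - 8 * r)) / 2)
  off <- (i - 1) * g - i * (i - 1) / 2
  j <- r - off + i
  ## guard against floating point at the boundary
  bad <- j <= i | j > g
  if (any(bad)) {
    i[bad] <- i[bad] - 1L
    off <- (i[bad] - 1) * g - i[bad] * (i[bad] - 1) / 2
    j[bad] <- r[bad] - off + i[bad]
  }
  cbind(as.integer(i), as.integer(j))
}

## per-gene expression differences over the design's sample pairs
## (genes x a); row i is E_i,m - E_i,n over all pairs (m, n)
.geneDiffs <- function(exprs, design) {
  p <- design@pairs
  exprs[, p[, 1L], drop = FALSE] - exprs[, p[, 2L], drop = FALSE]
}

#' Directional seed threshold
#'
#' The signed threshold T_oi applied to factor i for a particular set:
#' +C_T when the fitted coefficient is positive, -C_T when negative.
#'
#' @param CT nonnegative calibrated threshold (or a
#'   \linkS4class{ThresholdSet}).
#' @param sign +1 or -1, the direction of the fitted coefficient.
#' @return signed threshold
#' @export
directionalThreshold <- function(CT, sign) {
  if (is(CT, "ThresholdSet")) CT <- CT@CT
  stopifnot(sign %in% c(-1, 1))
  sign * CT
}

#' Relaxed augmentation threshold T_ni
#'
#' For a factor significant on the conservative set J (|h_i| = 1) the
#' augmentation threshold interpolates between the seed threshold and the
#' set's own coefficient:
#' \deqn{T_{ni} = \mathrm{Sign}(F_i(J))\,(\alpha |T_{oi}| +
#'   (1-\alpha)|F_i(J)|), \quad 0 \le \alpha \le 1,}
#' so it is at least as stringent as T_oi and at most equal to F_i(J). For
#' factors not significant on J the magnitude |T_oi| is used.
#'
#' @param Toi signed (or absolute) seed threshold for the factor.
#' @param FiJ fitted coefficient of the factor on J.
#' @param alpha interpolation weight in [0, 1]; 1 reduces to T_oi,
#'   0 to F_i(J).
#' @param h signed significance call of the factor on J (-1, 0, +1).
#' @return signed threshold (its magnitude when h = 0)
#' @export
augmentationThreshold <- function(Toi, FiJ, alpha, h) {
  stopifnot(alpha >= 0, alpha <= 1, h %in% c(-1L, 0L, 1L))
  if (abs(h) == 1)
    sign(FiJ) * (alpha * abs(Toi) + (1 - alpha) * abs(FiJ))
  else abs(Toi)
}

#' Signed factor profile of a fit under given threshold magnitudes
#'
#' The factor profile FP assigns each factor h_i = +1 if its coefficient
#' exceeds the threshold magnitude and its p-value is below \code{pCut},
#' h_i = -1 if it falls below the negated magnitude with p below
#' \code{pCut}, and h_i = 0 otherwise.
#'
#' @param coefs numeric factor coefficients (or a \linkS4class{DCoxFit}).
#' @param pvals per-factor p-values (taken from the fit when omitted).
#' @param threshold threshold magnitude(s), recycled over factors; signed
#'   values are used by magnitude.
#' @param pCut p-value cutoff, default 0.01.
#' @return named integer vector in \{-1, 0, +1\}
#' @export
factorProfile <- function(coefs, pvals = NULL, threshold, pCut = 0.01) {
  if (is(coefs, "DCoxFit")) {
    pvals <- coefs@pvalues
    coefs <- coefs@coefficients
  }
  thr <- abs(rep_len(threshold, length(coefs)))
  h <- integer(length(coefs))
  h[coefs > thr & pvals < pCut] <- 1L
  h[coefs < -thr & pvals < pCut] <- -1L
  names(h) <- names(coefs)
  h
}
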