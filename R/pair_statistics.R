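#' Pairwise co-expression statistic for a gene set
#'
#' For a gene set I and a within-stratum sample pair (m, n), the statistic
#' is the squared mean expression change
#' \deqn{A_{mn}(I) = \left(\frac{1}{|I|}\sum_{i \in I}(E_{im}-E_{in})\right)^2.}
#' It is large when the set shifts coherently between the two samples
#' (co-expression) and near zero when per-gene changes are incoherent and
#' cancel; it is symmetric in m and n, nonnegative, and invariant to adding
#' a constant to all expression values.
#'
#' @param exprs genes x samples numeric matrix.
#' @param genes gene ids or row indices of the set I (nonempty).
#' @param m,n sample ids or column indices.
#' @return a nonnegative scalar
#' @examples
#' ex <- matrix(c(3, 2, 1, 2), 2, 2,
#'              dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' pairStatistic(ex, "g1", "s1", "s2")  # ((3-1)/1)^2 = 4
#' @export
pairStatistic <- function(exprs, genes, m, n) {
  if (length(genes) == 0L) stop("gene set must be nonempty")
  d <- exprs[genes, m] - exprs[genes, n]
  mean(d)^2
}

#' Vector of co-expression statistics over all design pairs
#'
#' Element i is \code{pairStatistic} of the set over the i-th sample pair of
#' the design. Computed via the set centroid: the mean change of the set
#' equals the change of the per-sample mean expression.
#'
#' @param exprs genes x samples numeric matrix.
#' @param genes gene ids or row indices of the set (nonempty).
#' @param design a \linkS4class{PairDesign} built on the same samples.
#' @return numeric vector of length \code{nPairs(design)}
#' @export
statisticVector <- function(exprs, genes, design) {
  if (length(genes) == 0L) stop("gene set must be nonempty")
  cent <- if (length(genes) == 1L) exprs[genes, ] else
    colMeans(exprs[genes, , drop = FALSE])
  p <- design@pairs
  unname((cent[p[, 1L]] - cent[p[, 2L]])^2)
}

## One QR factorisation of the design, reused across all model fits of a
## run. Returns the pieces every fit needs: qr object, unscaled coefficient
## variances and residual df.
.designContext <- function(design) {
  X <- design@design
  a <- nrow(X)
  k <- ncol(X)
  if (a <= k) stop("need more sample pairs (", a, ") than model terms (",
                   k, "); a > z + 1 is required")
  qx <- qr(X)
  if (qx$rank < k) {
    piv <- qx$pivot[seq_len(qx$rank)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[setdiff(seq_len(k), piv)], collapse = ", "))
  }
  R <- qr.R(qx)
  XtXinv <- chol2inv(R)
  list(qr = qx, X = X, df = a - k, dvar = diag(XtXinv),
       factors = colnames(X)[-1L])
}

## Batch OLS: responses as COLUMNS of Y (a x k). Returns coefficients
## ((z+1) x k) from the shared QR.
.batchCoef <- function(ctx, Y) qr.coef(ctx$qr, Y)

## Per-coefficient partial F-test p-values for batch responses (columns of
## Y), given their coefficient matrix. F = (coef/se)^2 with df (1, a-z-1);
## identical to the squared t-test of summary.lm.
.batchPvalues <- function(ctx, Y, coefs) {
  res <- Y - ctx$X %*% coefs
  rss <- colSums(res^2)
  sigma2 <- rss / ctx$df
  se <- sqrt(outer(ctx$dvar, sigma2))
  Fstat <- (coefs / se)^2
  ## exact fits (zero residual up to rounding): a coefficient that is
  ## itself numerically zero is null, anything else infinitely significant
  exact <- which(rss <= 1e-20 * pmax(colSums(Y * Y), .Machine$double.xmin))
  for (j in exact) {
    ys <- max(sqrt(mean(Y[, j]^2)), 1e-300)
    Fstat[, j] <- ifelse(abs(coefs[, j]) <= 1e-8 * ys, 0, Inf)
  }
  pf(Fstat, 1, ctx$df, lower.tail = FALSE)
}

#' Fit the multi-factor co-expression model for one gene set
#'
#' Ordinary least squares of the pairwise statistic vector A(I) on
#' \code{(intercept | co-factors)}. The intercept absorbs co-expression
#' common to all strata (for example a set co-expressed in every sample),
#' so that only factor-dependent co-expression loads on the factor
#' coefficients. Per-factor p-values are single-coefficient partial F-tests
#' (df 1, a - z - 1); dependence among pairs sharing a sample is ignored
#' here, so they are nominal and gated downstream by permutation.
#'
#' @param A numeric statistic vector (length = number of pairs), or a gene
#'   id vector if \code{exprs} is supplied.
#' @param design a \linkS4class{PairDesign}.
#' @param exprs optional genes x samples matrix; when given, \code{A} is
#'   interpreted as a gene set and the statistic vector is computed first.
#' @param genes gene ids recorded in the returned fit.
#' @return a \linkS4class{DCoxFit}
#' @export
fitModel <- function(A, design, exprs = NULL, genes = character()) {
  if (!is.null(exprs)) {
    genes <- A
    if (is.numeric(genes)) genes <- rownames(exprs)[genes]
    A <- statisticVector(exprs, genes, design)
  }
  stopifnot(length(A) == nrow(design@design))
  ctx <- .designContext(design)
  Y <- matrix(A, ncol = 1L)
  co <- .batchCoef(ctx, Y)
  pv <- .batchPvalues(ctx, Y, co)
  new("DCoxFit",
      coefficients = stats::setNames(co[-1L, 1L], ctx$factors),
      intercept = co[1L, 1L],
      pvalues = stats::setNames(pv[-1L, 1L], ctx$factors),
      genes = as.character(genes), df = ctx$df)
}

#' Batch coefficient estimation for many statistic vectors
#'
#' Fits the same design to k responses with a single QR factorisation
#' (the batch \code{qr.coef} strategy), returning factor coefficients only.
#' P-values are deliberately not computed here: in the seed scan they are
#' evaluated only for pairs surviving the coefficient-magnitude filter,
#' which is the main speed gain over per-response \code{lm}.
#'
#' @param A numeric matrix of k statistic vectors in rows (k x a).
#' @param design a \linkS4class{PairDesign} with at least one co-factor.
#' @return k x z matrix of factor coefficients (intercept dropped)
#' @export
batchFitCoefficients <- function(A, design) {
  A <- rbind(A)
  if (ncol(design@design) < 2L)
    stop("at least one co-factor is required (z >= 1)")
  ctx <- .designContext(design)
  stopifnot(ncol(A) == nrow(ctx$X))
  co <- .batchCoef(ctx, t(A))
  out <- t(co[-1L, , drop = FALSE])
  colnames(out) <- ctx$factors
  out
}

#' @rdname DCXGeneSet-accessors
#' @export
setMethod("geneIds", "DCoxFit", function(x) x@genes)

#' @rdname DCXGeneSet-accessors
#' @export
setMethod("pvalues", "DCoxFit", function(x) x@pvalues)

#' @describeIn fitModel factor coefficients of a fit (intercept excluded)
#' @param object a \linkS4class{DCoxFit}
#' @param ... unused
#' @export
setMethod("coef", "DCoxFit", function(object, ...) object@coefficients)

setMethod("show", "DCoxFit", function(object) {
  cat("DCoxFit on", length(object@genes), "genes\n")
  print(round(rbind(coefficient = object@coefficients,
                    p.value = object@pvalues), 4))
  cat("intercept:", signif(object@intercept, 4), "\n")
})
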