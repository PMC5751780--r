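#' Construct a DCoxDataSet
#'
#' Bundles a genes x samples expression matrix with per-sample co-factor
#' codes. Expression values are assumed already log-transformed and
#' normalised; no normalisation is performed. Factor values must already be
#' numeric codes: binary factors as -1/+1, ordinal factors as small
#' integers (e.g. -1/0/+1). Use \code{\link{recodeCategorical}} to turn a
#' categorical column into binary columns and \code{\link{discretizeFactor}}
#' for real-valued covariates.
#'
#' @param exprs numeric matrix, genes in rows (unique rownames) and samples
#'   in columns (unique colnames), all values finite.
#' @param factors data.frame or matrix of numeric factor codes with one row
#'   per sample; rownames (if present) must match \code{colnames(exprs)}.
#' @return a \linkS4class{DCoxDataSet}
#' @examples
#' ex <- matrix(rnorm(30), 5, 6,
#'              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
#' fac <- data.frame(grp = rep(c(-1, 1), each = 3), row.names = colnames(ex))
#' dset <- DCoxDataSet(ex, fac)
#' @export
DCoxDataSet <- function(exprs, factors) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  factors <- as.data.frame(factors)
  if (nrow(factors) != ncol(exprs))
    stop("factor table must have one row per sample (",
         nrow(factors), " rows vs ", ncol(exprs), " samples)")
  if (!is.null(rownames(factors)) &&
      !identical(rownames(factors), as.character(seq_len(nrow(factors)))) &&
      !is.null(colnames(exprs))) {
    if (!setequal(rownames(factors), colnames(exprs)))
      stop("factor table sample ids do not match expression sample ids")
    factors <- factors[colnames(exprs), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(factors, row.names = colnames(exprs))
  )
  new("DCoxDataSet", se, factorNames = colnames(factors))
}

#' @rdname DCoxDataSet
#' @export
setMethod("factorNames", "DCoxDataSet", function(x) x@factorNames)

#' @rdname DCoxDataSet
#' @export
setMethod("exprValues", "DCoxDataSet",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname DCoxDataSet
#' @export
setMethod("factorTable", "DCoxDataSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- as.matrix(as.data.frame(cd[, x@factorNames, drop = FALSE]))
  rownames(m) <- colnames(x)
  m
})

setMethod("show", "DCoxDataSet", function(object) {
  cat("DCoxDataSet:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("co-factors:", paste(object@factorNames, collapse = ", "), "\n")
  st <- buildStrata(object)
  cat("strata:", length(st), "(",
      sum(lengths(lapply(st, `[[`, "samples")) == 1L), "singleton )\n")
})

## ---- file readers -------------------------------------------------------

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids; all
#' remaining cells numeric. Offending lines are named in load errors.
#' Optionally drops low-variance genes: with
#' \code{minVarianceQuantile = q}, genes whose across-sample variance falls
#' below the q-th quantile of all gene variances are removed (q = 0 keeps
#' every gene). Low-variance filtering can remove a large share of
#' undetected probes and the downstream search is at least quadratic in the
#' number of genes, so this is the main computational lever.
#'
#' @param path path to the tab-delimited file.
#' @param minVarianceQuantile fraction in [0, 1]; default 0 (no filter).
#' @return numeric matrix with gene rownames and sample colnames
#' @export
readExpression <- function(path, minVarianceQuantile = 0) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file needs a header and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sampleIds <- header[-1L]
  nf <- length(sampleIds) + 1L
  width <- lengths(fields[-1L])
  if (any(width != nf))
    stop("ragged row at line ", which(width != nf)[1L] + 1L,
         ": expected ", nf, " fields, found ", width[width != nf][1L])
  geneIds <- vapply(fields[-1L], `[[`, "", 1L)
  if (anyDuplicated(geneIds))
    stop("duplicated gene id '", geneIds[duplicated(geneIds)][1L],
         "' at line ", which(duplicated(geneIds))[1L] + 1L)
  if (anyDuplicated(sampleIds))
    stop("duplicated sample id in header: ",
         sampleIds[duplicated(sampleIds)][1L])
  vals <- suppressWarnings(
    vapply(fields[-1L], function(f) as.numeric(f[-1L]),
           numeric(length(sampleIds))))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop("non-numeric or missing cell at line ", bad + 1L,
         " (gene '", geneIds[bad], "')")
  }
  dimnames(vals) <- list(geneIds, sampleIds)
  filterByVariance(vals, minVarianceQuantile)
}

#' Drop low-variance genes
#'
#' @param exprs genes x samples numeric matrix.
#' @param minVarianceQuantile fraction in [0, 1]: genes with across-sample
#'   variance strictly below this quantile of the variance distribution are
#'   removed; 0 keeps all genes.
#' @return the filtered matrix
#' @export
filterByVariance <- function(exprs, minVarianceQuantile = 0) {
  stopifnot(minVarianceQuantile >= 0, minVarianceQuantile <= 1)
  if (minVarianceQuantile == 0) return(exprs)
  v <- rowVars(exprs)
  exprs[v >= quantile(v, minVarianceQuantile), , drop = FALSE]
}

## row variances without forming per-row calls; ok for dense doubles
rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}

#' Read a tab-delimited factor table
#'
#' First column sample id, remaining columns numeric co-factor codes.
#'
#' @param path path to the tab-delimited file.
#' @return data.frame of factor codes with sample-id rownames
#' @export
readFactorTable <- function(path) {
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  if (anyDuplicated(rownames(tab))) stop("duplicated sample id in ", path)
  for (j in colnames(tab))
    if (!is.numeric(tab[[j]]))
      stop("factor column '", j, "' is not numeric; recode it first")
  tab
}

## ---- factor recoding helpers -------------------------------------------

#' Recode a categorical covariate into binary -1/+1 columns
#'
#' A categorical factor with k levels becomes k - 1 binary columns, one per
#' non-reference level, coded +1 for samples at that level and -1 otherwise.
#'
#' @param values vector of category labels.
#' @param name prefix for the generated column names.
#' @param reference reference level (default: first sorted level).
#' @return data.frame of k - 1 columns of -1/+1 codes
#' @export
recodeCategorical <- function(values, name = "factor", reference = NULL) {
  lev <- sort(unique(as.character(values)))
  if (length(lev) < 2L) stop("categorical factor needs >= 2 levels")
  if (is.null(reference)) reference <- lev[1L]
  if (!reference %in% lev) stop("reference level not among the values")
  out <- lapply(setdiff(lev, reference), function(l)
    ifelse(as.character(values) == l, 1, -1))
  names(out) <- paste(name, setdiff(lev, reference), sep = ".")
  as.data.frame(out)
}

#' Discretize a real-valued covariate into ordinal codes
#'
#' Bins by user-supplied edges and maps the k bins onto codes evenly spaced
#' in [-1, 1] (so 3 bins give -1/0/+1).
#'
#' @param values numeric vector.
#' @param breaks full set of bin edges as for \code{cut} (length k + 1,
#'   spanning the data).
#' @return numeric vector of ordinal codes
#' @export
discretizeFactor <- function(values, breaks) {
  b <- cut(values, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  if (anyNA(b)) stop("bin edges do not span the data")
  k <- length(breaks) - 1L
  seq(-1, 1, length.out = k)[b]
}

## ---- strata and pairs ---------------------------------------------------

#' Group samples into strata of identical co-factor vectors
#'
#' @param x a \linkS4class{DCoxDataSet}, or a numeric matrix/data.frame of
#'   factor codes with one row per sample.
#' @return list of strata; each element is
#'   \code{list(vector = <factor codes>, samples = <sample indices>,
#'   singleton = <logical>)}. Singleton strata are retained (they yield no
#'   pairs) and flagged.
#' @export
buildStrata <- function(x) {
  ft <- if (is(x, "DCoxDataSet")) factorTable(x) else as.matrix(x)
  key <- apply(ft, 1L, paste, collapse = "\r")
  groups <- split(seq_len(nrow(ft)), factor(key, levels = unique(key)))
  st <- lapply(groups, function(idx)
    list(vector = ft[idx[1L], ], samples = idx, singleton = length(idx) == 1L))
  names(st) <- vapply(st, function(s) paste(s$vector, collapse = ","), "")
  unname(st)
}

#' Enumerate within-stratum sample pairs and build the regression design
#'
#' All unordered pairs of samples sharing a stratum, with the design matrix
#' whose row for pair (m, n) is \code{(1, B_mn)} -- the stratum's co-factor
#' vector behind an intercept. If the total pair count exceeds
#' \code{maxPairs}, a uniform random subset of that size is drawn (seeded),
#' always keeping at least one pair per non-singleton stratum; subsampling
#' to as little as ~10\% of all pairs is a supported cost reduction.
#'
#' @param x a \linkS4class{DCoxDataSet}.
#' @param maxPairs maximum number of pairs to keep (default Inf: keep all).
#' @param seed RNG seed for the subsample.
#' @return a \linkS4class{PairDesign}
#' @export
enumeratePairs <- function(x, maxPairs = Inf, seed = 1L) {
  strata <- buildStrata(x)
  ft <- factorTable(x)
  z <- ncol(ft)
  plist <- list()
  sid <- integer()
  for (k in seq_along(strata)) {
    s <- strata[[k]]
    ns <- length(s$samples)
    if (ns < 2L) next
    cmb <- utils::combn(sort(s$samples), 2L)
    plist[[length(plist) + 1L]] <- t(cmb)
    sid <- c(sid, rep.int(k, ncol(cmb)))
  }
  if (!length(plist))
    stop("no two samples share a stratum: every sample has a unique ",
         "co-factor vector, so no within-stratum pairs exist")
  nSingle <- sum(vapply(strata, function(s) length(s$samples) == 1L, TRUE))
  if (nSingle > 0L)
    warning(nSingle, " singleton stratum(s) contribute no sample pairs")
  pairs <- do.call(rbind, plist)
  if (nrow(pairs) > maxPairs) {
    if (maxPairs < length(unique(sid)))
      stop("maxPairs smaller than the number of non-singleton strata")
    set.seed(seed)
    keep <- vapply(split(seq_len(nrow(pairs)), sid),
                   function(ix) if (length(ix) == 1L) ix else sample(ix, 1L),
                   integer(1L))
    pool <- setdiff(seq_len(nrow(pairs)), keep)
    extra <- sample(pool, maxPairs - length(keep))
    sel <- sort(c(keep, extra))
    pairs <- pairs[sel, , drop = FALSE]
    sid <- sid[sel]
  }
  design <- cbind(1, ft[pairs[, 1L], , drop = FALSE])
  colnames(design) <- c("(Intercept)", colnames(ft))
  rownames(design) <- NULL
  dimnames(pairs) <- NULL
  new("PairDesign", pairs = pairs, design = design,
      strata = as.integer(sid), sampleIds = colnames(x))
}

#' @rdname PairDesign-accessors
#' @export
setMethod("designMatrix", "PairDesign", function(x) x@design)

#' @rdname PairDesign-accessors
#' @export
setMethod("pairIndices", "PairDesign", function(x) x@pairs)

#' @rdname PairDesign-accessors
#' @export
setMethod("nPairs", "PairDesign", function(x) nrow(x@pairs))

setMethod("show", "PairDesign", function(object) {
  cat("PairDesign:", nrow(object@pairs), "within-stratum sample pairs,",
      ncol(object@design) - 1L, "co-factors,",
      length(unique(object@strata)), "strata\n")
})
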