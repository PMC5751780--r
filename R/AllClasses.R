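#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats coef density lm.fit pf quantile rnorm runif sd var
#' @importFrom utils head
NULL

#' DCoxDataSet: expression matrix plus per-sample co-factor annotation
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"exprs"}
#' holds a genes x samples matrix of (log-scale, normalised) expression
#' values and whose \code{colData} carries the numeric co-factor codes for
#' each sample. Co-factors are binary (-1/+1) or ordinal small-integer
#' (-1/0/+1 style) codes; samples sharing an identical co-factor vector form
#' a stratum, and only within-stratum sample pairs enter the differential
#' co-expression model.
#'
#' @slot factorNames character vector naming the co-factor columns of
#'   \code{colData} that enter the model, in model order.
#'
#' @seealso \code{\link{DCoxDataSet}} (constructor),
#'   \code{\link{buildStrata}}, \code{\link{enumeratePairs}}
#' @export
setClass("DCoxDataSet",
  contains = "SummarizedExperiment",
  representation(factorNames = "character")
)

setValidity("DCoxDataSet", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    e <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(e)) msg <- c(msg, "expression values must be numeric")
    else if (!all(is.finite(e)))
      msg <- c(msg, "expression values must all be finite (no NA/NaN/Inf)")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  fn <- object@factorNames
  if (length(fn) < 1L) msg <- c(msg, "at least one co-factor is required")
  cd <- SummarizedExperiment::colData(object)
  missing <- setdiff(fn, colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("co-factor column(s) absent from colData: ",
                         paste(missing, collapse = ", ")))
  else for (f in fn) {
    v <- cd[[f]]
    if (!is.numeric(v) || !all(is.finite(v)))
      msg <- c(msg, paste0("co-factor '", f, "' must be finite numeric codes"))
    else if (length(unique(v)) < 2L)
      msg <- c(msg, paste0("co-factor '", f, "' is constant; ",
                           "each factor needs >= 2 distinct values"))
  }
  if (length(msg)) msg else TRUE
})

#' PairDesign: within-stratum sample pairs and their regression design
#'
#' Holds the enumerated (possibly subsampled) within-stratum sample pairs
#' and the corresponding design matrix whose rows are
#' \code{(1, B_mn)} -- an intercept column followed by the shared co-factor
#' vector of each pair's stratum. Row \code{i} of \code{design} corresponds
#' to row \code{i} of \code{pairs}.
#'
#' @slot pairs integer matrix (a x 2) of sample indices, first column
#'   strictly less than the second.
#' @slot design numeric matrix (a x (z+1)); columns
#'   \code{("(Intercept)", factor names)}. Checked for full column rank.
#' @slot strata integer vector of length a giving each pair's stratum id.
#' @slot sampleIds character vector of the sample ids the indices refer to.
#' @export
setClass("PairDesign",
  representation(pairs = "matrix", design = "matrix",
                 strata = "integer", sampleIds = "character")
)

setValidity("PairDesign", function(object) {
  msg <- character()
  p <- object@pairs
  X <- object@design
  if (ncol(p) != 2L) msg <- c(msg, "pairs must have two columns")
  if (nrow(p) != nrow(X))
    msg <- c(msg, "pairs and design must have the same number of rows")
  if (nrow(p) && any(p[, 1L] >= p[, 2L]))
    msg <- c(msg, "pairs must be canonically ordered (m < n)")
  if (length(object@strata) != nrow(p))
    msg <- c(msg, "strata must have one entry per pair")
  if (ncol(X) < 2L)
    msg <- c(msg, "design needs an intercept and at least one factor")
  if (nrow(X) >= ncol(X) && qr(X)$rank < ncol(X))
    msg <- c(msg, "design matrix is rank deficient")
  if (length(msg)) msg else TRUE
})

#' DCoxFit: fitted multi-factor co-expression model for one gene set
#'
#' Ordinary-least-squares fit of the pairwise co-expression statistic
#' \eqn{A(I)} on the stratum co-factor vectors. The factor coefficient
#' vector is the differential co-expression profile \eqn{F(I)}; per-factor
#' p-values come from the single-coefficient partial F-test
#' (df = 1, a - z - 1).
#'
#' @slot coefficients named numeric vector of factor coefficients (length z,
#'   intercept excluded).
#' @slot intercept baseline co-expression level common to all strata.
#' @slot pvalues named numeric vector of per-factor partial F-test p-values.
#' @slot genes character vector of the gene set the fit describes.
#' @slot df integer residual degrees of freedom.
#' @export
setClass("DCoxFit",
  representation(coefficients = "numeric", intercept = "numeric",
                 pvalues = "numeric", genes = "character", df = "integer")
)

setValidity("DCoxFit", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@pvalues))
    msg <- c(msg, "coefficients and pvalues must have equal length")
  p <- object@pvalues
  if (length(p) && (any(p < 0) || any(p > 1)))
    msg <- c(msg, "pvalues must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ThresholdSet: calibrated coefficient-significance threshold
#'
#' The global absolute threshold \eqn{C_T} derived from the pooled absolute
#' coefficients of randomly sampled gene pairs: half of the m-th largest
#' pooled value. Directional seed thresholds \eqn{T_{oi}} and relaxed
#' augmentation thresholds \eqn{T_{ni}} are derived from it.
#'
#' @slot CT nonnegative absolute significance threshold.
#' @slot m order-statistic index (default 10); m >= 2 guards against the
#'   sampled pairs themselves containing genuinely DCX pairs.
#' @slot nRandomPairs number of random gene pairs pooled.
#' @slot seed RNG seed used for pair sampling.
#' @export
setClass("ThresholdSet",
  representation(CT = "numeric", m = "integer",
                 nRandomPairs = "integer", seed = "integer")
)

setValidity("ThresholdSet", function(object) {
  msg <- character()
  if (object@CT < 0) msg <- c(msg, "CT must be nonnegative")
  if (object@m < 2L) msg <- c(msg, "m must be >= 2")
  if (length(msg)) msg else TRUE
})

#' DCXGeneSet: a candidate differentially co-expressed gene set
#'
#' A gene set produced by one seed-pair run of the greedy search, together
#' with its fitted model and signed factor profile. The profile entry for
#' factor i is +1 (co-expression increases with the factor), -1 (decreases)
#' or 0 (no significant influence).
#'
#' @slot genes character vector of member gene ids (the final set R).
#' @slot fit the \linkS4class{DCoxFit} of the set.
#' @slot profile named integer vector in \{-1, 0, +1\}, one entry per factor.
#' @slot provenance list recording the seed pair, target factor, direction,
#'   per-stage set sizes and related diagnostics.
#' @export
setClass("DCXGeneSet",
  representation(genes = "character", fit = "DCoxFit",
                 profile = "integer", provenance = "list")
)

setValidity("DCXGeneSet", function(object) {
  msg <- character()
  if (!all(object@profile %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "profile entries must be -1, 0 or +1")
  if (length(object@profile) != length(object@fit@coefficients))
    msg <- c(msg, "profile must have one entry per factor")
  if (length(msg)) msg else TRUE
})

#' EffectThresholds: effect-size significance thresholds from density valleys
#'
#' Thresholds \eqn{T_{f+} > 0 > T_{f-}} placed at the first density valleys
#' either side of the central (near-zero) mode of the pooled coefficient
#' distribution across all identified sets. When a side shows no mode beyond
#' the centre, the signed 97.5th percentile of that side is used instead and
#' the fallback flag is set.
#'
#' @slot tfPlus positive threshold.
#' @slot tfMinus negative threshold.
#' @slot fallback logical length 2 (negative side, positive side).
#' @slot bandwidth kernel bandwidth used (Silverman's rule).
#' @export
setClass("EffectThresholds",
  representation(tfPlus = "numeric", tfMinus = "numeric",
                 fallback = "logical", bandwidth = "numeric")
)

setValidity("EffectThresholds", function(object) {
  if (object@tfMinus < 0 && object@tfPlus > 0) TRUE
  else "need tfMinus < 0 < tfPlus"
})

#' DCoxResults: full output of a differential co-expression run
#'
#' All candidate sets from the greedy search, the post-hoc gating verdicts
#' (effect-size and permutation criteria per factor), the calibrated
#' thresholds and the configuration used, so a run is reproducible from its
#' metadata alone.
#'
#' @slot sets list of all candidate \linkS4class{DCXGeneSet}s (pre-gating).
#' @slot gated logical vector, TRUE for sets that pass gating (>= 1
#'   influential factor and minimum size).
#' @slot gating data.frame with one row per (set, factor): coefficient,
#'   p-value, effect-size pass, permutation fraction, final h.
#' @slot thresholds the calibrated \linkS4class{ThresholdSet}.
#' @slot effect the \linkS4class{EffectThresholds}, or NULL when
#'   permutation-only gating was used.
#' @slot config list echoing the run configuration (see
#'   \code{\link{dcoxConfig}}).
#' @export
setClass("DCoxResults",
  representation(sets = "list", gated = "logical", gating = "data.frame",
                 thresholds = "ThresholdSet", effect = "ANY", config = "list")
)
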