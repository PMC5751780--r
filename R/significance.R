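#' Effect-size thresholds from the pooled coefficient distribution
#'
#' Pools factor coefficients across all identified sets and estimates their
#' density (Gaussian kernel, Sheather-Jones bandwidth, 512-point grid
#' spanning 1.1 times the largest magnitude; Silverman's rule is used when
#' the Sheather-Jones solve fails, but its heavier smoothing can bridge
#' over genuine side modes in pools of a few dozen coefficients). Coefficients of factors
#' with little influence pile up in a central near-zero peak; genuinely
#' influential factors form side modes. The thresholds \eqn{T_{f+}} and
#' \eqn{T_{f-}} are placed at the first density valleys either side of the
#' central peak. When a side shows no mode beyond the centre the signed
#' 97.5th percentile of that side's values is used instead and the fallback
#' flag is set.
#'
#' @param pooled numeric vector of pooled factor coefficients (>= 20).
#' @param nGrid density grid size, default 512.
#' @return an \linkS4class{EffectThresholds}
#' @export
effectSizeThresholds <- function(pooled, nGrid = 512L) {
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) < 20L)
    stop("need at least 20 pooled coefficients for a density estimate; ",
         "with fewer sets use permutation-only gating")
  r <- 1.1 * max(abs(pooled))
  d <- tryCatch(density(pooled, bw = "SJ", n = nGrid, from = -r, to = r),
                error = function(e)
                  density(pooled, bw = "nrd0", n = nGrid, from = -r, to = r))
  y <- d$y
  ## local extrema from sign changes of the first difference
  dy <- diff(y)
  s <- sign(dy)
  turn <- which(s[-1L] != s[-length(s)] & s[-length(s)] != 0) + 1L
  maxima <- turn[y[turn] > y[turn - 1L] & y[turn] >= y[turn + 1L]]
  minima <- turn[y[turn] < y[turn - 1L] & y[turn] <= y[turn + 1L]]
  central <- maxima[which.min(abs(d$x[maxima]))]
  fallback <- c(neg = TRUE, pos = TRUE)

  tfPlus <- NA_real_
  rightModes <- maxima[maxima > central]
  if (length(rightModes)) {
    v <- minima[minima > central & minima < min(rightModes)]
    if (length(v)) {
      tfPlus <- d$x[v[1L]]
      fallback["pos"] <- FALSE
    }
  }
  if (is.na(tfPlus) || tfPlus <= 0) {
    pos <- pooled[pooled > 0]
    tfPlus <- if (length(pos)) quantile(pos, 0.975, names = FALSE)
              else max(abs(pooled))
    fallback["pos"] <- TRUE
  }

  tfMinus <- NA_real_
  leftModes <- maxima[maxima < central]
  if (length(leftModes)) {
    v <- minima[minima < central & minima > max(leftModes)]
    if (length(v)) {
      tfMinus <- d$x[v[length(v)]]
      fallback["neg"] <- FALSE
    }
  }
  if (is.na(tfMinus) || tfMinus >= 0) {
    neg <- pooled[pooled < 0]
    tfMinus <- if (length(neg)) quantile(neg, 0.025, names = FALSE)
               else -max(abs(pooled))
    fallback["neg"] <- TRUE
  }
  new("EffectThresholds", tfPlus = tfPlus, tfMinus = tfMinus,
      fallback = fallback, bandwidth = d$bw)
}

#' Permutation criterion for a factor's influence on a gene set
#'
#' Permutes the co-factor values across samples, rebuilds the strata and
#' within-stratum pairs, refits the model on the set's centroid statistic,
#' and counts permutations that beat the observed fit: coefficient beyond
#' the observed one in its direction AND p-value below
#' \code{min(observed p, 0.01)}. The factor is non-influential when at
#' least \code{cutoff} (default 0.01) of permutations beat it. By default
#' each factor column is permuted independently; \code{mode = "joint"}
#' applies one permutation to all columns, preserving each sample's factor
#' vector.
#'
#' @param dataset a \linkS4class{DCoxDataSet}.
#' @param genes gene ids or row indices of the set R.
#' @param factor factor name or index to test.
#' @param nPermutations number of permutations (default 1000; fewer than
#'   100 cannot resolve the 0.01 fraction and triggers a warning).
#' @param seed RNG seed.
#' @param cutoff non-influence fraction, default 0.01.
#' @param mode \code{"independent"} (default) or \code{"joint"} column
#'   permutation.
#' @return list with \code{factor}, \code{observed} (coefficient),
#'   \code{observedP}, \code{nBetter}, \code{permFraction} and
#'   \code{influential}
#' @export
permutationTest <- function(dataset, genes, factor, nPermutations = 1000L,
                            seed = 1L, cutoff = 0.01,
                            mode = c("independent", "joint")) {
  mode <- match.arg(mode)
  ft <- factorTable(dataset)
  if (is.character(factor)) factor <- match(factor, colnames(ft))
  ps <- .permuteSet(dataset, genes, nPermutations, seed, mode)
  frac <- ps$nBetter[factor] / nPermutations
  list(factor = colnames(ft)[factor], observed = ps$observed[factor],
       observedP = ps$observedP[factor], nBetter = ps$nBetter[factor],
       permFraction = frac, influential = frac < cutoff)
}

## One permutation pass for a gene set, scoring every factor at once:
## permuting the factor columns yields a refit whose coefficients and
## p-values are read off for all factors per permutation.
.permuteSet <- function(dataset, genes, nPermutations, seed, mode) {
  if (nPermutations < 100L)
    warning("fewer than 100 permutations cannot resolve a fraction of 0.01")
  ft <- factorTable(dataset)
  z <- ncol(ft)
  exprs <- exprValues(dataset)
  if (is.character(genes)) genes <- match(genes, rownames(exprs))
  cent <- colMeans(exprs[genes, , drop = FALSE])
  n <- nrow(ft)

  fitOne <- function(fm) {
    key <- fm[, 1L]
    if (z > 1L) for (k in 2:z) key <- paste(key, fm[, k])
    groups <- split(seq_len(n), key)
    pl <- lapply(groups, function(ix)
      if (length(ix) >= 2L) t(utils::combn(ix, 2L)))
    pairs <- do.call(rbind, pl)
    if (is.null(pairs) || nrow(pairs) <= z + 1L) return(NULL)
    A <- cent[pairs[, 1L]] - cent[pairs[, 2L]]
    A <- A * A
    X <- cbind(1, fm[pairs[, 1L], , drop = FALSE])
    M <- crossprod(X)
    Minv <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
    if (is.null(Minv)) return(NULL)
    co <- drop(Minv %*% crossprod(X, A))
    res <- A - drop(X %*% co)
    df <- nrow(X) - ncol(X)
    sigma2 <- sum(res * res) / df
    Fst <- co^2 / (sigma2 * diag(Minv))
    list(coef = co[-1L], p = pf(Fst[-1L], 1, df, lower.tail = FALSE))
  }

  obs <- fitOne(as.matrix(ft))
  if (is.null(obs)) stop("observed design cannot be fitted")
  dirn <- sign(obs$coef)
  pBar <- pmin(obs$p, 0.01)
  set.seed(seed)
  nBetter <- integer(z)
  for (b in seq_len(nPermutations)) {
    fm <- if (mode == "independent")
      vapply(seq_len(z), function(k) ft[sample.int(n), k], numeric(n))
    else ft[sample.int(n), , drop = FALSE]
    f <- fitOne(fm)
    if (is.null(f)) next
    nBetter <- nBetter +
      (dirn * (f$coef - obs$coef) > 0 & f$p < pBar)
  }
  list(observed = obs$coef, observedP = obs$p, nBetter = nBetter,
       factors = colnames(ft))
}

#' Gate candidate sets into reported DCX gene sets
#'
#' Applies the post-hoc significance criteria to the candidate sets of a
#' search: a factor is marked influential (h_i = +/-1, keeping the
#' coefficient's sign) only if its coefficient passes the effect-size
#' thresholds (> T_f+ or < T_f-) AND the permutation criterion. Sets with
#' no influential factor, or with fewer than \code{config$minSetSize}
#' genes, are dropped. When fewer than 20 coefficients are available to
#' pool, permutation-only gating is used and the effect thresholds slot is
#' NULL.
#'
#' @param searchResult the list returned by \code{\link{runSearch}}.
#' @param dataset the \linkS4class{DCoxDataSet} the search ran on.
#' @param config configuration list (\code{\link{dcoxConfig}}); uses
#'   \code{minSetSize}, \code{nPermutations}, \code{permCutoff},
#'   \code{permMode} and \code{seed}.
#' @return a \linkS4class{DCoxResults}
#' @export
gateSets <- function(searchResult, dataset, config = searchResult$config) {
  sets <- searchResult$sets
  fns <- factorNames(dataset)
  z <- length(fns)
  pooled <- unlist(lapply(sets, function(s) s@fit@coefficients))
  effect <- if (length(pooled) >= 20L) effectSizeThresholds(pooled) else NULL

  rows <- list()
  gated <- logical(length(sets))
  outSets <- sets
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    co <- s@fit@coefficients
    pv <- s@fit@pvalues
    effPass <- if (is.null(effect)) rep(TRUE, z) else
      (co > effect@tfPlus | co < effect@tfMinus)
    ## permutation is evaluated only where the effect-size criterion can
    ## still gate a factor in; one permutation pass scores all factors
    permFrac <- rep(NA_real_, z)
    permPass <- rep(FALSE, z)
    big <- length(s@genes) >= config$minSetSize
    if (big && any(effPass)) {
      ps <- .permuteSet(dataset, s@genes, config$nPermutations,
                        seed = config$seed + 11L * i,
                        mode = config$permMode)
      permFrac[effPass] <- ps$nBetter[effPass] / config$nPermutations
      permPass <- !is.na(permFrac) & permFrac < config$permCutoff
    }
    h <- ifelse(effPass & permPass, sign(co), 0L)
    outSets[[i]]@profile <- stats::setNames(as.integer(h), fns)
    gated[i] <- big && any(h != 0L)
    rows[[i]] <- data.frame(
      set = i, factor = fns, coefficient = unname(co), p.value = unname(pv),
      effectPass = unname(effPass), permFraction = permFrac,
      h = as.integer(h), row.names = NULL)
  }
  gating <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = integer(), factor = character(),
               coefficient = numeric(), p.value = numeric(),
               effectPass = logical(), permFraction = numeric(),
               h = integer())
  new("DCoxResults", sets = outSets, gated = gated, gating = gating,
      thresholds = searchResult$thresholds, effect = effect,
      config = config)
}

## ---- accessors ----------------------------------------------------------

#' @rdname DCXGeneSet-accessors
#' @export
setMethod("geneIds", "DCXGeneSet", function(x) x@genes)

#' @rdname DCXGeneSet-accessors
#' @export
setMethod("dcxProfile", "DCXGeneSet", function(x) x@profile)

#' @rdname DCXGeneSet-accessors
#' @export
setMethod("pvalues", "DCXGeneSet", function(x) x@fit@pvalues)

setMethod("show", "DCXGeneSet", function(object) {
  cat("DCXGeneSet of", length(object@genes), "genes; profile:",
      paste(names(object@profile), object@profile, sep = "=",
            collapse = " "), "\n")
})

#' @rdname DCoxResults-accessors
#' @export
setMethod("dcxSets", "DCoxResults", function(x) x@sets[x@gated])

#' @rdname DCoxResults-accessors
#' @export
setMethod("candidateSets", "DCoxResults", function(x) x@sets)

#' @rdname DCoxResults-accessors
#' @export
setMethod("gatingTable", "DCoxResults", function(x) x@gating)

#' @rdname DCoxResults-accessors
#' @export
setMethod("thresholds", "DCoxResults", function(x) x@thresholds)

setMethod("show", "DCoxResults", function(object) {
  cat("DCoxResults:", length(object@sets), "candidate sets,",
      sum(object@gated), "reported after gating\n")
  if (!is.null(object@effect))
    cat("effect thresholds: [", signif(object@effect@tfMinus, 4), ",",
        signif(object@effect@tfPlus, 4), "]\n")
  cat("CT =", signif(object@thresholds@CT, 4), "\n")
})
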