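#' Run configuration with documented defaults
#'
#' Collects every tunable of the pipeline. All randomness in a run flows
#' from \code{seed}, so a configuration fully reproduces a run.
#'
#' \describe{
#'   \item{m}{order-statistic index of the C_T calibration (default 10).}
#'   \item{nRandomPairs}{random gene pairs pooled for C_T (default 10000;
#'     large enough for a stable 10th order statistic, cheap with batch
#'     fitting).}
#'   \item{alpha}{augmentation-threshold interpolation weight in [0, 1]
#'     (default 0.5, midway between the conservative and permissive
#'     extremes).}
#'   \item{minSetSize}{minimum reported set size (default 6).}
#'   \item{maxPairs}{cap on within-stratum sample pairs; Inf keeps all.}
#'   \item{splitHalf}{scan only cross-half gene pairs for seeds
#'     (default TRUE).}
#'   \item{seedPCut}{per-factor p-value cutoff for seeds and profiles
#'     (default 0.01).}
#'   \item{minVarianceQuantile}{variance-filter quantile applied before the
#'     search (default 0.5: drop the least-variable half, the share of
#'     undetected probes a typical array carries).}
#'   \item{readmitDropped}{genes without a significant partner are excluded
#'     from expansion but re-admitted as augmentation candidates
#'     (default TRUE); augmentation exists to recover weak true
#'     positives.}
#'   \item{maxSetsPerDirection}{seed runs per factor and direction
#'     (default 25). Seeds are processed in decreasing coefficient order,
#'     so genuine sets are reached first; the cap bounds the long tail of
#'     weak seeds, whose sets rarely survive gating.}
#'   \item{nPermutations}{permutations per gating test (default 1000).}
#'   \item{permCutoff}{non-influence fraction (default 0.01).}
#'   \item{permMode}{"independent" (each factor column permuted on its
#'     own; default) or "joint".}
#'   \item{matchThreshold}{Jaccard fraction for benchmark scoring
#'     (default 0.5).}
#'   \item{seed}{master RNG seed (default 1).}
#' }
#'
#' @param ... overrides of the defaults above.
#' @return named list of configuration values
#' @export
dcoxConfig <- function(...) {
  cfg <- list(
    m = 10L, nRandomPairs = 10000L, alpha = 0.5, minSetSize = 6L,
    maxPairs = Inf, splitHalf = TRUE, seedPCut = 0.01,
    minVarianceQuantile = 0.5, readmitDropped = TRUE,
    maxSetsPerDirection = 25L, nPermutations = 1000L, permCutoff = 0.01,
    permMode = "independent", matchThreshold = 0.5, seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load a configuration from a YAML file
#'
#' @param path YAML file of configuration keys (see
#'   \code{\link{dcoxConfig}}).
#' @return configuration list with defaults filled in
#' @export
readConfig <- function(path) {
  dcoxConfig(yaml::read_yaml(path))
}

#' Run the complete differential co-expression pipeline
#'
#' Convenience wrapper: search plus gating, returning a
#' \linkS4class{DCoxResults}.
#'
#' @param dataset a \linkS4class{DCoxDataSet}.
#' @param config configuration list (\code{\link{dcoxConfig}}).
#' @param verbose print per-stage progress.
#' @return a \linkS4class{DCoxResults}
#' @export
runMultiDCoX <- function(dataset, config = dcoxConfig(), verbose = FALSE) {
  gateSets(runSearch(dataset, config, verbose = verbose), dataset, config)
}

## ---- writers / readers --------------------------------------------------

#' Write results to a directory
#'
#' Produces \code{sets.tsv} (one row per reported set: id, genes, per
#' factor coefficient, p-value and h, plus provenance) and
#' \code{metadata.json} (thresholds, configuration echo and gating table)
#' at full double precision; \code{\link{readResults}} round-trips them.
#'
#' @param results a \linkS4class{DCoxResults}.
#' @param dir output directory (created if needed).
#' @param all write all candidate sets instead of only the gated ones.
#' @return invisibly, the paths written
#' @export
writeResults <- function(results, dir, all = FALSE) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  sel <- if (all) seq_along(results@sets) else which(results@gated)
  tab <- do.call(rbind, lapply(sel, function(i) {
    s <- results@sets[[i]]
    co <- s@fit@coefficients
    row <- data.frame(set = i, nGenes = length(s@genes),
                      genes = paste(s@genes, collapse = ";"),
                      stringsAsFactors = FALSE)
    for (f in names(co)) {
      row[[paste0("coef.", f)]] <- sprintf("%.17g", co[[f]])
      row[[paste0("p.", f)]] <- sprintf("%.17g", s@fit@pvalues[[f]])
      row[[paste0("h.", f)]] <- s@profile[[f]]
    }
    row$seed <- paste(s@provenance$seed, collapse = ";")
    row$targetFactor <- s@provenance$factor
    row$direction <- s@provenance$direction
    row$sizeJ <- s@provenance$sizes[["J"]]
    row$sizeL <- s@provenance$sizes[["L"]]
    row
  }))
  setsPath <- file.path(dir, "sets.tsv")
  if (is.null(tab))
    tab <- data.frame(set = integer(), nGenes = integer(),
                      genes = character())
  utils::write.table(tab, setsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    CT = results@thresholds@CT, m = results@thresholds@m,
    nRandomPairs = results@thresholds@nRandomPairs,
    calibrationSeed = results@thresholds@seed,
    interceptIncluded = TRUE,
    effect = if (is.null(results@effect)) NULL else list(
      tfPlus = results@effect@tfPlus, tfMinus = results@effect@tfMinus,
      fallback = as.list(results@effect@fallback),
      bandwidth = results@effect@bandwidth),
    config = results@config,
    gating = results@gating,
    gated = results@gated)
  metaPath <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(c(sets = setsPath, metadata = metaPath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read back written results
#'
#' @param dir directory written by \code{\link{writeResults}}.
#' @return list with \code{sets} (data.frame with numeric coefficients and
#'   gene-id lists) and \code{metadata}
#' @export
readResults <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "sets.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (cn in colnames(tab))
    if (grepl("^(coef|p)\\.", cn)) tab[[cn]] <- as.numeric(tab[[cn]])
    else if (cn %in% c("set", "nGenes", "direction", "sizeJ", "sizeL") ||
             grepl("^h\\.", cn)) tab[[cn]] <- as.integer(tab[[cn]])
  tab$geneList <- strsplit(tab$genes, ";", fixed = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  list(sets = tab, metadata = meta)
}
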