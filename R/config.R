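#' Create a synthetic-community configuration
#'
#' Defaults describe the emulated study design: 4 broiler trials, 12 cecal
#' samples per diet group per trial at day 35, 500 OTUs, 10 planted
#' diet-sensitive OTUs at 4-fold change (5 increased, 5 decreased in the
#' treatment group), log-normal baseline abundances (sdlog 1.5, heavy
#' tailed), 5% zero inflation, library sizes 2000-5000 reads, and a small
#' per-trial log-abundance offset (sd 0.2) emulating inter-trial variation.
#'
#' @param nTrials,nPerGroup,nOtus,nSensitive Study-design counts.
#' @param effectSizes Per-sensitive-OTU multiplicative fold change (> 0,
#'   != 1) applied on the composition scale in the treatment group.
#' @param baseLogMean,baseLogSd Log-normal baseline parameters.
#' @param zeroInflation Per-entry probability of a forced zero.
#' @param librarySizeRange `c(min, max)` reads per sample.
#' @param trialSd SD of the per-trial log offset.
#' @param seed Master seed; see [deriveSeeds()].
#' @return A validated [SimulationConfig-class].
#' @export
#' @examples
#' simulationConfig(nOtus = 50L, nSensitive = 2L, effectSizes = c(4, 0.25))
simulationConfig <- function(nTrials = 4L, nPerGroup = 12L, nOtus = 500L,
                             nSensitive = 10L,
                             effectSizes = rep(c(4, 0.25),
                                               each = ceiling(nSensitive / 2))[
                                               seq_len(nSensitive)],
                             baseLogMean = 0, baseLogSd = 1.5,
                             zeroInflation = 0.05,
                             librarySizeRange = c(2000L, 5000L),
                             trialSd = 0.2, seed = 1L) {
  new("SimulationConfig",
      nTrials = as.integer(nTrials), nPerGroup = as.integer(nPerGroup),
      nOtus = as.integer(nOtus), nSensitive = as.integer(nSensitive),
      effectSizes = as.numeric(effectSizes),
      baseLogMean = as.numeric(baseLogMean),
      baseLogSd = as.numeric(baseLogSd),
      zeroInflation = as.numeric(zeroInflation),
      librarySizeRange = as.integer(librarySizeRange),
      trialSd = as.numeric(trialSd), seed = as.integer(seed))
}

#' Create a shadow-forest configuration
#'
#' @param nRepetitions Forest refits with fresh shadow permutations.
#' @param nTrees Trees per forest.
#' @param vimMetric `"permutation"` (OOB permutation-accuracy decrease) or
#'   `"impurity"`.
#' @param likelihoodThreshold Selection threshold in percent; 100 means
#'   "rounds to 100", i.e. one-sided p <= 0.005.
#' @param importanceThreshold Minimum mean importance for selection.
#' @param useRelativeAbundance Feed compositions rather than raw counts.
#' @param seed Master seed.
#' @return A validated [ErfConfig-class].
#' @export
#' @examples
#' erfConfig(nRepetitions = 20L, nTrees = 200L)
erfConfig <- function(nRepetitions = 50L, nTrees = 500L,
                      vimMetric = c("permutation", "impurity"),
                      likelihoodThreshold = 100,
                      importanceThreshold = 0.001,
                      useRelativeAbundance = TRUE, seed = 1L) {
  new("ErfConfig",
      nRepetitions = as.integer(nRepetitions), nTrees = as.integer(nTrees),
      vimMetric = match.arg(vimMetric),
      likelihoodThreshold = as.numeric(likelihoodThreshold),
      importanceThreshold = as.numeric(importanceThreshold),
      useRelativeAbundance = isTRUE(useRelativeAbundance),
      seed = as.integer(seed))
}

#' @export
#' @describeIn ErfResult-class Compact display.
setMethod("show", "ErfResult", function(object) {
  res <- object@results
  nsel <- sum(res$selected)
  cat(sprintf("ErfResult: %d OTUs scored over %d repetitions x %d trees\n",
              nrow(res), object@config@nRepetitions, object@config@nTrees))
  cat(sprintf("  selected: %d (%d increased, %d decreased)\n", nsel,
              sum(res$selected & res$direction == "increased"),
              sum(res$selected & res$direction == "decreased")))
  cat(sprintf("  top shadow reference: %s (mean VIM %.2g)\n",
              object@topShadow,
              mean(object@vims[object@topShadow, ])))
  invisible(NULL)
})

#' @export
#' @describeIn PermanovaResult-class Compact display.
setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g, p = %.4g (%d permutations)\n",
    object@pseudoF, object@pValue, object@nPermutations))
  invisible(NULL)
})

#' @export
#' @describeIn OrdinationResult-class Compact display.
setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("PCoA: %d samples, %d axes (%s%% explained)\n",
              nrow(object@coordinates), ncol(object@coordinates),
              paste(sprintf("%.1f", 100 * object@explainedVariance),
                    collapse = ", ")))
  invisible(NULL)
})

#' Extractors for ErfResult
#'
#' `relevanceTable()` returns the per-OTU results `DataFrame`;
#' `selectedOtus()` the ids passing both selection gates; `vimMatrix()` the
#' raw (real + shadow) x repetition importance matrix.
#'
#' @param x An [ErfResult-class].
#' @aliases relevanceTable selectedOtus vimMatrix
#' @name relevanceTable
NULL

#' @rdname relevanceTable
#' @export
setMethod("relevanceTable", "ErfResult", function(x) x@results)

#' @rdname relevanceTable
#' @export
setMethod("selectedOtus", "ErfResult",
          function(x) x@results$otu_id[x@results$selected])

#' @rdname relevanceTable
#' @export
setMethod("vimMatrix", "ErfResult", function(x) x@vims)
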