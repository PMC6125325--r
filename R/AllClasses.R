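#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assays colData colData<- rowData rowData<-
NULL

#' OtuExperiment: an OTU count table with sample metadata and taxonomy
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' `counts` assay holding nonnegative integer abundances, OTUs as rows and
#' samples as columns. Sample metadata (`trial`, `day`, `group`) lives in
#' `colData()`, the taxonomic lineage (`phylum` ... `genus`,
#' `nearest_species`) in `rowData()`. On-disk TSVs use the transposed
#' samples-as-rows layout common for OTU tables; [readCountTable()] and
#' [writeCountTable()] convert.
#'
#' @seealso [OtuExperiment()] the constructor, [otuCounts()], [rarefy()],
#'   [aggregateByRank()], [erfRelevance()]
#' @export
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  m <- assay(object, "counts")
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m)))
    return("counts must be nonnegative NA-free integers")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("OTU ids (rownames) and sample ids (colnames) are required")
  if (anyDuplicated(rownames(object)))
    return("duplicate OTU ids")
  if (anyDuplicated(colnames(object)))
    return("duplicate sample ids")
  cd <- colData(object)
  if ("group" %in% names(cd)) {
    g <- unique(as.character(cd$group))
    if (length(setdiff(g, c("control", "treatment"))) > 0)
      return("group must be 'control' or 'treatment'")
  }
  TRUE
})

#' Configuration for the synthetic community generator
#'
#' Holds the study-design and distributional parameters for
#' [simulateCommunity()]. Defaults mirror a multi-trial broiler-cecum
#' feeding-trial design: 4 trials, 12 samples per group per trial, 500 OTUs
#' with heavy-tailed log-normal baseline abundances, 10 planted
#' treatment-sensitive OTUs at 4-fold change (5 up, 5 down), per-entry zero
#' inflation and variable library sizes.
#'
#' @slot nTrials Number of independent trials.
#' @slot nPerGroup Samples per group per trial.
#' @slot nOtus Number of OTUs.
#' @slot nSensitive Number of planted treatment-sensitive OTUs.
#' @slot effectSizes Multiplicative fold change (> 0, != 1) applied to each
#'   sensitive OTU's relative abundance in the treatment group.
#' @slot baseLogMean,baseLogSd Log-normal baseline abundance parameters.
#' @slot zeroInflation Probability an individual count is forced to zero
#'   (applied to the sample's composition before resampling, so library
#'   sizes are preserved).
#' @slot librarySizeRange Integer min/max reads per sample.
#' @slot trialSd SD of the per-trial log-abundance offset emulating
#'   inter-trial variation.
#' @slot seed Master RNG seed.
#' @seealso [simulationConfig()], [simulateCommunity()]
#' @export
setClass("SimulationConfig",
  representation(
    nTrials = "integer", nPerGroup = "integer", nOtus = "integer",
    nSensitive = "integer", effectSizes = "numeric",
    baseLogMean = "numeric", baseLogSd = "numeric",
    zeroInflation = "numeric", librarySizeRange = "integer",
    trialSd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  chk <- function(cond, msg) if (!cond) msg else NULL
  msgs <- c(
    chk(object@nTrials >= 1L, "nTrials must be >= 1"),
    chk(object@nPerGroup >= 1L, "nPerGroup must be >= 1"),
    chk(object@nOtus >= 1L, "nOtus must be >= 1"),
    chk(object@nSensitive >= 0L && object@nSensitive <= object@nOtus,
        "nSensitive must be in [0, nOtus]"),
    chk(length(object@effectSizes) == object@nSensitive,
        "effectSizes must have length nSensitive"),
    chk(all(object@effectSizes > 0) && !any(object@effectSizes == 1),
        "effectSizes must be > 0 and != 1"),
    chk(object@baseLogSd >= 0, "baseLogSd must be >= 0"),
    chk(object@zeroInflation >= 0 && object@zeroInflation <= 1,
        "zeroInflation must be a probability in [0, 1]"),
    chk(length(object@librarySizeRange) == 2L &&
          object@librarySizeRange[1] >= 1L &&
          object@librarySizeRange[2] >= object@librarySizeRange[1],
        "librarySizeRange must be c(min, max) with 1 <= min <= max"),
    chk(object@trialSd >= 0, "trialSd must be >= 0"),
    chk(length(object@seed) == 1L, "seed must be a single integer"))
  if (length(msgs)) msgs else TRUE
})

#' Configuration for shadow-forest relevance scoring
#'
#' @slot nRepetitions Forest refits, each with fresh shadow permutations
#'   (>= 2; the Welch test needs at least two importance values per side).
#' @slot nTrees Trees per forest.
#' @slot vimMetric `"permutation"` (out-of-bag permutation accuracy
#'   decrease, the default) or `"impurity"` (Gini).
#' @slot likelihoodThreshold Selection threshold on the relevance
#'   likelihood, in percent. The default 100 means "likelihood that rounds
#'   to 100 at integer precision", i.e. one-sided p <= 0.005.
#' @slot importanceThreshold Minimum mean importance for selection; on the
#'   permutation metric this is an absolute accuracy fraction (default
#'   0.001).
#' @slot useRelativeAbundance Feed per-sample relative abundances to the
#'   forest (default) rather than raw counts, since library size is a
#'   nuisance variable.
#' @slot seed Master seed split into per-repetition shadow and forest
#'   streams.
#' @seealso [erfConfig()], [erfRelevance()]
#' @export
setClass("ErfConfig",
  representation(
    nRepetitions = "integer", nTrees = "integer", vimMetric = "character",
    likelihoodThreshold = "numeric", importanceThreshold = "numeric",
    useRelativeAbundance = "logical", seed = "integer"))

setValidity("ErfConfig", function(object) {
  chk <- function(cond, msg) if (!cond) msg else NULL
  msgs <- c(
    chk(object@nRepetitions >= 2L, "nRepetitions must be >= 2"),
    chk(object@nTrees >= 1L, "nTrees must be >= 1"),
    chk(object@vimMetric %in% c("permutation", "impurity"),
        "vimMetric must be 'permutation' or 'impurity'"),
    chk(object@likelihoodThreshold >= 0,
        "likelihoodThreshold must be >= 0"),
    chk(object@importanceThreshold >= 0,
        "importanceThreshold must be >= 0"))
  if (length(msgs)) msgs else TRUE
})

#' Result of shadow-forest relevance scoring
#'
#' @slot results `DataFrame` with one row per OTU, sorted by decreasing
#'   mean importance (ties broken by OTU id): `otu_id`, `mean_vim`,
#'   `p_value`, `likelihood_pct`, `selected`, `direction`, `fold_change`.
#' @slot vims Importance matrix, (real + shadow features) x repetitions.
#' @slot topShadow Id of the shadow feature with the highest mean
#'   importance, the null reference of the Welch tests.
#' @slot config The [ErfConfig-class] used.
#' @seealso [erfRelevance()], [selectedOtus()], [relevanceTable()]
#' @export
setClass("ErfResult",
  representation(results = "DataFrame", vims = "matrix",
                 topShadow = "character", config = "ErfConfig"))

#' Principal-coordinates ordination of a distance matrix
#'
#' @slot coordinates Samples x k coordinate matrix; axes ordered by
#'   decreasing explained variance.
#' @slot eigenvalues All eigenvalues of the double-centred Gower matrix,
#'   including any negative ones (whose axes are discarded).
#' @slot explainedVariance Fraction of the positive-eigenvalue total
#'   captured by each returned axis.
#' @seealso [pcoa()]
#' @export
setClass("OrdinationResult",
  representation(coordinates = "matrix", eigenvalues = "numeric",
                 explainedVariance = "numeric"))

#' One-factor PERMANOVA result
#'
#' @slot pseudoF Observed pseudo-F statistic.
#' @slot pValue Permutation p-value, add-one convention:
#'   `(1 + #\{F_perm >= F_obs\}) / (1 + nPermutations)`.
#' @slot nPermutations Number of label permutations.
#' @slot ssTotal,ssWithin,ssBetween Squared-distance partition.
#' @seealso [permanova()]
#' @export
setClass("PermanovaResult",
  representation(pseudoF = "numeric", pValue = "numeric",
                 nPermutations = "integer", ssTotal = "numeric",
                 ssWithin = "numeric", ssBetween = "numeric"))
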