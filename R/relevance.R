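#' One-sided Welch two-sample t-test p-value
#'
#' Tests `H1: mean(x) > mean(y)` with unequal variances
#' (Welch-Satterthwaite degrees of freedom). Degenerate zero-variance
#' inputs follow the limiting convention: if both samples are constant the
#' p-value is 0 when `mean(x) > mean(y)`, 1 when smaller and 0.5 when
#' equal.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @return The one-sided p-value.
#' @export
welchOneSidedP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    badInput("both samples need >= 2 observations")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0)
    return(if (m1 > m2) 0 else if (m1 < m2) 1 else 0.5)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  pt(tstat, df, lower.tail = FALSE)
}

#' Relevance likelihood of real features against the strongest shadow
#'
#' The null reference is the *shadow envelope*: in each repetition the
#' highest importance reached by any shadow feature. Because every
#' repetition regenerates all shadow permutations, the envelope's values
#' are independent draws of "the best score pure noise can achieve on this
#' dataset", and judging every real feature against it makes the gate a
#' family-wise control device — no further multiplicity correction is
#' applied. Each real feature's per-repetition importances are compared to
#' the envelope with a one-sided Welch t-test; the relevance likelihood is
#' `100 x (1 - p)`, near 100 when the feature reliably beats everything
#' the null produced.
#'
#' (Comparing instead against the per-repetition values of the single
#' shadow with the highest *mean* importance gives no such control: fresh
#' permutations shrink every individual shadow's mean towards zero while a
#' real feature keeps its fixed chance association with the labels, so
#' under a pure null the best real features test significant against that
#' weaker reference at almost any level.)
#'
#' @param vims Importance matrix from [stabilityVims()] (rows: real
#'   features then `shadow__`-prefixed shadows; >= 2 columns).
#' @return `DataFrame` with `otu_id`, `mean_vim`, `p_value`,
#'   `likelihood_pct`; `metadata()` carries `reference` (the envelope
#'   values) and `topShadow` (the shadow with the highest mean
#'   importance, for display).
#' @export
relevanceLikelihood <- function(vims) {
  if (ncol(vims) < 2L)
    badInput("vims needs >= 2 repetitions")
  shadow <- grepl(paste0("^", SHADOW_PREFIX), rownames(vims))
  if (!any(shadow))
    badInput("vims contains no shadow rows")
  shadowBlock <- vims[shadow, , drop = FALSE]
  ref <- apply(shadowBlock, 2L, max)
  topShadow <- rownames(shadowBlock)[which.max(rowMeans(shadowBlock))]
  real <- rownames(vims)[!shadow]
  p <- vapply(real, function(f) welchOneSidedP(vims[f, ], ref), numeric(1))
  out <- S4Vectors::DataFrame(
    otu_id = real,
    mean_vim = rowMeans(vims[real, , drop = FALSE]),
    p_value = unname(p),
    likelihood_pct = unname(100 * (1 - p)),
    row.names = real)
  S4Vectors::metadata(out)$reference <- ref
  S4Vectors::metadata(out)$topShadow <- topShadow
  out
}

#' Apply the two selection gates
#'
#' A feature is selected when its relevance likelihood reaches
#' `likelihoodThreshold` *and* its mean importance reaches
#' `importanceThreshold`. A threshold of 100 is read as "likelihood that
#' rounds to 100 at integer reporting precision", i.e. one-sided
#' p <= 0.005; any lower threshold is compared directly. Output is sorted
#' by mean importance, descending, ties broken by OTU id.
#'
#' @param results `DataFrame` from [relevanceLikelihood()].
#' @param config An [ErfConfig-class] carrying the thresholds.
#' @return `results` with a logical `selected` column, sorted.
#' @export
selectRelevant <- function(results, config = erfConfig()) {
  thr <- config@likelihoodThreshold
  likGate <- if (thr >= 100) results$likelihood_pct >= 99.5
             else results$likelihood_pct >= thr
  results$selected <- likGate &
    results$mean_vim >= config@importanceThreshold
  ord <- order(-results$mean_vim, results$otu_id)
  results[ord, ]
}

#' Direction and magnitude of the treatment effect per OTU
#'
#' Compares mean relative abundance between groups. The fold change is
#' `(mean_treatment + eps) / (mean_control + eps)` with `eps` half the
#' smallest nonzero relative abundance in the table, so OTUs absent from
#' one group still get a finite ratio. Direction is `increased` when the
#' fold change exceeds 1, `decreased` below 1, and `unchanged` at exactly
#' 1 (tied means; excluded from either count in summaries).
#'
#' @param x An [OtuExperiment-class] with a binary `group` in `colData`.
#' @param otuIds OTUs to annotate (default: all).
#' @return `DataFrame` with `otu_id`, `control_mean`, `treatment_mean`,
#'   `fold_change`, `direction`.
#' @export
directionOfChange <- function(x, otuIds = NULL) {
  g <- groupFactor(x)
  rel <- relativeAbundance(x)
  if (is.null(otuIds)) otuIds <- rownames(rel)
  missing <- setdiff(otuIds, rownames(rel))
  if (length(missing))
    badInput("OTU(s) absent from table: %s",
             paste(head(missing, 10), collapse = ", "))
  eps <- min(rel[rel > 0]) / 2
  mC <- rowMeans(rel[otuIds, g == "control", drop = FALSE])
  mT <- rowMeans(rel[otuIds, g == "treatment", drop = FALSE])
  fc <- (mT + eps) / (mC + eps)
  S4Vectors::DataFrame(
    otu_id = otuIds,
    control_mean = unname(mC),
    treatment_mean = unname(mT),
    fold_change = unname(fc),
    direction = unname(ifelse(fc > 1, "increased",
                              ifelse(fc < 1, "decreased", "unchanged"))),
    row.names = otuIds)
}

#' Shadow-forest relevance scoring of OTUs
#'
#' The package's core routine. Per-sample relative abundances (or raw
#' counts, see [erfConfig()]) and the binary group label feed
#' [stabilityVims()]; [relevanceLikelihood()] scores every OTU against the
#' strongest shadow; [selectRelevant()] applies the likelihood and
#' importance gates; and [directionOfChange()] annotates each OTU with the
#' direction and magnitude of its abundance shift.
#'
#' @param x An [OtuExperiment-class] with a binary `group` column.
#' @param config An [ErfConfig-class].
#' @return An [ErfResult-class]; see [relevanceTable()] and
#'   [selectedOtus()].
#' @export
#' @examples
#' \donttest{
#' sim <- simulateCommunity(simulationConfig(nTrials = 1L, nOtus = 30L,
#'   nSensitive = 2L, effectSizes = c(8, 0.125), seed = 5L))
#' res <- erfRelevance(sim$experiment,
#'                     erfConfig(nRepetitions = 5L, nTrees = 100L))
#' res
#' }
erfRelevance <- function(x, config = erfConfig()) {
  validObject(config)
  g <- groupFactor(x)
  X <- t(if (config@useRelativeAbundance) relativeAbundance(x)
         else otuCounts(x))
  vims <- stabilityVims(X, g, config)
  res <- relevanceLikelihood(vims)
  topShadow <- S4Vectors::metadata(res)$topShadow
  res <- selectRelevant(res, config)
  dir <- directionOfChange(x, otuIds = res$otu_id)
  res$direction <- dir[res$otu_id, "direction"]
  res$fold_change <- dir[res$otu_id, "fold_change"]
  new("ErfResult", results = res, vims = vims,
      topShadow = topShadow, config = config)
}
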