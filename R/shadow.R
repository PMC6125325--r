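SHADOW_PREFIX <- "shadow__"

#' Augment a feature matrix with shadow features
#'
#' For every original feature a shadow copy is made by independently
#' permuting its values across samples, destroying any association with
#' the class label while preserving the marginal distribution. The
#' shadows' importances form an empirical null against which real
#' features are judged.
#'
#' @param X Samples x features numeric matrix (>= 2 rows), columns named.
#' @param seed RNG seed; one permutation stream per column.
#' @return Samples x (2 x features) matrix: the originals followed by
#'   their shadows, named `shadow__<feature>`.
#' @export
#' @examples
#' X <- matrix(1:6, 3, dimnames = list(NULL, c("f1", "f2")))
#' makeShadowFeatures(X, seed = 1)
makeShadowFeatures <- function(X, seed = 1L) {
  if (!is.matrix(X) || nrow(X) < 2L || ncol(X) < 1L)
    badInput("X must be a matrix with >= 2 samples and >= 1 feature")
  if (is.null(colnames(X)))
    badInput("X columns must be named")
  shadows <- withSeed(seed, apply(X, 2L, sample))
  colnames(shadows) <- paste0(SHADOW_PREFIX, colnames(X))
  cbind(X, shadows)
}

#' Random-forest variable importance over real and shadow features
#'
#' Fits one classification forest on the shadow-augmented matrix and
#' returns an importance value per column. With the default
#' `vimMetric = "permutation"` this is the mean over trees of the
#' out-of-bag accuracy minus the accuracy after permuting the feature
#' among the OOB samples (an absolute accuracy fraction); the forest is
#' [ranger::ranger()] restricted to one thread for reproducibility.
#'
#' @param Xaug Samples x (2 x features) matrix from
#'   [makeShadowFeatures()] (an even column count is required).
#' @param y Binary class labels, both classes present.
#' @param nTrees Trees in the forest.
#' @param vimMetric `"permutation"` or `"impurity"`.
#' @param seed Forest seed.
#' @return Named numeric vector, one importance per column of `Xaug`.
#' @export
fitForestVim <- function(Xaug, y, nTrees = 500L,
                         vimMetric = c("permutation", "impurity"),
                         seed = 1L) {
  vimMetric <- match.arg(vimMetric)
  if (ncol(Xaug) %% 2L != 0L)
    badInput("Xaug must contain real features plus their shadows")
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    badInput("y must contain both classes")
  fit <- ranger::ranger(
    x = as.data.frame(Xaug, check.names = FALSE), y = y,
    num.trees = as.integer(nTrees),
    importance = vimMetric, classification = TRUE,
    seed = as.integer(seed), num.threads = 1L,
    respect.unordered.factors = "order")
  fit$variable.importance[colnames(Xaug)]
}

#' Importance stability across repeated forest fits
#'
#' The shadow-forest relevance statistic needs a distribution of
#' importances, not a single fit: each repetition regenerates every shadow
#' permutation from a fresh sub-seed and refits the forest, giving each
#' real and shadow feature `nRepetitions` importance values. Fresh shadows
#' per repetition are what make the top-shadow importance a proper null
#' draw rather than a fixed quirk of one permutation.
#'
#' @param X Samples x features matrix of real features.
#' @param y Binary class labels.
#' @param config An [ErfConfig-class]; `config@seed` is split into one
#'   (shadow, forest) seed pair per repetition via [deriveSeeds()].
#' @return Matrix (2 x features) x `nRepetitions`; rows are the real
#'   features followed by their shadows, columns `rep_1` ... .
#' @export
stabilityVims <- function(X, y, config = erfConfig()) {
  validObject(config)
  R <- config@nRepetitions
  seeds <- deriveSeeds(config@seed, 2L * R)
  vims <- matrix(NA_real_, nrow = 2L * ncol(X), ncol = R,
                 dimnames = list(c(colnames(X),
                                   paste0(SHADOW_PREFIX, colnames(X))),
                                 sprintf("rep_%d", seq_len(R))))
  for (r in seq_len(R)) {
    Xaug <- makeShadowFeatures(X, seed = seeds[2L * r - 1L])
    vims[, r] <- fitForestVim(Xaug, y, nTrees = config@nTrees,
                              vimMetric = config@vimMetric,
                              seed = seeds[2L * r])
  }
  vims
}
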