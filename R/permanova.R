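#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions the squared pairwise distances into between- and
#' within-group components:
#' `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_between = SS_total - SS_within`, and
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))` with `a` groups.
#' Significance is assessed by freely permuting the group labels;
#' the p-value uses the add-one convention
#' `(1 + #\{F_perm >= F_obs\}) / (1 + nPerm)`, so it is never zero.
#'
#' @param dm `dist` or symmetric distance matrix.
#' @param labels Group label per sample (two or more groups, each
#'   represented at least once).
#' @param nPerm Number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return A [PermanovaResult-class].
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(10), 5), matrix(rnorm(10, 4), 5))
#' permanova(dist(pts), rep(c("a", "b"), each = 5), nPerm = 199, seed = 1)
permanova <- function(dm, labels, nPerm = 999L, seed = 1L) {
  D2 <- as.matrix(dm)^2
  n <- nrow(D2)
  labels <- as.character(labels)
  if (length(labels) != n)
    badInput("labels length (%d) must match samples (%d)",
             length(labels), n)
  if (length(unique(labels)) < 2L)
    badInput("labels must contain at least two groups")
  if (nPerm < 99L)
    badInput("nPerm must be >= 99")

  fStat <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      idx <- lab == g
      ssw <- ssw + sum(D2[idx, idx]) / (2 * sum(idx))
    }
    sst <- sum(D2) / (2 * n)
    a <- length(unique(lab))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }

  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    ssw <- ssw + sum(D2[idx, idx]) / (2 * sum(idx))
  }
  fObs <- fStat(labels)
  fPerm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
    fStat(sample(labels)), numeric(1)))
  new("PermanovaResult",
      pseudoF = fObs,
      pValue = (1 + sum(fPerm >= fObs)) / (1 + nPerm),
      nPermutations = as.integer(nPerm),
      ssTotal = sst, ssWithin = ssw, ssBetween = sst - ssw)
}
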