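#' Principal-coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centred
#' (Gower) and eigendecomposed; axes with positive eigenvalues give
#' coordinates whose Euclidean distances reproduce the input exactly when
#' it is Euclidean-embeddable. Negative eigenvalues are retained in the
#' result for inspection but their axes are discarded; `k` is truncated
#' (with a warning) when fewer positive axes exist.
#'
#' @param dm A `dist` or symmetric distance matrix.
#' @param k Number of axes requested (>= 1).
#' @return An [OrdinationResult-class].
#' @export
#' @examples
#' pts <- matrix(rnorm(20), 10, 2)
#' ord <- pcoa(dist(pts), k = 2)
#' ord
pcoa <- function(dm, k = 2L) {
  if (length(k) != 1L || is.na(k) || k < 1)
    badInput("k must be a single integer >= 1")
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  fit <- withCallingHandlers(
    stats::cmdscale(d, k = min(k, n - 1L), eig = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  kEff <- min(k, pos)
  if (kEff < k)
    warning(sprintf("only %d positive axes available; k truncated", kEff),
            call. = FALSE)
  coords <- fit$points[, seq_len(kEff), drop = FALSE]
  colnames(coords) <- sprintf("Axis%d", seq_len(kEff))
  new("OrdinationResult",
      coordinates = coords,
      eigenvalues = eig,
      explainedVariance = eig[seq_len(kEff)] / sum(eig[eig > 0]))
}
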