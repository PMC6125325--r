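# Shared fixtures and independent oracles for the suite. Oracles are coded
# against the definitions directly (explicit descendant sets, closed-form
# statistics) and never share code paths with the implementations they check.

randomCountMatrix <- function(nOtus, nSamples, seed, lambdaMax = 50) {
  set.seed(seed)
  lam <- runif(nOtus, 0.5, lambdaMax)
  m <- matrix(rpois(nOtus * nSamples, rep(lam, nSamples)), nrow = nOtus,
              dimnames = list(sprintf("OTU_%03d", seq_len(nOtus)),
                              sprintf("s%03d", seq_len(nSamples))))
  storage.mode(m) <- "integer"
  m
}

makeExperiment <- function(m, group = rep(c("control", "treatment"),
                                          length.out = ncol(m)),
                           trial = "T1", day = 35L) {
  OtuExperiment(m, sampleData = data.frame(
    row.names = colnames(m), trial = trial, day = day, group = group))
}

# Leaf sets below every edge, found by explicit graph descent (the oracle's
# own mechanism; the implementation uses postorder accumulation instead).
edgeLeafSets <- function(tree) {
  children <- split(tree$edge[, 2], tree$edge[, 1])
  nTips <- length(tree$tip.label)
  descend <- function(node) {
    if (node <= nTips) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], descend))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) descend(tree$edge[e, 2]))
}

# Brute-force generalized UniFrac: per-branch accumulation over explicit
# descendant leaf sets.
oracleGUniFrac <- function(counts, tree, alpha) {
  rel <- sweep(counts, 2, colSums(counts), "/")
  sets <- edgeLeafSets(tree)
  b <- tree$edge.length
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0; den <- 0
      for (e in seq_along(sets)) {
        tips <- intersect(sets[[e]], rownames(counts))
        pa <- sum(rel[tips, i]); pb <- sum(rel[tips, j])
        if (pa + pb == 0) next
        w <- b[e] * (pa + pb)^alpha
        num <- num + w * abs(pa - pb) / (pa + pb)
        den <- den + w
      }
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  as.dist(d)
}

# Independently coded weighted-normalized UniFrac:
# sum_i b_i |pA - pB| / sum_i b_i (pA + pB).
oracleWeightedNormalizedUnifrac <- function(counts, tree) {
  rel <- sweep(counts, 2, colSums(counts), "/")
  sets <- edgeLeafSets(tree)
  b <- tree$edge.length
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0; den <- 0
      for (e in seq_along(sets)) {
        tips <- intersect(sets[[e]], rownames(counts))
        pa <- sum(rel[tips, i]); pb <- sum(rel[tips, j])
        num <- num + b[e] * abs(pa - pb)
        den <- den + b[e] * (pa + pb)
      }
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  as.dist(d)
}

# Random UniFrac test instance: tree plus counts with occasional zero rows.
randomUnifracInstance <- function(seed, maxLeaves = 16, maxSamples = 10) {
  set.seed(seed)
  nLeaf <- sample(3:maxLeaves, 1)
  nSamp <- sample(2:maxSamples, 1)
  ids <- sprintf("L%02d", seq_len(nLeaf))
  tree <- simulateTree(ids, seed = seed + 7L)
  m <- matrix(rpois(nLeaf * nSamp, 3), nLeaf,
              dimnames = list(ids, sprintf("s%d", seq_len(nSamp))))
  m[sample(length(m), length(m) %/% 4)] <- 0L
  empty <- colSums(m) == 0
  m[1, empty] <- 1L
  storage.mode(m) <- "integer"
  m
  list(tree = tree, counts = m)
}
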