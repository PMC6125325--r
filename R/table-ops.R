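#' Rarefy samples to a common sequencing depth
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, removing library-size
#' differences before beta-diversity comparison. Samples whose total is
#' below `depth` are dropped and reported via a message; the returned
#' object carries their ids in `attr(, "dropped")` (for matrices) or in
#' `metadata(x)$dropped` (for `OtuExperiment`).
#'
#' @param x An [OtuExperiment-class], or an OTUs x samples count matrix.
#' @param depth Target reads per sample (>= 1).
#' @param seed RNG seed; one sub-seed is derived per sample.
#' @param ... Unused.
#' @return Same class as `x`, every retained sample summing to `depth`.
#' @export
#' @examples
#' m <- matrix(c(10L, 0L, 4L, 6L), 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' rarefy(m, depth = 5, seed = 1)
#' @name rarefy
NULL

#' @rdname rarefy
#' @export
setMethod("rarefy", "matrix", function(x, depth, seed = 1L, ...) {
  assertCountMatrix(x)
  if (length(depth) != 1L || is.na(depth) || depth < 1)
    badInput("depth must be a single integer >= 1")
  depth <- as.integer(depth)
  tot <- colSums(x)
  keep <- tot >= depth
  if (any(!keep))
    message("rarefy: dropping ", sum(!keep), " sample(s) below depth ",
            depth, ": ", paste(colnames(x)[!keep], collapse = ", "))
  seeds <- deriveSeeds(seed, ncol(x))
  out <- x[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    col <- out[, j]
    if (sum(col) == depth) next
    take <- withSeed(seeds[which(keep)[j]],
                     sample(rep.int(seq_along(col), col), depth))
    out[, j] <- tabulate(take, nbins = length(col))
  }
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- colnames(x)[!keep]
  out
})

#' @rdname rarefy
#' @export
setMethod("rarefy", "OtuExperiment", function(x, depth, seed = 1L, ...) {
  m <- rarefy(otuCounts(x), depth = depth, seed = seed)
  dropped <- attr(m, "dropped")
  attr(m, "dropped") <- NULL
  out <- x[, colnames(m)]
  SummarizedExperiment::assay(out, "counts") <- m
  S4Vectors::metadata(out)$dropped <- dropped
  out
})

#' Per-sample relative abundances
#'
#' @param x An [OtuExperiment-class] or OTUs x samples count matrix.
#' @param ... Unused.
#' @return Numeric matrix, same shape and dimnames as the counts, each
#'   sample (column) summing to 1.
#' @export
#' @name relativeAbundance
NULL

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "matrix", function(x, ...) {
  tot <- colSums(x)
  zero <- tot <= 0
  if (any(zero))
    badInput("sample(s) with zero total: %s",
             paste(colnames(x)[zero], collapse = ", "))
  sweep(x, 2L, tot, "/")
})

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "OtuExperiment",
          function(x, ...) relativeAbundance(otuCounts(x)))

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts over all OTUs sharing the same label at `rank`; per-sample
#' totals are conserved.
#'
#' @param x An [OtuExperiment-class] (taxonomy taken from `rowData`) or an
#'   OTUs x samples count matrix (supply `taxonomy`).
#' @param taxonomy Lineage table keyed by OTU id containing column `rank`.
#' @param rank Column of the taxonomy to aggregate by, e.g. `"phylum"` or
#'   `"family"`.
#' @param unclassified If `TRUE`, OTUs missing from the taxonomy are routed
#'   to an `"unclassified"` bin instead of raising an error.
#' @param ... Unused.
#' @return Same class as `x`, rows renamed to the distinct rank labels.
#' @export
#' @name aggregateByRank
NULL

#' @rdname aggregateByRank
#' @export
setMethod("aggregateByRank", "matrix",
  function(x, taxonomy, rank = "phylum", unclassified = FALSE, ...) {
    assertCountMatrix(x)
    if (!rank %in% colnames(taxonomy))
      badInput("taxonomy lacks a '%s' column", rank)
    lab <- setNames(as.character(taxonomy[[rank]]), rownames(taxonomy))
    missing <- setdiff(rownames(x), names(lab))
    if (length(missing)) {
      if (!unclassified)
        badInput("OTU(s) missing from taxonomy: %s",
                 paste(head(missing, 10), collapse = ", "))
      lab[missing] <- "unclassified"
    }
    lab <- lab[rownames(x)]
    lab[is.na(lab) | !nzchar(lab)] <- "unclassified"
    agg <- rowsum(x, group = lab, reorder = TRUE)
    storage.mode(agg) <- "integer"
    agg
  })

#' @rdname aggregateByRank
#' @export
setMethod("aggregateByRank", "OtuExperiment",
  function(x, taxonomy = NULL, rank = "phylum", unclassified = FALSE, ...) {
    if (is.null(taxonomy)) taxonomy <- rowData(x)
    m <- aggregateByRank(otuCounts(x), taxonomy = taxonomy, rank = rank,
                         unclassified = unclassified)
    OtuExperiment(m, sampleData = colData(x))
  })

#' Pool per-trial experiments into one table
#'
#' Prefixes every sample id with its trial label, takes the union of the
#' OTU namespaces (absent OTUs become zero counts), and concatenates the
#' samples, conserving every individual count.
#'
#' @param xs List of [OtuExperiment-class] objects whose `colData` carries
#'   a `trial` column (or supply `trials`).
#' @param trials Optional character vector of trial labels, one per
#'   element of `xs`, overriding `colData`.
#' @return One [OtuExperiment-class] with `sum(sapply(xs, ncol))` samples.
#' @export
poolExperiments <- function(xs, trials = NULL) {
  stopifnot(is.list(xs), length(xs) >= 1L)
  allOtus <- sort(unique(unlist(lapply(xs, otuIds))))
  pieces <- vector("list", length(xs))
  metas <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    trial <- if (!is.null(trials)) rep(trials[i], ncol(x))
             else as.character(colData(x)$trial)
    if (length(trial) != ncol(x) || anyNA(trial))
      badInput("element %d: trial labels unavailable", i)
    m <- matrix(0L, nrow = length(allOtus), ncol = ncol(x),
                dimnames = list(allOtus, paste0(trial, ".", sampleIds(x))))
    m[otuIds(x), ] <- otuCounts(x)
    pieces[[i]] <- m
    md <- as.data.frame(colData(x))
    md$trial <- trial
    rownames(md) <- colnames(m)
    metas[[i]] <- md
  }
  pooled <- do.call(cbind, pieces)
  if (anyDuplicated(colnames(pooled)))
    badInput("sample id collision after trial-prefixing: %s",
             paste(unique(colnames(pooled)[duplicated(colnames(pooled))]),
                   collapse = ", "))
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(md) {
    md[setdiff(cols, names(md))] <- NA
    md[cols]
  })
  OtuExperiment(pooled, sampleData = do.call(rbind, metas))
}

#' Restrict an experiment to one sampling day
#'
#' @param x An [OtuExperiment-class] with a `day` column in `colData`.
#' @param day Day to keep (e.g. 35).
#' @return The subset experiment; a warning (not an error) is raised when
#'   no sample matches.
#' @export
filterToDay <- function(x, day) {
  if (!"day" %in% names(colData(x)))
    badInput("colData(x) must contain a 'day' column")
  keep <- colData(x)$day == day
  if (!any(keep))
    warning("no samples at day ", day, call. = FALSE)
  x[, keep]
}
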