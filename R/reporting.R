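#' Phylum-level roll-up of the selected OTUs
#'
#' Partitions the selected set by taxonomic rank and direction of change.
#' OTUs whose direction is `unchanged` count towards `n_selected` but
#' towards neither direction.
#'
#' @param result An [ErfResult-class] (or its `relevanceTable()`
#'   `DataFrame` with `selected` and `direction` columns).
#' @param taxonomy Lineage table keyed by OTU id.
#' @param rank Rank to roll up to, `"phylum"` (default) or `"family"`.
#' @return `DataFrame` with `n_selected`, `n_increased`, `n_decreased`
#'   per rank label, sorted by `n_selected` descending.
#' @export
summarizeSelected <- function(result, taxonomy, rank = "phylum") {
  res <- if (is(result, "ErfResult")) relevanceTable(result) else result
  sel <- res[res$selected, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(S4Vectors::DataFrame(n_selected = integer(0),
                                n_increased = integer(0),
                                n_decreased = integer(0)))
  if (!rank %in% colnames(taxonomy))
    badInput("taxonomy lacks a '%s' column", rank)
  missing <- setdiff(sel$otu_id, rownames(taxonomy))
  if (length(missing))
    badInput("selected OTU(s) missing from taxonomy: %s",
             paste(missing, collapse = ", "))
  lab <- as.character(taxonomy[sel$otu_id, rank])
  out <- S4Vectors::DataFrame(
    n_selected = unname(as.integer(table(lab)[unique(lab)])),
    n_increased = unname(vapply(unique(lab), function(l)
      sum(lab == l & sel$direction == "increased"), integer(1))),
    n_decreased = unname(vapply(unique(lab), function(l)
      sum(lab == l & sel$direction == "decreased"), integer(1))),
    row.names = unique(lab))
  out[order(-out$n_selected, rownames(out)), ]
}

#' Group-wise abundance shift per taxon
#'
#' Aggregates counts to `rank`, converts to percentage relative abundance
#' per sample, and contrasts the group means: `delta_pct` is the
#' percentage-point difference (treatment - control) and
#' `relative_change_pct` the change relative to the control mean. Deltas
#' sum to zero across taxa (compositional closure).
#'
#' @param x An [OtuExperiment-class] with taxonomy in `rowData` and binary
#'   `group` in `colData`.
#' @param rank Rank to aggregate by.
#' @return `DataFrame` sorted by control abundance descending, columns
#'   `control_mean_pct`, `treatment_mean_pct`, `delta_pct`,
#'   `relative_change_pct`.
#' @export
phylumShift <- function(x, rank = "phylum") {
  g <- groupFactor(x)
  agg <- aggregateByRank(x, rank = rank)
  relPct <- 100 * relativeAbundance(agg)
  mC <- rowMeans(relPct[, g == "control", drop = FALSE])
  mT <- rowMeans(relPct[, g == "treatment", drop = FALSE])
  out <- S4Vectors::DataFrame(
    taxon = rownames(relPct),
    control_mean_pct = unname(mC),
    treatment_mean_pct = unname(mT),
    delta_pct = unname(mT - mC),
    relative_change_pct = unname(100 * (mT - mC) / mC),
    row.names = rownames(relPct))
  out[order(-out$control_mean_pct), ]
}

#' Export per-leaf tree annotations for the selected OTUs
#'
#' Writes a TSV consumable by tree viewers next to a newick file: one row
#' per selected, directionally changed OTU with a colour class
#' (`increased`/`decreased`) and a size proportional to `|log2 fold
#' change|`. Unchanged OTUs are excluded; every id is checked against the
#' tree's leaves before writing.
#'
#' @param result An [ErfResult-class].
#' @param tree `ape::phylo` whose tips cover the selected OTUs.
#' @param path Output TSV path.
#' @return The annotation `DataFrame`, invisibly.
#' @export
exportTreeAnnotations <- function(result, tree, path) {
  res <- relevanceTable(result)
  sel <- res[res$selected & res$direction != "unchanged", , drop = FALSE]
  missing <- setdiff(sel$otu_id, tree$tip.label)
  if (length(missing))
    badInput("selected OTU(s) absent from tree: %s",
             paste(missing, collapse = ", "))
  ann <- S4Vectors::DataFrame(
    otu_id = sel$otu_id,
    colour_class = sel$direction,
    size = abs(log2(sel$fold_change)))
  write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(ann)
}
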