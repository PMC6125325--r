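#' Construct an OtuExperiment
#'
#' @param counts Nonnegative integer matrix of abundances. Either OTUs x
#'   samples (the internal orientation) or samples x OTUs with
#'   `samplesAsRows = TRUE`; both dimensions must be named.
#' @param sampleData `data.frame`/`DataFrame` of per-sample metadata keyed
#'   by sample id (rownames or a `#SampleID`/`sample_id` column); typically
#'   columns `trial`, `day`, `group` with `group` in
#'   `c("control", "treatment")`.
#' @param taxonomy Optional per-OTU lineage table keyed by OTU id
#'   (rownames or an `otu_id` column); see [simulateTaxonomy()] for the
#'   expected columns.
#' @param samplesAsRows Set `TRUE` when `counts` has samples as rows (the
#'   on-disk TSV layout).
#' @return An [OtuExperiment-class].
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 3L), 2,
#'             dimnames = list(c("OTU_1", "OTU_2"), c("s1", "s2")))
#' OtuExperiment(m)
OtuExperiment <- function(counts, sampleData = NULL, taxonomy = NULL,
                          samplesAsRows = FALSE) {
  counts <- as.matrix(counts)
  if (samplesAsRows) counts <- t(counts)
  assertCountMatrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    badInput("counts must carry OTU ids and sample ids as dimnames")
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sampleData <- .keyedFrame(sampleData, c("#SampleID", "sample_id"))
    missing <- setdiff(colnames(counts), rownames(sampleData))
    if (length(missing))
      badInput("sampleData lacks records for sample(s): %s",
               paste(missing, collapse = ", "))
    cd <- S4Vectors::DataFrame(sampleData[colnames(counts), , drop = FALSE])
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    taxonomy <- .keyedFrame(taxonomy, c("#OTUID", "otu_id"))
    missing <- setdiff(rownames(counts), rownames(taxonomy))
    if (length(missing))
      badInput("taxonomy lacks lineage for OTU(s): %s",
               paste(head(missing, 5), collapse = ", "))
    rd <- S4Vectors::DataFrame(taxonomy[rownames(counts), , drop = FALSE])
  }
  new("OtuExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           colData = cd, rowData = rd))
}

# Promote an id column to rownames if rownames are absent/default.
.keyedFrame <- function(df, idCols) {
  df <- as.data.frame(df)
  hit <- intersect(idCols, names(df))
  if (length(hit)) {
    rownames(df) <- as.character(df[[hit[1]]])
    df[[hit[1]]] <- NULL
  }
  df
}

#' Accessors for OtuExperiment and results
#'
#' `otuCounts()` returns the integer count matrix (OTUs x samples);
#' `otuIds()`/`sampleIds()` the feature and sample identifiers;
#' `taxonomyTable()` the per-OTU lineage `DataFrame`.
#'
#' @param x An [OtuExperiment-class].
#' @return See each description.
#' @aliases otuCounts otuIds sampleIds taxonomyTable
#' @name otuCounts
NULL

#' @rdname otuCounts
#' @export
setMethod("otuCounts", "OtuExperiment", function(x) assay(x, "counts"))

#' @rdname otuCounts
#' @export
setMethod("otuIds", "OtuExperiment", function(x) rownames(x))

#' @rdname otuCounts
#' @export
setMethod("sampleIds", "OtuExperiment", function(x) colnames(x))

#' @rdname otuCounts
#' @export
setMethod("taxonomyTable", "OtuExperiment", function(x) rowData(x))

#' @export
#' @describeIn OtuExperiment-class Compact display.
setMethod("show", "OtuExperiment", function(object) {
  cat(sprintf("OtuExperiment: %d OTUs x %d samples\n",
              nrow(object), ncol(object)))
  tot <- colSums(assay(object, "counts"))
  cat(sprintf("  library sizes: %d-%d (median %.0f)\n",
              min(tot), max(tot), stats::median(tot)))
  cd <- colData(object)
  for (f in intersect(c("trial", "day", "group"), names(cd))) {
    tab <- table(as.character(cd[[f]]))
    cat(sprintf("  %s: %s\n", f,
                paste(sprintf("%s(%d)", names(tab), tab), collapse = " ")))
  }
  if ("phylum" %in% names(rowData(object)))
    cat(sprintf("  taxonomy: %d phyla\n",
                length(unique(rowData(object)$phylum))))
  invisible(NULL)
})

# Binary group factor with control as reference; errors unless both present.
groupFactor <- function(x, requireBoth = TRUE) {
  if (!"group" %in% names(colData(x)))
    badInput("colData(x) must contain a 'group' column")
  g <- factor(as.character(colData(x)$group),
              levels = c("control", "treatment"))
  if (anyNA(g))
    badInput("group must be 'control' or 'treatment'")
  if (requireBoth && length(unique(g)) < 2L)
    badInput("both 'control' and 'treatment' samples are required")
  g
}
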