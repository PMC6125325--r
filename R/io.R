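#' Read and write OTU count tables
#'
#' Tab-separated, UTF-8, samples as rows: header `#SampleID` followed by
#' OTU ids, one sample per line with nonnegative integer counts (the
#' BIOM-TSV-compatible layout). Parse failures (ragged rows, non-integer or
#' negative cells, duplicate ids) report the offending line.
#'
#' @param path File path.
#' @param x For the writer, an [OtuExperiment-class] (its sample metadata
#'   and taxonomy are not written; see [writeSampleMetadata()] and
#'   [writeTaxonomy()]).
#' @return `readCountTable()` returns an [OtuExperiment-class] with empty
#'   metadata; `writeCountTable()` returns `path` invisibly.
#' @export
readCountTable <- function(path) {
  lines <- .readTsvLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "#SampleID")
    badInput("line 1: header must start with '#SampleID' and list OTU ids")
  ids <- header[-1]
  if (anyDuplicated(ids))
    badInput("line 1: duplicate OTU id(s): %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      badInput("line %d: expected %d fields, found %d",
               i, length(header), length(f))
    vals <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(vals) | vals < 0 | vals != round(vals))
    if (length(bad))
      badInput("line %d: non-integer or negative count in column '%s'",
               i, ids[bad[1]])
    list(id = f[1], counts = as.integer(vals))
  })
  samples <- vapply(body, `[[`, "", "id")
  if (anyDuplicated(samples))
    badInput("duplicate sample id '%s'",
             samples[duplicated(samples)][1])
  m <- do.call(rbind, lapply(body, `[[`, "counts"))
  dimnames(m) <- list(samples, ids)
  OtuExperiment(m, samplesAsRows = TRUE)
}

#' @rdname readCountTable
#' @export
writeCountTable <- function(x, path) {
  m <- t(otuCounts(x))
  out <- data.frame("#SampleID" = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

.readTsvLines <- function(path) {
  if (!file.exists(path))
    badInput("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    badInput("%s: need a header and at least one data row", path)
  lines
}

#' Read and write sample metadata
#'
#' TSV with columns `#SampleID`, `trial`, `day`, `group`.
#'
#' @param path File path.
#' @param x A `data.frame`/`DataFrame` keyed by sample id (for the writer),
#'   e.g. `colData()` of an [OtuExperiment-class].
#' @return `readSampleMetadata()` returns a `data.frame` with sample ids as
#'   rownames.
#' @export
readSampleMetadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  need <- c("#SampleID", "trial", "day", "group")
  missing <- setdiff(need, names(df))
  if (length(missing))
    badInput("%s: missing column(s): %s", path,
             paste(missing, collapse = ", "))
  if (anyDuplicated(df[["#SampleID"]]))
    badInput("%s: duplicate sample id(s)", path)
  .keyedFrame(df, "#SampleID")
}

#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(x, path) {
  df <- as.data.frame(x)
  out <- cbind("#SampleID" = rownames(df), df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write taxonomy tables
#'
#' TSV with columns `#OTUID`, `phylum`, `class`, `order`, `family`,
#' `genus` and optional `nearest_species`; `phylum` must be non-empty
#' (use `"unclassified"` for unknowns).
#'
#' @param path File path.
#' @param x Lineage table keyed by OTU id (for the writer).
#' @return `readTaxonomy()` returns a `DataFrame` keyed by OTU id.
#' @export
readTaxonomy <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  need <- c("#OTUID", "phylum")
  missing <- setdiff(need, names(df))
  if (length(missing))
    badInput("%s: missing column(s): %s", path,
             paste(missing, collapse = ", "))
  if (any(!nzchar(df$phylum) | is.na(df$phylum)))
    badInput("%s: empty phylum for OTU(s): %s", path,
             paste(df[["#OTUID"]][!nzchar(df$phylum)], collapse = ", "))
  S4Vectors::DataFrame(.keyedFrame(df, "#OTUID"))
}

#' @rdname readTaxonomy
#' @export
writeTaxonomy <- function(x, path) {
  df <- as.data.frame(x)
  df$otu_id <- NULL
  out <- cbind("#OTUID" = rownames(df), df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from newick
#'
#' Thin wrapper over [ape::read.tree()] that enforces what UniFrac needs:
#' a rooted tree whose every edge carries a nonnegative branch length.
#'
#' @param path Newick file.
#' @return An `ape::phylo`.
#' @export
readPhyloTree <- function(path) {
  if (!file.exists(path))
    badInput("file not found: %s", path)
  tree <- ape::read.tree(path)
  if (is.null(tree))
    badInput("%s: not parseable as newick", path)
  if (is.null(tree$edge.length))
    badInput("%s: tree lacks branch lengths", path)
  if (any(tree$edge.length < 0))
    badInput("%s: negative branch length(s)", path)
  if (!ape::is.rooted(tree))
    badInput("%s: tree must be rooted", path)
  tree
}

#' Read and write distance matrices as TSV
#'
#' Square layout with a `#SampleID` header column.
#'
#' @param dm A `dist` or symmetric matrix with sample ids.
#' @param path File path.
#' @return `readDistanceMatrix()` returns a `dist`.
#' @export
readDistanceMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  if (names(df)[1] != "#SampleID")
    badInput("%s: first column must be '#SampleID'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[["#SampleID"]]
  if (!identical(rownames(m), colnames(m)))
    badInput("%s: row and column sample ids differ", path)
  if (max(abs(m - t(m))) > 1e-8)
    badInput("%s: matrix is not symmetric", path)
  stats::as.dist(m)
}

#' @rdname readDistanceMatrix
#' @export
writeDistanceMatrix <- function(dm, path) {
  m <- as.matrix(dm)
  out <- data.frame("#SampleID" = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
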