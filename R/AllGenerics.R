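#' @rdname rarefy
#' @export
setGeneric("rarefy", function(x, depth, seed = 1L, ...)
  standardGeneric("rarefy"))

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance", function(x, ...)
  standardGeneric("relativeAbundance"))

#' @rdname aggregateByRank
#' @export
setGeneric("aggregateByRank", function(x, taxonomy = NULL,
                                       rank = "phylum", ...)
  standardGeneric("aggregateByRank"))

#' @rdname generalizedUnifrac
#' @export
setGeneric("generalizedUnifrac", function(x, tree, alpha = 0.5, ...)
  standardGeneric("generalizedUnifrac"))

#' @rdname otuCounts
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname otuCounts
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname otuCounts
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname otuCounts
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname relevanceTable
#' @export
setGeneric("relevanceTable", function(x) standardGeneric("relevanceTable"))

#' @rdname relevanceTable
#' @export
setGeneric("selectedOtus", function(x) standardGeneric("selectedOtus"))

#' @rdname relevanceTable
#' @export
setGeneric("vimMatrix", function(x) standardGeneric("vimMatrix"))
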