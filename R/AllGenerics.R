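#' Accessors for retroMosaic classes
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param x an object
#' @return the corresponding component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @rdname accessors
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))
#' @rdname accessors
#' @export
setGeneric("refREAnnotation", function(x) standardGeneric("refREAnnotation"))
#' @rdname accessors
#' @export
setGeneric("insertionEvents", function(x) standardGeneric("insertionEvents"))
#' @rdname accessors
#' @export
setGeneric("callRanges", function(x) standardGeneric("callRanges"))
#' @rdname accessors
#' @export
setGeneric("libraryTissue", function(x) standardGeneric("libraryTissue"))
#' @rdname accessors
#' @export
setGeneric("libraryFamily", function(x) standardGeneric("libraryFamily"))
#' @rdname accessors
#' @export
setGeneric("callTallies", function(x) standardGeneric("callTallies"))
#' @rdname accessors
#' @export
setGeneric("promoterRanges", function(x) standardGeneric("promoterRanges"))

#' @rdname accessors
#' @export
setMethod("genomeSequences", "GenomeModel", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("geneAnnotation", "GenomeModel", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("refREAnnotation", "GenomeModel", function(x) x@refRE)
#' @rdname accessors
#' @export
setMethod("insertionEvents", "InsertionSet", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("callRanges", "CallSet", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("libraryTissue", "CallSet", function(x) x@tissue)
#' @rdname accessors
#' @export
setMethod("libraryFamily", "CallSet", function(x) x@family)
#' @rdname accessors
#' @export
setMethod("callTallies", "CallSet", function(x) x@tallies)
#' @rdname accessors
#' @export
setMethod("geneAnnotation", "AnnotationIndex", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("promoterRanges", "AnnotationIndex", function(x) x@promoters)

#' @rdname accessors
#' @param object a \code{CallSet}
#' @export
setMethod("length", "CallSet", function(x) length(x@calls))
#' @rdname accessors
#' @export
setMethod("length", "InsertionSet", function(x) length(x@events))
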