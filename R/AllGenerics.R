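#' @name accessors
#' @title Accessors for intronTurnover classes
#' @param x an object.
#' @description Slot accessors: use these rather than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("geneID", function(x) standardGeneric("geneID"))

#' @rdname accessors
#' @export
setGeneric("geneSpecies", function(x) standardGeneric("geneSpecies"))

#' @rdname accessors
#' @export
setGeneric("exonTable", function(x) standardGeneric("exonTable"))

#' @rdname accessors
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))

#' @rdname accessors
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))

#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname accessors
#' @export
setGeneric("siteMembers", function(x) standardGeneric("siteMembers"))

#' @rdname accessors
#' @export
setGeneric("siteSpecies", function(x) standardGeneric("siteSpecies"))

#' @rdname accessors
#' @export
setGeneric("siteEvents", function(x) standardGeneric("siteEvents"))

#' @rdname accessors
#' @export
setGeneric("branchRates", function(x) standardGeneric("branchRates"))

#' @rdname accessors
#' @export
setGeneric("rootAmbiguousCount", function(x) standardGeneric("rootAmbiguousCount"))
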