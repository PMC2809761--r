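## GeneModel construction and accessors.

emptyIntronTable <- function() {
  data.frame(gene_id = character(0), species = character(0),
             index = integer(0), start = integer(0), end = integer(0),
             length = integer(0), phase = integer(0), seq = character(0),
             donor6 = character(0), acceptor3 = character(0),
             cds_offset = integer(0), cds_length = integer(0),
             stringsAsFactors = FALSE)
}

#' Build a GeneModel from a contig sequence and exon coordinates
#'
#' Exon coordinates are contig coordinates (1-based inclusive, ascending).
#' For minus-strand genes the coding sequence and intron table are computed on
#' the coding strand (coordinates flipped with `pos' = L - pos + 1`, sequences
#' reverse-complemented) so introns always read 5'->3'.
#'
#' @param geneID,species,contig identifiers.
#' @param strand "+" or "-".
#' @param exons 2-column matrix (start, end), 1-based inclusive, ascending.
#' @param contigSeq character, full contig sequence (plus strand).
#' @return a [GeneModel-class] object.
#' @export
geneModelFromContig <- function(geneID, species, contig, strand, exons,
                                contigSeq) {
  exons <- matrix(as.integer(exons), ncol = 2L)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  L <- nchar(contigSeq)
  if (any(exons[, 1] < 1L) || any(exons[, 2] > L))
    stop("CDS coordinates outside contig '", contig, "' for gene '", geneID, "'")
  exonSeqs <- substring(contigSeq, exons[, 1], exons[, 2])
  cds <- paste(exonSeqs, collapse = "")
  nEx <- nrow(exons)
  if (nEx > 1L) {
    gapStart <- exons[-nEx, 2] + 1L          # contig coords, ascending order
    gapEnd <- exons[-1L, 1] - 1L
    gapSeqs <- substring(contigSeq, gapStart, gapEnd)
  } else {
    gapStart <- gapEnd <- integer(0)
    gapSeqs <- character(0)
  }
  if (strand == "-") {
    cds <- revComp(cds)
    if (length(gapSeqs)) {
      gapSeqs <- vapply(rev(gapSeqs), revComp, character(1), USE.NAMES = FALSE)
      ## flip half: coding-strand coordinate of contig position p is L - p + 1
      s <- L - rev(gapEnd) + 1L
      e <- L - rev(gapStart) + 1L
      gapStart <- s
      gapEnd <- e
    }
    exonWidths <- rev(exons[, 2] - exons[, 1] + 1L)
  } else {
    exonWidths <- exons[, 2] - exons[, 1] + 1L
  }
  cdsLen <- nchar(cds)
  nIntr <- length(gapSeqs)
  if (nIntr > 0L) {
    offs <- cumsum(exonWidths)[seq_len(nIntr)]
    lens <- gapEnd - gapStart + 1L
    it <- data.frame(
      gene_id = geneID, species = species, index = seq_len(nIntr),
      start = gapStart, end = gapEnd, length = lens,
      phase = as.integer(offs %% 3L), seq = gapSeqs,
      donor6 = substr(gapSeqs, 1L, 6L),
      acceptor3 = substr(gapSeqs, lens - 2L, lens),
      cds_offset = as.integer(offs), cds_length = cdsLen,
      stringsAsFactors = FALSE)
  } else {
    it <- emptyIntronTable()
  }
  new("GeneModel", geneID = geneID, species = species, contig = contig,
      strand = strand, exons = exons, contigLength = as.integer(L),
      contigSeq = contigSeq, cdsSeq = cds, intronTable = it)
}

#' @rdname accessors
#' @export
setMethod("geneID", "GeneModel", function(x) x@geneID)

#' @rdname accessors
#' @export
setMethod("geneSpecies", "GeneModel", function(x) x@species)

#' @rdname accessors
#' @export
setMethod("exonTable", "GeneModel", function(x) x@exons)

#' @rdname accessors
#' @export
setMethod("cdsSeq", "GeneModel", function(x) x@cdsSeq)

#' @rdname accessors
#' @export
setMethod("introns", "GeneModel", function(x) x@intronTable)

#' Contig sequence of a gene model (plus strand)
#' @param x a [GeneModel-class].
#' @return character scalar.
#' @export
contigSequence <- function(x) x@contigSeq

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneID, "(", object@species, ")\n")
  cat("  contig:", object@contig, object@strand, " exons:", nrow(object@exons),
      " CDS:", nchar(object@cdsSeq), "nt  introns:",
      nrow(object@intronTable), "\n")
})

#' Pool the intron tables of many gene models
#'
#' @param models a list of [GeneModel-class] objects, or a list of such lists
#'   (e.g. per-species lists).
#' @return a single intron data.frame.
#' @export
intronTableOf <- function(models) {
  if (length(models) && !is(models[[1]], "GeneModel"))
    models <- unlist(models, recursive = FALSE)
  tabs <- lapply(models, introns)
  tabs <- tabs[vapply(tabs, nrow, integer(1)) > 0L]
  if (!length(tabs)) return(emptyIntronTable())
  do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}
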