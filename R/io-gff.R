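## GFF3 + FASTA gene-model input/output.
##
## Reading goes through rtracklayer::import (GFF3, 1-based inclusive on disk);
## writing uses a small formatter that emits the same gene/mRNA/CDS layout the
## reader consumes, so a write/read round trip is the identity on valid input.

#' Read gene models from a GFF3 annotation and a genome FASTA
#'
#' One [GeneModel-class] is returned per gene, keeping the longest
#' amino-acid isoform (ties broken lexicographically by transcript id).
#' Minus-strand genes are strand-normalized at load. Genes whose CDS length is
#' not divisible by 3, or whose translation contains an internal stop (both
#' symptoms of a frameshift, real or from sequencing error), are skipped with
#' a warning. CDS coordinates outside their contig are a hard error naming the
#' offending feature.
#'
#' @param gff3Path path to a GFF3 file with gene/mRNA/CDS features.
#' @param fastaPath path to the genome FASTA covering all CDS coordinates.
#' @param species species label stamped on every model.
#' @return named list of [GeneModel-class] objects (possibly empty).
#' @export
readGeneModels <- function(gff3Path, fastaPath, species) {
  gr <- rtracklayer::import(gff3Path)
  if (length(gr) == 0L) return(list())
  genome <- Biostrings::readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))

  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- vapply(as.list(md$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  mrnaIdx <- which(type == "mRNA")
  cdsIdx <- which(type == "CDS")
  if (!length(mrnaIdx) || !length(cdsIdx)) return(list())

  mrnaGene <- setNames(parents[mrnaIdx], ids[mrnaIdx])
  cdsByTx <- split(cdsIdx, parents[cdsIdx])

  ## longest isoform per gene, aa length = total CDS width / 3
  txLen <- vapply(cdsByTx, function(i) sum(GenomicRanges::width(gr[i])),
                  numeric(1))
  txGene <- mrnaGene[names(cdsByTx)]
  keepTx <- vapply(split(names(cdsByTx), txGene), function(txs) {
    lens <- txLen[txs]
    best <- txs[lens == max(lens)]
    sort(best)[1L]
  }, character(1))

  out <- list()
  for (gene in names(keepTx)) {
    tx <- keepTx[[gene]]
    i <- cdsByTx[[tx]]
    contig <- as.character(GenomicRanges::seqnames(gr[i]))[1]
    strand <- as.character(GenomicRanges::strand(gr[i]))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    exons <- cbind(GenomicRanges::start(gr[i]), GenomicRanges::end(gr[i]))
    if (!contig %in% names(genome))
      stop("CDS of transcript '", tx, "' references unknown contig '",
           contig, "'")
    contigSeq <- as.character(genome[[contig]])
    if (max(exons[, 2]) > nchar(contigSeq) || min(exons[, 1]) < 1L)
      stop("CDS coordinate outside contig for transcript '", tx, "'")
    if (sum(exons[, 2] - exons[, 1] + 1L) %% 3L != 0L) {
      warning("gene '", gene, "' skipped: CDS length not divisible by 3 ",
              "(frameshift?)", call. = FALSE)
      next
    }
    gm <- geneModelFromContig(gene, species, contig, strand, exons, contigSeq)
    prot <- translateCds(cdsSeq(gm))
    if (grepl("\\*", substr(prot, 1L, nchar(prot) - 1L))) {
      warning("gene '", gene, "' skipped: internal stop codon in CDS",
              call. = FALSE)
      next
    }
    out[[gene]] <- gm
  }
  out[order(names(out))]
}

#' Write gene models to GFF3
#'
#' Emits the gene/mRNA/CDS hierarchy [readGeneModels()] consumes, 1-based
#' inclusive coordinates, with CDS phase columns.
#'
#' @param models list of [GeneModel-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    ex <- gm@exons
    g0 <- min(ex[, 1]); g1 <- max(ex[, 2])
    gid <- gm@geneID
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
      paste(gm@contig, "intronTurnover", "gene", g0, g1, ".", gm@strand, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(gm@contig, "intronTurnover", "mRNA", g0, g1, ".", gm@strand, ".",
            paste0("ID=", tid, ";Parent=", gid), sep = "\t"))
    widths <- ex[, 2] - ex[, 1] + 1L
    ## phase: coding nt left over before each CDS part, in transcription order
    ord <- if (gm@strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    upstream <- cumsum(c(0L, widths[ord]))[seq_along(ord)]
    phase <- (3L - (upstream %% 3L)) %% 3L
    phaseByRow <- integer(nrow(ex))
    phaseByRow[ord] <- phase
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines,
        paste(gm@contig, "intronTurnover", "CDS", ex[k, 1], ex[k, 2], ".",
              gm@strand, phaseByRow[k],
              paste0("ID=cds-", tid, ";Parent=", tid), sep = "\t"))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a set of contigs as FASTA
#'
#' @param seqs named character vector or DNAStringSet.
#' @param path output path.
#' @export
writeGenomeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
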