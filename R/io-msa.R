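## Aligned protein FASTA input/output and residue->column maps.

#' Read a protein multiple alignment (aligned FASTA)
#'
#' @param fastaPath path to an aligned FASTA file; all rows must have equal
#'   length; gap character is `-`.
#' @return an `AAStringSet` of equal-width rows.
#' @export
readProteinMSA <- function(fastaPath) {
  aln <- Biostrings::readAAStringSet(fastaPath)
  names(aln) <- sub("\\s.*$", "", names(aln))
  w <- Biostrings::width(aln)
  if (length(unique(w)) > 1L)
    stop("alignment rows have unequal lengths (",
         paste(unique(w), collapse = ", "), ")")
  aln
}

#' Write a protein multiple alignment
#' @param aln `AAStringSet` (equal widths) or named character vector.
#' @param path output path.
#' @export
writeProteinMSA <- function(aln, path) {
  if (!is(aln, "AAStringSet")) aln <- Biostrings::AAStringSet(aln)
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

#' Residue-to-column maps for an alignment
#'
#' For each row, returns an integer vector mapping the 1-based ungapped
#' residue index to its 1-based alignment column. All-gap columns map to no
#' residue.
#'
#' @param aln `AAStringSet` or named character vector of equal-length rows.
#' @return named list of integer vectors.
#' @export
msaRowMap <- function(aln) {
  rows <- as.character(aln)
  names(rows) <- names(aln)
  lapply(rows, function(r) which(chars(r) != "-"))
}
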