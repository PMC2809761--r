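## Small internal helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

## All 64 codons in lexicographic order (AAA, AAC, ..., TTT).
ALL_CODONS <- sort(apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1, paste0,
                         collapse = ""))

SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Reverse-complement a DNA string
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @keywords internal
#' @noRd
revComp <- function(x) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

#' Translate a coding sequence (no terminal stop expected)
#'
#' Lookup-table translation (standard code); codons with ambiguous bases
#' give "X", stops give "*".
#' @keywords internal
#' @noRd
translateCds <- local({
  code <- NULL
  function(x) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    n <- nchar(x) %/% 3L
    codons <- substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- code[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})

## Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Random DNA of length n from the global RNG.
randomDna <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

## Random sense (non-stop) codons, concatenated.
randomSenseCodons <- function(n) {
  if (n <= 0) return("")
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

## Derive k child seeds (< 2^31) from the current RNG stream.
deriveSeeds <- function(k) sample.int(.Machine$integer.max - 1L, k)

## Integer check helper for validity methods.
isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
  x == as.integer(x)

## Collapse a character vector into a comma-joined field (empty -> "").
joinField <- function(x) if (length(x) == 0L) "" else paste(x, collapse = ",")

## Inverse of joinField.
splitField <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}

## Write a data.frame as a UTF-8 tab-delimited file with a header row.
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

readTsv <- function(path, colClasses = NA) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = colClasses)
}
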