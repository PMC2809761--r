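## 5' positional bias tests and intron "codon" usage.

#' Relative positions of introns within their genes
#'
#' @param intronTable intron data.frame with `cds_offset` and `cds_length`.
#' @return numeric vector of `cds_offset / cds_length` in [0, 1).
#' @export
relativePositions <- function(intronTable) {
  r <- intronTable$cds_offset / intronTable$cds_length
  stopifnot(all(r >= 0 & r < 1))
  r
}

#' Chi-square test of positional uniformity
#'
#' Bins relative positions into `nBins` equal-width bins on [0, 1) and
#' computes the Pearson chi-square statistic against the uniform expectation
#' (df = nBins - 1). With two bins this is the minimal 5'-half versus 3'-half
#' comparison; when an expected count falls below 5 a warning is raised and,
#' for `nBins = 2`, an exact binomial p-value is reported instead.
#'
#' @param positions numeric vector in [0, 1).
#' @param nBins number of equal-width bins (default 2).
#' @return list with `chisq`, `df`, `p`, `method`, `counts`.
#' @export
uniformityChisq <- function(positions, nBins = 2L) {
  stopifnot(all(positions >= 0 & positions < 1), nBins >= 2L)
  n <- length(positions)
  counts <- tabulate(pmin(floor(positions * nBins) + 1L, nBins), nBins)
  expected <- n / nBins
  chisq <- sum((counts - expected)^2 / expected)
  df <- nBins - 1L
  method <- "pearson"
  p <- pchisq(chisq, df, lower.tail = FALSE)
  if (expected < 5) {
    warning("expected count per bin below 5", call. = FALSE)
    if (nBins == 2L) {
      p <- binom.test(counts[1], n, 0.5)$p.value
      method <- "exact_binomial"
    }
  }
  list(chisq = chisq, df = df, p = p, method = method, counts = counts)
}

#' Two-sample chi-square comparison of 5' bias
#'
#' Builds the 2x2 table (sample x 5'/3' half) and computes the Pearson
#' chi-square statistic without continuity correction (df = 1).
#'
#' @param positionsA,positionsB numeric vectors in [0, 1), both non-empty.
#' @return list with `chisq`, `df`, `p`, `table`.
#' @export
twoSampleChisq <- function(positionsA, positionsB) {
  if (!length(positionsA) || !length(positionsB))
    stop("both samples must be non-empty")
  tab <- rbind(a = c(sum(positionsA < 0.5), sum(positionsA >= 0.5)),
               b = c(sum(positionsB < 0.5), sum(positionsB >= 0.5)))
  colnames(tab) <- c("five_prime", "three_prime")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the 2x2 table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Codon usage of intron sequences
#'
#' Reads codons in the retention frame (starting at
#' [retentionFrameOffset()] for each intron's phase; `frame = "zero"` starts
#' at the first base instead), pools the counts over all introns, and scales
#' to frequencies per 1,000 codons. Codons containing ambiguous bases are
#' skipped and counted.
#'
#' @param intronTable intron data.frame with `seq` and `phase`.
#' @param frame `"retention"` (default) or `"zero"`.
#' @return named numeric vector of length 64 (per-1000 frequencies), with
#'   attributes `n_codons` and `n_skipped`.
#' @export
intronCodonUsage <- function(intronTable, frame = c("retention", "zero")) {
  frame <- match.arg(frame)
  if (!nrow(intronTable)) stop("empty intron set")
  off <- if (frame == "retention") retentionFrameOffset(intronTable$phase)
         else rep(0L, nrow(intronTable))
  trimmed <- substr(intronTable$seq, off + 1L, nchar(intronTable$seq))
  nSlots <- sum(nchar(trimmed) %/% 3L)
  counts <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(trimmed), step = 3))
  total <- sum(counts)
  if (total == 0L) stop("no complete codons in the intron set")
  usage <- 1000 * counts / total
  structure(usage[ALL_CODONS], names = ALL_CODONS,
            n_codons = total, n_skipped = nSlots - total)
}

#' Spearman correlation between a usage vector and a reference table
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value, after
#' aligning the two vectors by codon name.
#'
#' @param usage named numeric vector of length 64 (see [intronCodonUsage()]).
#' @param reference named numeric vector of length 64, or a data.frame with
#'   columns `codon` and a numeric usage column, or a path to such a TSV.
#' @return list with `rho` and `p`.
#' @export
usageCorrelation <- function(usage, reference) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- readTsv(reference)
  if (is.data.frame(reference)) {
    num <- vapply(reference, is.numeric, logical(1))
    reference <- setNames(reference[[which(num)[1]]], reference$codon)
  }
  stopifnot(length(usage) == 64L, length(reference) == 64L)
  reference <- reference[names(usage)]
  if (anyNA(reference)) stop("reference table must cover all 64 codons")
  if (sd(usage) == 0 || sd(reference) == 0)
    stop("constant vector: Spearman correlation undefined")
  ct <- suppressWarnings(cor.test(usage, reference, method = "spearman",
                                  alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Path to the packaged synthetic codon-usage reference table
#'
#' A synthetic reference (not organism data) with realistic per-1000
#' magnitudes, shipped so the usage-correlation stage can run without
#' external downloads. Supply a real organism table for genuine analyses.
#' @return file path.
#' @export
syntheticCodonUsagePath <- function() {
  system.file("extdata", "synthetic_codon_usage.tsv",
              package = "intronTurnover", mustWork = TRUE)
}
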