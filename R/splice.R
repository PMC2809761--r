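## Splice-site strength and motif diversity by bootstrap resampling.
##
## Strength is the fraction of introns using the strong consensus motifs:
## GT(A/G)AGT at donor positions +1..+6 and CAG at acceptor positions -3..-1.
## Significance is assessed by resampling (with replacement) focal-sized
## samples from the reference intron population and reading off the 2.5/97.5
## percentile interval.

CANONICAL_DONORS <- c("GTAAGT", "GTGAGT")

#' Is a donor 6-mer the strong consensus?
#'
#' TRUE iff the 6-mer at intron positions +1..+6 is GTAAGT or GTGAGT.
#' Ambiguous bases (N) never match.
#'
#' @param donor6 character vector of 6-mers.
#' @return logical vector.
#' @export
donorIsConsensus <- function(donor6) donor6 %in% CANONICAL_DONORS

#' Is an acceptor 3-mer the strong consensus?
#'
#' TRUE iff the 3-mer at intron positions -3..-1 is CAG.
#'
#' @param acceptor3 character vector of 3-mers.
#' @return logical vector.
#' @export
acceptorIsConsensus <- function(acceptor3) acceptor3 == "CAG"

#' Number of distinct donor motifs in a sample
#'
#' @param donor6 character vector of donor 6-mers (non-empty).
#' @return integer count of distinct motifs.
#' @export
motifDiversity <- function(donor6) {
  if (!length(donor6)) stop("sample must be non-empty")
  length(unique(donor6))
}

statValue <- function(statistic, donor6, acceptor3) {
  switch(statistic,
         donor_consensus_frac = mean(donorIsConsensus(donor6)),
         acceptor_consensus_frac = mean(acceptorIsConsensus(acceptor3)),
         distinct_donor_motifs = motifDiversity(donor6),
         stop("unknown statistic: ", statistic))
}

#' Percentile-bootstrap comparison of a focal intron set against a reference
#'
#' Draws `B` samples of size `focalN` with replacement from the reference
#' introns, computes the statistic on each, and reports the 2.5th/97.5th
#' percentile interval (empirical quantiles with linear interpolation). The
#' focal set is significantly different when its observed statistic falls
#' outside that interval. Optionally the focal set is resampled too, which
#' indicates the variance within the focal set but is not required for the
#' significance call.
#'
#' @param reference,focal data.frames with columns `donor6` and `acceptor3`
#'   (or character vectors of donor 6-mers for the donor statistics). The
#'   reference should exclude the focal introns.
#' @param statistic one of `"donor_consensus_frac"`,
#'   `"acceptor_consensus_frac"`, `"distinct_donor_motifs"`.
#' @param B bootstrap replicates (>= 100).
#' @param seed integer seed; results are deterministic given the seed.
#' @param focalN resample size; defaults to the focal set size.
#' @param resampleFocal also bootstrap the focal set.
#' @return a [BootstrapSummary-class].
#' @export
bootstrapStatistic <- function(reference, focal, statistic, B = 10000L,
                               seed = 1L, focalN = NULL,
                               resampleFocal = FALSE) {
  getCols <- function(x) {
    if (is.data.frame(x)) list(d = x$donor6, a = x$acceptor3)
    else list(d = x, a = x)
  }
  ref <- getCols(reference); foc <- getCols(focal)
  nRef <- length(ref$d)
  if (nRef < 1L) stop("reference set must be non-empty")
  if (is.null(focalN)) focalN <- length(foc$d)
  focalN <- as.integer(focalN)
  if (focalN < 1L) stop("focalN must be >= 1")
  B <- as.integer(B)
  if (B < 100L) stop("B must be >= 100")

  obsFocal <- statValue(statistic, foc$d, foc$a)
  obsRef <- statValue(statistic, ref$d, ref$a)

  resample <- function(d, a, n) {
    idx <- matrix(sample.int(length(d), B * focalN, replace = TRUE), nrow = B)
    if (statistic == "donor_consensus_frac") {
      isC <- donorIsConsensus(d)
      rowMeans(matrix(isC[idx], nrow = B))
    } else if (statistic == "acceptor_consensus_frac") {
      isC <- acceptorIsConsensus(a)
      rowMeans(matrix(isC[idx], nrow = B))
    } else {
      codes <- as.integer(factor(d))
      m <- matrix(codes[idx], nrow = B)
      apply(m, 1L, function(r) length(unique(r)))
    }
  }

  withr::with_seed(as.integer(seed), {
    stats <- resample(ref$d, ref$a)
    ci <- unname(quantile(stats, c(0.025, 0.975), type = 7))
    if (resampleFocal) {
      fstats <- resample(foc$d, foc$a)
      fci <- unname(quantile(fstats, c(0.025, 0.975), type = 7))
    } else fci <- c(NA_real_, NA_real_)
  })

  new("BootstrapSummary", statistic = statistic, observedFocal = obsFocal,
      observedReference = obsRef, B = B, ciLow = ci[1], ciHigh = ci[2],
      significant = obsFocal < ci[1] || obsFocal > ci[2],
      focalCiLow = fci[1], focalCiHigh = fci[2],
      seed = as.integer(seed), focalN = focalN)
}

setMethod("show", "BootstrapSummary", function(object) {
  cat("BootstrapSummary:", object@statistic, "\n")
  cat(sprintf("  focal %.4g vs reference %.4g; 95%% CI [%.4g, %.4g] (B=%d)\n",
              object@observedFocal, object@observedReference, object@ciLow,
              object@ciHigh, object@B))
  cat("  significant:", object@significant, " seed:", object@seed, "\n")
})

#' Flatten BootstrapSummary objects to a TSV-ready data.frame
#' @param summaries list of [BootstrapSummary-class] objects (or one).
#' @return data.frame, one row per summary.
#' @export
bootstrapTable <- function(summaries) {
  if (is(summaries, "BootstrapSummary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) data.frame(
    statistic = s@statistic, observed_focal = s@observedFocal,
    observed_reference = s@observedReference, ci_low = s@ciLow,
    ci_high = s@ciHigh, significant = s@significant, B = s@B, seed = s@seed,
    stringsAsFactors = FALSE)))
}
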