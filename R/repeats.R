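## Direct repeats linking the two splice junctions of an intron.
##
## Dotplot-style seed-and-extend: exact word-length matches between the
## 5'-junction window and the 3'-junction window are chained per diagonal and
## extended while the total number of mismatches stays within budget. With
## maxMismatches = 0 the hit set equals the exact-match dotplot (window 8,
## mismatch 0); mismatch-tolerant extension reports identities such as 16/18.

#' Find direct repeats spanning the splice junctions of an intron
#'
#' Window A covers `flank` bp on each side of the 5' splice site and window B
#' `flank` bp on each side of the 3' splice site. All exact `word`-length
#' matches between the windows are seeds; seeds on one diagonal are merged
#' and extended into the inclusion-maximal gapless segment pairs containing
#' an exact `word`-run with at most `maxMismatches` mismatches, trimmed to
#' start and end on a match. Only direct (same-strand) repeats are searched.
#'
#' When the intron is shorter than the two windows require, both windows are
#' truncated at the intron midpoint (attribute `truncated` is set).
#'
#' @param sequence character; region containing the intron and at least
#'   `flank` bp of flanking exon on each side (coordinates refer to this
#'   string).
#' @param intronStart,intronEnd 1-based inclusive positions of the first and
#'   last intron base within `sequence`.
#' @param flank window half-width in bp.
#' @param word seed word size (>= 4).
#' @param maxMismatches mismatch budget for extension (0 = exact dotplot).
#' @return data.frame of hits sorted by matches (desc), span (desc), then
#'   leftmost: columns `copy_a_start`, `copy_a_end`, `copy_b_start`,
#'   `copy_b_end` (1-based inclusive), `matches`, `span`, `identity`
#'   (e.g. "16/18"), `overlaps_5ss` (copy A covers the first intron base),
#'   `overlaps_3ss` (copy B covers the first base after the intron).
#' @export
findJunctionRepeats <- function(sequence, intronStart, intronEnd, flank = 50L,
                                word = 8L, maxMismatches = 2L) {
  stopifnot(word >= 4L, maxMismatches >= 0L, intronEnd >= intronStart)
  n <- nchar(sequence)
  s <- as.integer(intronStart); e <- as.integer(intronEnd)
  if (s < 1L || e > n) stop("intron coordinates outside sequence")
  len <- e - s + 1L

  aLo <- max(1L, s - flank); aHi <- min(n, s + flank - 1L)
  bLo <- max(1L, e - flank + 1L); bHi <- min(n, e + flank)
  truncated <- FALSE
  if (aHi >= bLo) {            # intron shorter than the windows: split at mid
    mid <- s + len %/% 2L - 1L
    aHi <- min(aHi, mid)
    bLo <- max(bLo, mid + 1L)
    truncated <- TRUE
  }
  sv <- chars(sequence)

  hits <- list()
  for (d in (bLo - aHi):(bHi - aLo)) {
    a0 <- max(aLo, bLo - d); a1 <- min(aHi, bHi - d)
    m <- a1 - a0 + 1L
    if (m < word) next
    match <- sv[a0:a1] == sv[(a0 + d):(a1 + d)]
    r <- rle(match)
    runs <- r$lengths[r$values]
    if (!length(runs) || max(runs) < word) next   # no seed on this diagonal

    mis <- which(!match)
    k <- maxMismatches
    if (length(mis) <= k) {
      cand <- matrix(c(1L, m), ncol = 2L)
    } else {
      nm <- length(mis)
      js <- 0:(nm - k)
      lo <- ifelse(js == 0L, 1L, mis[pmax(js, 1L)] + 1L)
      lo[js == 0L] <- 1L
      hi <- ifelse(js + k + 1L > nm, m, mis[pmin(js + k + 1L, nm)] - 1L)
      hi[js + k + 1L > nm] <- m
      cand <- cbind(lo, hi)
    }
    iv <- list()
    for (ci in seq_len(nrow(cand))) {
      st <- cand[ci, 1]; en <- cand[ci, 2]
      while (st <= en && !match[st]) st <- st + 1L
      while (en >= st && !match[en]) en <- en - 1L
      if (en - st + 1L < word) next
      seg <- match[st:en]
      rr <- rle(seg)
      if (max(rr$lengths[rr$values]) < word) next
      iv[[length(iv) + 1L]] <- c(st, en, sum(seg))
    }
    if (!length(iv)) next
    ivm <- unique(do.call(rbind, iv))
    ## containment filter within the diagonal
    keep <- rep(TRUE, nrow(ivm))
    if (nrow(ivm) > 1L) {
      for (i in seq_len(nrow(ivm))) {
        for (j in seq_len(nrow(ivm))) {
          if (i != j && ivm[j, 1] <= ivm[i, 1] && ivm[j, 2] >= ivm[i, 2] &&
              (ivm[j, 2] - ivm[j, 1]) > (ivm[i, 2] - ivm[i, 1]))
            keep[i] <- FALSE
        }
      }
    }
    ivm <- ivm[keep, , drop = FALSE]
    for (ci in seq_len(nrow(ivm))) {
      aS <- a0 + ivm[ci, 1] - 1L
      aE <- a0 + ivm[ci, 2] - 1L
      hits[[length(hits) + 1L]] <- data.frame(
        copy_a_start = aS, copy_a_end = aE,
        copy_b_start = aS + d, copy_b_end = aE + d,
        matches = ivm[ci, 3], span = aE - aS + 1L,
        stringsAsFactors = FALSE)
    }
  }

  if (!length(hits)) {
    out <- data.frame(copy_a_start = integer(0), copy_a_end = integer(0),
                      copy_b_start = integer(0), copy_b_end = integer(0),
                      matches = integer(0), span = integer(0),
                      identity = character(0), overlaps_5ss = logical(0),
                      overlaps_3ss = logical(0), stringsAsFactors = FALSE)
    attr(out, "truncated") <- truncated
    return(out)
  }
  out <- do.call(rbind, hits)
  out$identity <- paste0(out$matches, "/", out$span)
  out$overlaps_5ss <- out$copy_a_start <= s & s <= out$copy_a_end
  out$overlaps_3ss <- out$copy_b_start <= e + 1L & e + 1L <= out$copy_b_end
  out <- out[order(-out$matches, -out$span, out$copy_a_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truncated") <- truncated
  out
}
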