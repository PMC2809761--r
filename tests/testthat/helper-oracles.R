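## Independent oracles used to validate the package's algorithms. These are
## deliberately written as brute force / direct translation, sharing no code
## with the implementation paths they check.

STOPS <- c("TAA", "TAG", "TGA")

## --- Dollo: exhaustive minimum over all single-gain placements -------------
## Returns a vector indexed by presence bitmask (bit i = tip i present)
## giving the minimal number of loss edges over all placements of a single
## gain compatible with the pattern.
dolloOracleTable <- function(tree) {
  nTip <- ape::Ntip(tree)
  nNode <- nTip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tipMask <- integer(nNode)
  fill <- function(nd) {
    if (nd <= nTip) {
      tipMask[nd] <<- bitwShiftL(1L, nd - 1L)
    } else {
      m <- 0L
      for (ch in kids[[as.character(nd)]]) {
        fill(ch)
        m <- bitwOr(m, tipMask[ch])
      }
      tipMask[nd] <<- m
    }
  }
  fill(nTip + 1L)
  subtreeNodes <- function(g) {
    out <- g
    frontier <- g
    while (length(frontier)) {
      nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
      out <- c(out, nxt)
      frontier <- nxt[nxt > nTip]
    }
    out
  }
  best <- rep(Inf, bitwShiftL(1L, nTip) - 1L)
  for (g in seq_len(nNode)) {
    below <- setdiff(subtreeNodes(g), g)   # loss edges = child nodes below g
    m <- length(below)
    u <- integer(bitwShiftL(1L, m))
    pc <- integer(bitwShiftL(1L, m))
    for (i in seq_len(m)) {
      half <- bitwShiftL(1L, i - 1L)
      idx <- seq_len(half)
      u[idx + half] <- bitwOr(u[idx], tipMask[below[i]])
      pc[idx + half] <- pc[idx] + 1L
    }
    res <- bitwAnd(tipMask[g], bitwNot(u))
    keep <- res > 0L
    if (!any(keep)) next
    agg <- tapply(pc[keep], res[keep], min)
    pat <- as.integer(names(agg))
    imp <- agg < best[pat]
    best[pat[imp]] <- agg[imp]
  }
  best
}

presenceMask <- function(tree, presentSpecies) {
  sum(bitwShiftL(1L, match(presentSpecies, tree$tip.label) - 1L))
}

## random rooted binary tree with branch lengths and node labels
randomLabelledTree <- function(nLeaves) {
  tr <- ape::rtree(nLeaves, rooted = TRUE)
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}

## --- PTC: direct-translation oracle ----------------------------------------
## flank5 must end at the intron with `phase` coding nt of the interrupted
## codon, i.e. nchar(flank5) %% 3 == phase, so the exonic frame tiles the
## concatenation from position 1.
ptcOracle <- function(intronSeq, phase, flank5, flank3,
                      includeBoundary = FALSE) {
  stopifnot(nchar(flank5) %% 3L == phase)
  full <- paste0(flank5, intronSeq, flank3)
  L5 <- nchar(flank5)
  len <- nchar(intronSeq)
  starts <- seq(1L, nchar(full) - 2L, by = 3L)
  codons <- substring(full, starts, starts + 2L)
  stops <- starts[codons %in% STOPS]
  sel <- if (includeBoundary)
    stops[stops + 2L >= L5 + 1L & stops <= L5 + len]
  else
    stops[stops >= L5 + 1L & stops + 2L <= L5 + len]
  if (!length(sel)) list(has_ptc = FALSE, first_ptc_offset = NA_integer_)
  else list(has_ptc = TRUE, first_ptc_offset = sel[1] - (L5 + 1L))
}

## --- Junction repeats: brute force over all substring pairs ----------------
## Enumerates every gapless segment pair between the two windows, keeps the
## valid ones (<= maxMismatches mismatches, match at both ends, an exact run
## >= word) and filters to inclusion-maximal per diagonal.
repeatOracle <- function(sequence, intronStart, intronEnd, flank = 50L,
                         word = 8L, maxMismatches = 0L) {
  n <- nchar(sequence)
  s <- intronStart; e <- intronEnd
  len <- e - s + 1L
  aLo <- max(1L, s - flank); aHi <- min(n, s + flank - 1L)
  bLo <- max(1L, e - flank + 1L); bHi <- min(n, e + flank)
  if (aHi >= bLo) {
    mid <- s + len %/% 2L - 1L
    aHi <- min(aHi, mid); bLo <- max(bLo, mid + 1L)
  }
  sv <- strsplit(sequence, "")[[1]]
  hits <- list()
  for (d in (bLo - aHi):(bHi - aLo)) {
    a0 <- max(aLo, bLo - d); a1 <- min(aHi, bHi - d)
    m <- a1 - a0 + 1L
    if (m < word) next
    mt <- sv[a0:a1] == sv[(a0 + d):(a1 + d)]
    r <- rle(mt); runs <- r$lengths[r$values]
    if (!length(runs) || max(runs) < word) next
    valid <- list()
    for (i in seq_len(m)) {
      if (!mt[i]) next
      mism <- 0L; run <- 0L; maxrun <- 0L
      for (j in i:m) {
        if (mt[j]) { run <- run + 1L; maxrun <- max(maxrun, run) }
        else { mism <- mism + 1L; run <- 0L; if (mism > maxMismatches) break }
        if (mt[j] && j - i + 1L >= word && maxrun >= word)
          valid[[length(valid) + 1L]] <- c(i, j, j - i + 1L - mism)
      }
    }
    if (!length(valid)) next
    vm <- unique(do.call(rbind, valid))
    keep <- rep(TRUE, nrow(vm))
    for (i in seq_len(nrow(vm))) for (j in seq_len(nrow(vm)))
      if (i != j && vm[j, 1] <= vm[i, 1] && vm[j, 2] >= vm[i, 2] &&
          (vm[j, 2] - vm[j, 1]) > (vm[i, 2] - vm[i, 1])) keep[i] <- FALSE
    vm <- vm[keep, , drop = FALSE]
    for (i in seq_len(nrow(vm))) {
      aS <- a0 + vm[i, 1] - 1L; aE <- a0 + vm[i, 2] - 1L
      hits[[length(hits) + 1L]] <- data.frame(
        copy_a_start = aS, copy_a_end = aE, copy_b_start = aS + d,
        copy_b_end = aE + d, matches = vm[i, 3], span = aE - aS + 1L)
    }
  }
  if (!length(hits))
    return(data.frame(copy_a_start = integer(0), copy_a_end = integer(0),
                      copy_b_start = integer(0), copy_b_end = integer(0),
                      matches = integer(0), span = integer(0)))
  out <- do.call(rbind, hits)
  out[order(-out$matches, -out$span, out$copy_a_start), , drop = FALSE]
}

randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
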