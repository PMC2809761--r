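## Direct repeats linking the splice junctions: seed-and-extend vs brute force.

## constructed region: 50 nt exon | intron | 50 nt exon
makeRegion <- function(intron, exon5 = NULL, exon3 = NULL) {
  if (is.null(exon5)) exon5 <- randomDnaStr(50)
  if (is.null(exon3)) exon3 <- randomDnaStr(50)
  list(seq = paste0(exon5, intron, exon3),
       s = nchar(exon5) + 1L, e = nchar(exon5) + nchar(intron))
}

test_that("a planted perfect repeat covering both junctions is found", {
  set.seed(91)
  ## copy A: last 4 exon nt + first 6 intron nt; copy B: last 8 intron nt +
  ## first 2 exon nt -- both copies identical, both junction flags must set
  exon5 <- paste0(randomDnaStr(46), "TTCA")
  copy <- paste0("TTCA", "GTAAGT")            # 10-mer spanning the 5' site
  intronCore <- randomDnaStr(40)
  exon3 <- paste0("GT", randomDnaStr(48))
  intron <- paste0("GTAAGT", substr(intronCore, 1, 34), "TTCAGTAA", "AG")
  ## make intron end + exon start reproduce the copy: last 8 intron = TTCAGTAA+AG?
  ## simpler: build directly so that seq[s-4..s+5] == seq[e-7..e+2]
  intron <- paste0("GTAAGT", intronCore, "TTCAGTAA")
  reg <- makeRegion(intron, exon5, exon3)
  ## copyA = positions s-4..s+5 = "TTCAGTAAGT"; copyB = e-7..e+2 = "TTCAGTAAGT"
  expect_equal(substr(reg$seq, reg$s - 4, reg$s + 5),
               substr(reg$seq, reg$e - 7, reg$e + 2))
  hits <- findJunctionRepeats(reg$seq, reg$s, reg$e, flank = 50, word = 8,
                              maxMismatches = 0)
  top <- hits[1, ]
  expect_gte(top$matches, 10L)
  expect_true(top$overlaps_5ss)
  expect_true(top$overlaps_3ss)
  expect_equal(top$matches, top$span)
})

test_that("mismatch extension reports composite identities like 16/18", {
  set.seed(92)
  ## two 18-mers differing at 2 positions, one at each junction
  ## mismatches at positions 3 and 12 leave an exact 8-run (4..11) as seed
  core <- randomDnaStr(18)
  mut <- core
  substr(mut, 3, 3) <- if (substr(core, 3, 3) == "A") "C" else "A"
  substr(mut, 12, 12) <- if (substr(core, 12, 12) == "G") "T" else "G"
  exon5 <- paste0(randomDnaStr(38), substr(core, 1, 8))
  intron <- paste0(substr(core, 9, 18), randomDnaStr(30),
                   substr(mut, 1, 14))
  exon3 <- paste0(substr(mut, 15, 18), randomDnaStr(46))
  reg <- makeRegion(intron, exon5, exon3)
  hits <- findJunctionRepeats(reg$seq, reg$s, reg$e, flank = 50, word = 8,
                              maxMismatches = 2)
  top <- hits[1, ]
  expect_equal(top$span, 18L)
  expect_equal(top$matches, 16L)
  expect_equal(top$identity, "16/18")
  expect_true(top$overlaps_5ss)
  expect_true(top$overlaps_3ss)
  ## exact mode only finds the sub-words
  hits0 <- findJunctionRepeats(reg$seq, reg$s, reg$e, flank = 50, word = 8,
                               maxMismatches = 0)
  expect_true(all(hits0$matches == hits0$span))
  expect_lt(max(hits0$span), 18L)
})

test_that("random sequences rarely contain word-8 junction repeats", {
  set.seed(93)
  nHits <- vapply(1:50, function(i) {
    reg <- makeRegion(randomDnaStr(60))
    nrow(findJunctionRepeats(reg$seq, reg$s, reg$e, word = 8,
                             maxMismatches = 0))
  }, numeric(1))
  expect_lt(mean(nHits > 0), 0.30)
})

test_that("hits equal the brute-force oracle on random windows", {
  set.seed(94)
  cols <- c("copy_a_start", "copy_a_end", "copy_b_start", "copy_b_end",
            "matches", "span")
  for (i in 1:60) {
    intronLen <- sample(c(46, 60, 150, 200), 1)
    reg <- makeRegion(randomDnaStr(intronLen))
    ## plant a degraded repeat in half the cases so hits exist
    if (i %% 2 == 0) {
      w <- randomDnaStr(12)
      substr(reg$seq, reg$s - 6, reg$s + 5) <- w
      if (i %% 4 == 0) substr(w, 6, 6) <- "A"
      substr(reg$seq, reg$e - 5, reg$e + 6) <- w
    }
    for (k in c(0L, 2L)) {
      got <- findJunctionRepeats(reg$seq, reg$s, reg$e, flank = 50,
                                 word = 8, maxMismatches = k)
      want <- repeatOracle(reg$seq, reg$s, reg$e, flank = 50, word = 8,
                           maxMismatches = k)
      expect_equal(nrow(got), nrow(want), info = paste("case", i, "k", k))
      if (nrow(got)) {
        g <- got[do.call(order, got[cols]), cols]
        w2 <- want[do.call(order, want[cols]), cols]
        rownames(g) <- rownames(w2) <- NULL
        expect_equal(g, w2, info = paste("case", i, "k", k))
      }
    }
  }
})

test_that("reverse-complementing the region mirrors the hit set", {
  set.seed(95)
  for (i in 1:10) {
    reg <- makeRegion(randomDnaStr(80))
    w <- randomDnaStr(10)
    substr(reg$seq, reg$s - 4, reg$s + 5) <- w
    substr(reg$seq, reg$e - 7, reg$e + 2) <- w
    fwd <- findJunctionRepeats(reg$seq, reg$s, reg$e, maxMismatches = 0)
    n <- nchar(reg$seq)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(reg$seq)))
    rev <- findJunctionRepeats(rc, n - reg$e + 1L, n - reg$s + 1L,
                               maxMismatches = 0)
    expect_equal(nrow(fwd), nrow(rev))
    ## mirrored coordinates: copy A of one strand is copy B of the other
    mirA <- sort(n - fwd$copy_b_end + 1L)
    expect_equal(sort(rev$copy_a_start), mirA)
    expect_equal(sort(fwd$matches), sort(rev$matches))
  }
})

test_that("introns shorter than the windows are truncated at the midpoint", {
  set.seed(96)
  reg <- makeRegion(randomDnaStr(46))   # < 2 * flank: windows would overlap
  hits <- findJunctionRepeats(reg$seq, reg$s, reg$e, flank = 50)
  expect_true(attr(hits, "truncated"))
  reg2 <- makeRegion(randomDnaStr(150))
  hits2 <- findJunctionRepeats(reg2$seq, reg2$s, reg2$e, flank = 50)
  expect_false(attr(hits2, "truncated"))
})
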