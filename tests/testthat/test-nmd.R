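## Retention-frame arithmetic, PTC scanning, and the logistic PTC model.

test_that("retention frame offset is (3 - phase) mod 3", {
  expect_equal(retentionFrameOffset(0), 0L)
  expect_equal(retentionFrameOffset(1), 2L)
  expect_equal(retentionFrameOffset(2), 1L)
  expect_equal(retentionFrameOffset(c(0, 1, 2)), c(0L, 2L, 1L))
  expect_error(retentionFrameOffset(3))
})

test_that("canonical phase-2 donors force a PTC at intron offset 1", {
  ## GT(A/G)AGT under phase 2: first full internal codon is TAA or TGA
  r <- scanPTC("GTAAGTTTTCC", phase = 2)
  expect_true(r$has_ptc)
  expect_equal(r$first_ptc_offset, 1L)
  r2 <- scanPTC("GTGAGTTTTCC", phase = 2)
  expect_equal(r2$first_ptc_offset, 1L)

  ## direct read-off, phase 0: PTC at offset 3 (TGA), 3n length, visible
  r3 <- scanPTC("GTATGAAGCCAG", phase = 0)
  expect_equal(r3$first_ptc_offset, 3L)
  expect_true(r3$is_3n)
  expect_true(r3$nmd_visible)

  ## stop-free 3n intron: invisible to NMD
  r4 <- scanPTC("GTACCCCCCAAG", phase = 0)
  expect_false(r4$has_ptc)
  expect_false(r4$nmd_visible)

  ## ambiguous codon skipped and counted
  r5 <- scanPTC("GTNAGTCCCCC", phase = 2)
  expect_gte(r5$n_ambiguous_skipped, 1L)
})

test_that("nmd visibility is monotone in frame shift", {
  ## appending 1 nt to a 3n PTC-free intron makes it NMD-visible
  seq3n <- "GTACCCCCCAAG"
  expect_false(scanPTC(seq3n, 0)$nmd_visible)
  expect_true(scanPTC(paste0(seq3n, "C"), 0)$nmd_visible)
})

test_that("scanPTC agrees with the direct-translation oracle", {
  set.seed(81)
  for (i in 1:800) {
    phase <- sample(0:2, 1)
    len <- sample(10:80, 1)
    intron <- randomDnaStr(len)
    f5 <- randomDnaStr(3 * sample(2:4, 1) + phase)
    f3 <- randomDnaStr(9)
    for (boundary in c(FALSE, TRUE)) {
      got <- scanPTC(intron, phase, f5, f3, includeBoundary = boundary)
      want <- ptcOracle(intron, phase, f5, f3, includeBoundary = boundary)
      expect_identical(got$has_ptc, want$has_ptc,
                       info = paste(i, phase, boundary, intron))
      expect_identical(got$first_ptc_offset, want$first_ptc_offset,
                       info = paste(i, phase, boundary, intron))
    }
  }
})

test_that("phase-2 canonical-donor stop constraint reports 1.0", {
  set.seed(82)
  tab <- data.frame(
    seq = vapply(1:50, function(i)
      paste0(sample(c("GTAAGT", "GTGAGT"), 1), randomDnaStr(40)),
      character(1)),
    phase = 2L, stringsAsFactors = FALSE)
  tab$donor6 <- substr(tab$seq, 1, 6)
  expect_equal(phaseStopConstraint(tab, phase = 2, canonicalDonorOnly = TRUE),
               1.0)
  ## phase-0 canonical introns with stop-free tails: 0.0
  tab0 <- data.frame(seq = paste0("GTAAGT", strrep("CCC", 10), "CAG"),
                     phase = 0L, stringsAsFactors = FALSE)
  tab0$donor6 <- substr(tab0$seq, 1, 6)
  expect_equal(phaseStopConstraint(tab0, phase = 0,
                                   canonicalDonorOnly = TRUE), 0.0)
})

test_that("annotateNMD matches direct per-intron recount", {
  set.seed(83)
  tab <- data.frame(seq = vapply(1:100, function(i)
    randomDnaStr(sample(45:90, 1)), character(1)),
    phase = sample(0:2, 100, replace = TRUE), stringsAsFactors = FALSE)
  ann <- annotateNMD(tab)
  direct <- vapply(seq_len(nrow(tab)), function(i)
    scanPTC(tab$seq[i], tab$phase[i])$has_ptc, logical(1))
  expect_equal(ann$has_ptc, direct)
  expect_equal(mean(ann$has_ptc), phaseStopConstraint(tab))
})

test_that("the logistic model recovers designed odds ratios", {
  tab <- simulatePtcTable(nNovel = 307, nConserved = 8810, orNovel = 3.0,
                          orConserved = 1.6, seed = 84)
  fit <- fitPTCModel(tab)
  expect_false(fit$separation)
  cs <- fit$contrasts
  novel <- cs[cs$contrast == "novel_3n_vs_non3n", ]
  cons <- cs[cs$contrast == "conserved_3n_vs_non3n", ]
  expect_gt(novel$ci_high, 3.0); expect_lt(novel$ci_low, 3.0)
  expect_gt(cons$ci_high, 1.6); expect_lt(cons$ci_low, 1.6)
  ## ratio-of-odds-ratios contrast is consistent with the two components
  ratio <- cs[cs$contrast == "novel_vs_conserved", ]
  expect_equal(ratio$odds_ratio, novel$odds_ratio / cons$odds_ratio,
               tolerance = 1e-8)
  expect_gt(fit$pseudoR2, 0)
  expect_true(all(cs$ci_low < cs$odds_ratio & cs$odds_ratio < cs$ci_high))
  ## phase should dominate: strong phase-2 coefficient designed in
  expect_true(!is.null(fit$waldTests))
})

test_that("constant outcome exercises the separation path", {
  tab <- simulatePtcTable(nNovel = 100, nConserved = 400, seed = 85)
  tab$has_ptc <- TRUE
  expect_warning(fit <- fitPTCModel(tab), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$contrasts$odds_ratio)))
})
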