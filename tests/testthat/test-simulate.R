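## The turnover simulator: determinism, sequence model, planted structure.

test_that("identical seeds give byte-identical emitted files", {
  p <- simulationParams(nGenes = 12L, seed = 42L, pPlantedRepeat = 0.2,
                        pLargeInsertion = 0.1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateTurnover(p), d1)
  writeSimulation(simulateTurnover(p), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  ## different seed changes the data
  p2 <- simulationParams(nGenes = 12L, seed = 43L)
  d3 <- withr::local_tempdir()
  writeSimulation(simulateTurnover(p2), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "truth_sites.tsv"))),
    unname(tools::md5sum(file.path(d3, "truth_sites.tsv")))))
})

test_that("zero rates give identical structures everywhere and no events", {
  p <- simulationParams(nGenes = 8L, gainRate = 0, lossRate = 0,
                        pLargeInsertion = 0, pCodingChange = 0, seed = 2L)
  sim <- simulateTurnover(p)
  expect_equal(nrow(truthEvents(sim)), 0L)
  expect_true(all(sim$truth$sites$gain_branch == "ROOT"))
  expect_true(all(sim$truth$sites$n_present == 9L))
  sps <- names(sim$models)
  for (g in names(sim$models[[1]])) {
    ref <- introns(sim$models[[sps[1]]][[g]])[, c("index", "phase", "seq",
                                                  "cds_offset")]
    for (sp in sps[-1])
      expect_equal(introns(sim$models[[sp]][[g]])[, c("index", "phase",
                                                      "seq", "cds_offset")],
                   ref, info = paste(g, sp))
  }
})

test_that("drawn intron sequences obey the motif and length model", {
  p <- simulationParams(pCanonicalDonor = 1, pCanonicalAcceptor = 1)
  withr::with_seed(11, {
    for (i in 1:50) {
      s <- drawIntronSequence(p, sample(0:2, 1), want3n = i %% 2 == 0)
      expect_gte(nchar(s), 45L)
      expect_equal(substr(s, 1, 2), "GT")
      expect_equal(substr(s, nchar(s) - 1, nchar(s)), "AG")
      expect_true(substr(s, 1, 6) %in% c("GTAAGT", "GTGAGT"))
      expect_equal(substr(s, nchar(s) - 2, nchar(s)), "CAG")
      expect_equal(nchar(s) %% 3 == 0, i %% 2 == 0)
    }
  })
  ## empirical canonical-donor fraction within 3 SE of the target
  p7 <- simulationParams(pCanonicalDonor = 0.7)
  frac <- withr::with_seed(12, {
    mean(vapply(1:10000, function(i)
      donorIsConsensus(substr(drawIntronSequence(p7, 0, TRUE), 1, 6)),
      logical(1)))
  })
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
})

test_that("retention-frame stop density tracks ptcDensity", {
  pHi <- simulationParams(ptcDensity = 0.3)
  pLo <- simulationParams(ptcDensity = 0)
  nHi <- withr::with_seed(13, mean(vapply(1:300, function(i)
    scanPTC(drawIntronSequence(pHi, 0, TRUE), 0)$has_ptc, logical(1))))
  nLo <- withr::with_seed(14, mean(vapply(1:300, function(i)
    scanPTC(drawIntronSequence(pLo, 0, TRUE), 0)$has_ptc, logical(1))))
  expect_gt(nHi, nLo + 0.2)
})

test_that("planted repeats are perfect, junction-spanning, and recoverable", {
  p <- simulationParams(nGenes = 15L, pPlantedRepeat = 1, seed = 21L,
                        pCodingChange = 0, pLargeInsertion = 0)
  sim <- simulateTurnover(p)
  tr <- sim$truth$sites
  planted <- tr[tr$planted_repeat, ]
  expect_gt(nrow(planted), 10)
  for (i in seq_len(min(nrow(planted), 25))) {
    row <- planted[i, ]
    pres <- strsplit(row$presence, "")[[1]] == "1"
    carrier <- names(sim$models)[pres][1]
    gm <- sim$models[[carrier]][[row$group]]
    it <- introns(gm)
    it <- it[it$cds_offset == row$ancestral_offset, ]
    expect_equal(nrow(it), 1L)
    ## locate this intron on the coding-strand contig
    ctg <- contigSequence(gm)
    if (gm@strand == "-")
      ctg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ctg)))
    hits <- findJunctionRepeats(ctg, it$start[1], it$end[1],
                                flank = 50, word = 8, maxMismatches = 0)
    expect_gt(nrow(hits), 0)
    top <- hits[1, ]
    expect_gte(top$matches, p@repeatLength)
    expect_equal(top$matches, top$span)
    expect_true(top$overlaps_5ss)
    expect_true(top$overlaps_3ss)
  }
})

test_that("rates implying over one gain per gene per branch warn", {
  p <- simulationParams(nGenes = 3L, gainRate = 200, seed = 5L)
  w <- capture_warnings(simulateTurnover(p))
  expect_true(any(grepl("expected >1 gain", w)))
})

test_that("per-branch named rates override the scalar rate", {
  ## zero everywhere except a hot melanogaster-subgroup stem
  p <- simulationParams(nGenes = 40L, gainRate = c(0, mel_subgroup = 40),
                        lossRate = 0, seed = 6L)
  sim <- simulateTurnover(p)
  ev <- truthEvents(sim)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$gain_branch == "mel_subgroup"))
})
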