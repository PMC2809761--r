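## Intron homologization: mapping, site building, coding changes, insertions.

test_that("mapIntron places the interrupted codon's residue column", {
  ## ungapped row "MKV": 6 coding nt upstream -> residue 3 -> column 3
  expect_equal(mapIntron(6, 9, 1:3), list(column = 3L, phase = 0L))
  ## one further nt: same residue's column, phase 1
  expect_equal(mapIntron(7, 9, 1:3), list(column = 3L, phase = 1L))
  ## gapped rows shift the column
  rowMap <- msaRowMap(c(r = "M--KV"))$r      # residues at columns 1, 4, 5
  expect_equal(mapIntron(3, 9, rowMap)$column, 4L)
  expect_error(mapIntron(9, 9, 1:3), "beyond CDS")
})

test_that("gapped-row mapping agrees with brute-force gap counting", {
  set.seed(111)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    gaps <- sort(sample(1:(2 * n), n))   # residue columns among 2n columns
    row <- rep("-", 2 * n)
    row[gaps] <- "M"
    rowStr <- paste(row, collapse = "")
    rm <- msaRowMap(setNames(rowStr, "r"))$r
    off <- sample(0:(3 * n - 1), 1)
    got <- mapIntron(off, 3 * n, rm)$column
    ## brute force: walk columns counting residues until the target index
    target <- off %/% 3 + 1
    seen <- 0
    for (colI in seq_len(2 * n)) {
      if (row[colI] != "-") seen <- seen + 1
      if (seen == target) break
    }
    expect_equal(got, colI)
  }
})

toyModels <- function(offsets, seqsBySpecies = NULL) {
  ## one gene "g" across species; each species gets introns at the given
  ## cds_offsets (list indexed by species) in an identical 30-codon CDS
  cds <- strrep("ATGCATCATAAACCC", 6)   # 90 nt, 30 codons, no stops
  lapply(offsets, function(offs) {
    offs <- sort(offs)
    intr <- vapply(seq_along(offs), function(i)
      paste0("GTAAGT", strrep("C", 39), "CAG"), character(1))
    cuts <- c(0, offs, nchar(cds))
    pieces <- substring(cds, head(cuts, -1) + 1, cuts[-1])
    body <- if (length(offs))
      paste0(paste0(pieces[seq_along(offs)], intr, collapse = ""),
             pieces[length(pieces)])
    else cds
    ctg <- paste0(strrep("A", 10), body, strrep("A", 10))
    pos <- 10
    ex <- matrix(0L, length(offs) + 1, 2)
    for (k in seq_along(pieces)) {
      ex[k, 1] <- pos + 1
      pos <- pos + nchar(pieces[k])
      ex[k, 2] <- pos
      if (k <= length(offs)) pos <- pos + 48
    }
    list(g = geneModelFromContig("g", "sp", "c", "+", ex, ctg))
  })
}

test_that("sites cluster by exact (column, phase) and honor slack", {
  cds30 <- Biostrings::AAStringSet(setNames(rep(strrep("M", 30), 2),
                                            c("sp1", "sp2")))
  ## both species: intron after 30 nt -> residue 11, phase 0
  models <- toyModels(list(sp1 = 30, sp2 = 30))
  sites <- buildIntronSites(models, list(g = cds30))
  st <- siteTable(sites)
  expect_equal(nrow(st), 1L)
  expect_equal(st$presence, "11")
  expect_equal(st$phase, 0L)

  ## columns 11 vs 12 with slack 0: two sites; with slack 1: one site
  models2 <- toyModels(list(sp1 = 30, sp2 = 33))
  st0 <- siteTable(buildIntronSites(models2, list(g = cds30)))
  expect_equal(nrow(st0), 2L)
  expect_setequal(st0$presence, c("10", "01"))
  st1 <- siteTable(buildIntronSites(models2, list(g = cds30), slack = 1L))
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$presence, "11")

  ## slack merging two introns of ONE gene is an annotation defect
  models3 <- toyModels(list(sp1 = c(30, 33), sp2 = 30))
  expect_error(buildIntronSites(models3, list(g = cds30), slack = 1L),
               "annotation defect")

  ## different phase never merges
  models4 <- toyModels(list(sp1 = 30, sp2 = 31))
  st4 <- siteTable(buildIntronSites(models4, list(g = cds30), slack = 2L))
  expect_equal(nrow(st4), 2L)
})

test_that("groups missing a species are dropped with a message", {
  cds30 <- Biostrings::AAStringSet(setNames(rep(strrep("M", 30), 2),
                                            c("sp1", "sp2")))
  models <- toyModels(list(sp1 = 30, sp2 = 30))
  models$sp2$g2missing <- NULL
  msas <- list(g = cds30, g2 = cds30)
  models$sp1$g2 <- models$sp1$g
  expect_message(sites <- buildIntronSites(models, msas),
                 "dropped")
  expect_equal(unique(siteTable(sites)$group), "g")
})

test_that("simulated sites are recovered 1:1 from annotations + alignments", {
  p <- simulationParams(nGenes = 60L, seed = 31L, pCodingChange = 0,
                        pLargeInsertion = 0, pPlantedRepeat = 0)
  sim <- simulateTurnover(p)
  sites <- buildIntronSites(sim$models, sim$msas, slack = 0L,
                            species = sim$tree$tip.label)
  st <- siteTable(sites)
  tr <- sim$truth$sites
  expect_equal(nrow(st), nrow(tr))
  key <- function(d, col) paste(d$group, d[[col]], d$phase, d$presence)
  expect_setequal(key(st, "column"), paste(tr$group, tr$column, tr$phase,
                                           tr$presence))
})

test_that("site recovery also holds with coding changes and insertions", {
  p <- simulationParams(nGenes = 60L, seed = 32L, pCodingChange = 0.5,
                        pLargeInsertion = 0.08, lossRate = 0)
  sim <- simulateTurnover(p)
  sites <- buildIntronSites(sim$models, sim$msas, slack = 0L,
                            species = sim$tree$tip.label)
  st <- siteTable(sites)
  tr <- sim$truth$sites
  expect_equal(nrow(st), nrow(tr))
  expect_setequal(paste(st$group, st$column, st$phase, st$presence),
                  paste(tr$group, tr$column, tr$phase, tr$presence))
})

test_that("coding-change classes are recovered at known sizes", {
  p <- simulationParams(nGenes = 80L, seed = 33L, pCodingChange = 0.6,
                        lossRate = 0, pLargeInsertion = 0,
                        pPlantedRepeat = 0)
  sim <- simulateTurnover(p)
  sites <- buildIntronSites(sim$models, sim$msas, slack = 0L,
                            species = sim$tree$tip.label)
  cc <- classifyCodingChange(sites, sim$msas)
  tr <- sim$truth$sites
  tr <- tr[tr$gain_branch != "ROOT" & tr$n_present < 9, ]
  m <- merge(cc, tr[, c("group", "column", "phase", "coding_change_aa")],
             by = c("group", "column", "phase"))
  expect_equal(nrow(m), nrow(tr))
  expect_gt(sum(m$coding_change_aa > 0), 5)
  expect_equal(m$n_aa_delta, m$coding_change_aa)
  expect_true(all(m$change_class[m$coding_change_aa == 0] == "0"))
  expect_true(all(m$change_class[m$coding_change_aa %in% 1:3] == "1-3"))
})

test_that("unspliced insertions are detected at the >=15 aa threshold", {
  ## trivial constructed case: one row with a 20-residue insertion
  base <- strrep("M", 40)
  with20 <- paste0(strrep("M", 10), strrep("W", 20), strrep("M", 30))
  aln <- Biostrings::AAStringSet(c(
    sp1 = paste0(strrep("M", 10), strrep("-", 20), strrep("M", 30)),
    sp2 = paste0(strrep("M", 10), strrep("-", 20), strrep("M", 30)),
    sp3 = with20))
  ins <- detectUnsplicedInsertions(list(g = aln))
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$species, "sp3")
  expect_equal(ins$length_aa, 20L)

  ## 14 residues (42 nt) stay below the 45 nt floor: not reported
  aln14 <- Biostrings::AAStringSet(c(
    sp1 = paste0(strrep("M", 10), strrep("-", 14), strrep("M", 30)),
    sp2 = paste0(strrep("M", 10), strrep("W", 14), strrep("M", 30))))
  expect_equal(nrow(detectUnsplicedInsertions(list(g = aln14))), 0L)

  ## simulator truth: all planted large insertions found, none invented
  p <- simulationParams(nGenes = 50L, seed = 34L, pLargeInsertion = 0.12,
                        pCodingChange = 0)
  sim <- simulateTurnover(p)
  sites <- buildIntronSites(sim$models, sim$msas, slack = 0L,
                            species = sim$tree$tip.label)
  ins2 <- detectUnsplicedInsertions(sim$msas, siteSet = sites)
  tru <- sim$truth$insertions
  expect_equal(nrow(ins2), nrow(tru))
  expect_setequal(paste(ins2$group, ins2$species, ins2$length_aa),
                  paste(tru$group, tru$species, tru$length_aa))
})

test_that("site building is invariant under species order permutation", {
  p <- simulationParams(nGenes = 25L, seed = 35L)
  sim <- simulateTurnover(p)
  s1 <- buildIntronSites(sim$models, sim$msas,
                         species = sim$tree$tip.label)
  perm <- rev(sim$tree$tip.label)
  s2 <- buildIntronSites(sim$models[perm], sim$msas, species = perm)
  expect_equal(nrow(siteTable(s1)), nrow(siteTable(s2)))
  expect_setequal(siteTable(s1)$site_id, siteTable(s2)$site_id)
})
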