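## Dollo parsimony: gain placement, loss edges, rates, oracle equivalence.

balTree <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")

test_that("gain node is the MRCA and losses are maximal absent subtrees", {
  r <- inferSiteDollo(c("A", "B"), balTree)
  expect_equal(r$gainNode, "ab")
  expect_false(r$rootAmbiguous)
  expect_length(r$lossBranches, 0L)

  ## present on both sides of the root: unclassifiable root event
  r2 <- inferSiteDollo(c("A", "C"), balTree)
  expect_true(r2$rootAmbiguous)
  expect_setequal(r2$lossBranches, c("B", "D"))

  ## single-species presence: gain on the terminal branch
  r3 <- inferSiteDollo("C", balTree)
  expect_equal(r3$gainNode, "C")
  expect_length(r3$lossBranches, 0L)

  ## sibling losses collapse to their parent edge
  tr6 <- ape::read.tree(text = "(((A:1,B:1)ab:1,(C:1,D:1)cd:1)abcd:1,(E:1,F:1)ef:1)r;")
  r4 <- inferSiteDollo(c("A", "B"), tr6)
  expect_equal(r4$gainNode, "ab")
  r5 <- inferSiteDollo(c("A", "B", "E", "F"), tr6)
  expect_true(r5$rootAmbiguous)
  expect_equal(r5$lossBranches, "cd")

  expect_error(inferSiteDollo(character(0), balTree), "all-absent")
})

test_that("loss counts equal the exhaustive single-gain minimum", {
  set.seed(61)
  for (rep in 1:10) {
    nL <- sample(4:6, 1)
    tr <- randomLabelledTree(nL)
    best <- dolloOracleTable(tr)
    for (mask in seq_len(2^nL - 1)) {
      present <- tr$tip.label[bitwAnd(mask, bitwShiftL(1L, 0:(nL - 1))) > 0]
      r <- inferSiteDollo(present, tr)
      expect_equal(length(r$lossBranches), as.integer(best[mask]),
                   info = paste("tree", rep, "mask", mask))
    }
  }
})

test_that("leaf relabeling permutes but does not change event multisets", {
  set.seed(62)
  tr <- randomLabelledTree(6)
  perm <- sample(tr$tip.label)
  tr2 <- tr
  tr2$tip.label <- perm[match(tr$tip.label, sort(tr$tip.label))]
  ## apply the same relabeling map to the presence sets
  relab <- setNames(tr2$tip.label, tr$tip.label)
  for (mask in sample(seq_len(63), 20)) {
    present <- tr$tip.label[bitwAnd(mask, bitwShiftL(1L, 0:5)) > 0]
    a <- inferSiteDollo(present, tr)
    b <- inferSiteDollo(unname(relab[present]), tr2)
    expect_equal(length(a$lossBranches), length(b$lossBranches))
    expect_equal(a$rootAmbiguous, b$rootAmbiguous)
  }
})

test_that("per-branch rates follow events / genes / (My / 1000)", {
  ## 10 gains on a 10 My branch over 1,000 genes -> 1.0 gains/gene/Bya
  tr <- ape::read.tree(text = "((A:10,B:10)ab:10,C:20)r;")
  sites <- data.frame(
    site_id = sprintf("s%02d", 1:10), group = sprintf("G%02d", 1:10),
    column = 1:10, phase = 0L, presence = rep("110", 10),
    stringsAsFactors = FALSE)
  recon <- reconstructEvents(sites, tr, nGenes = 1000,
                             species = c("A", "B", "C"))
  br <- branchRates(recon)
  expect_equal(br$n_gains[br$branch == "ab"], 10L)
  expect_equal(br$gain_rate[br$branch == "ab"], 1.0)
  expect_equal(sum(br$n_losses[br$branch != "TOTAL"]), 0L)
  expect_equal(rootAmbiguousCount(recon), 0L)

  ## no gains anywhere -> all gain rates zero
  sites2 <- data.frame(site_id = "s1", group = "G1", column = 1L, phase = 0L,
                       presence = "111", stringsAsFactors = FALSE)
  recon2 <- reconstructEvents(sites2, tr, nGenes = 10,
                              species = c("A", "B", "C"))
  expect_true(all(branchRates(recon2)$gain_rate == 0))
  expect_equal(rootAmbiguousCount(recon2), 1L)

  ## zero-length branch with events -> Inf rate with warning
  tr0 <- ape::read.tree(text = "((A:0,B:10)ab:10,C:20)r;")
  sites3 <- data.frame(site_id = "s1", group = "G1", column = 1L, phase = 0L,
                       presence = "100", stringsAsFactors = FALSE)
  expect_warning(recon3 <- reconstructEvents(sites3, tr0, nGenes = 10,
                                             species = c("A", "B", "C")),
                 "Inf")
  br3 <- branchRates(recon3)
  expect_true(is.infinite(br3$gain_rate[br3$branch == "A"]))
})

test_that("groups with both gain and loss are identified", {
  tr <- balTree
  sites <- data.frame(
    site_id = c("s1", "s2", "s3", "s4"),
    group = c("G1", "G2", "G2", "G3"),
    column = c(5L, 5L, 9L, 5L), phase = 0L,
    presence = c("1100",   # G1: gain on ab, no loss -> excluded
                 "1110",   # G2 ancestral, lost in D
                 "0011",   # G2 gain on cd
                 "1111"),  # G3 conserved everywhere -> excluded
    stringsAsFactors = FALSE)
  recon <- reconstructEvents(sites, tr, nGenes = 3,
                             species = c("A", "B", "C", "D"))
  expect_equal(genesWithBoth(recon), "G2")
})

test_that("event reconstruction regenerates every presence pattern", {
  set.seed(63)
  tr <- randomLabelledTree(6)
  idxTips <- tr$tip.label
  for (mask in sample(seq_len(63), 30)) {
    present <- idxTips[bitwAnd(mask, bitwShiftL(1L, 0:5)) > 0]
    r <- inferSiteDollo(present, tr)
    ## regenerate: tips under gain node minus tips under loss edges
    tipsOf <- function(name) {
      if (name %in% tr$tip.label) return(name)
      nd <- length(tr$tip.label) + match(name, tr$node.label)
      ape::extract.clade(tr, nd)$tip.label
    }
    got <- setdiff(tipsOf(r$gainNode),
                   unlist(lapply(r$lossBranches, tipsOf)))
    expect_setequal(got, present)
  }
})
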