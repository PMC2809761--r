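## Synthetic intron-turnover data with known ground truth.
##
## The simulator emulates the data regime of a multi-genome intron turnover
## study: a set of ortholog groups present in every species of a dated tree,
## ancestral introns, per-branch Poisson gains and Dollo-consistent losses,
## intron sequences with controllable splice-motif and PTC structure, a
## 5'-biased positional law, occasional coding-sequence changes beside new
## introns, species-private large unspliced insertions, and optional planted
## direct repeats spanning both splice junctions. Exon sequences do not
## evolve, so protein alignments reflect the true homology exactly.

#' Construct simulation parameters
#'
#' Defaults are the package's study conditions: the 9-taxon dated fixture
#' tree; gain and loss rates of 2.8 and 7 events/gene/Bya (a roughly 1:2.6
#' gain:loss ratio); ~2.45 ancestral introns per gene; intron lengths
#' shifted-geometric with floor 45 nt and mean ~70 nt with a one-third 3n
#' class; 45% canonical donors and 60% canonical acceptors; retention-frame
#' stop density 3/64 per codon; 5' positional skew beta = 1; 13% of gains
#' changing 1-3 flanking codons; 5% per gene/species large insertions; 2% of
#' gains carrying a planted 10 bp junction repeat.
#'
#' @param nGenes number of ortholog groups.
#' @param tree rooted `ape::phylo` with branch lengths in My (default: the
#'   packaged 9-taxon tree).
#' @param gainRate,lossRate events/gene/Bya; scalar, or vector named by
#'   branch (child-node name) for per-branch rates.
#' @param meanIntronLength,p3n,pCanonicalDonor,pCanonicalAcceptor,ptcDensity
#'   intron sequence model; see [SimulationParams-class].
#' @param positionBeta 5'-skew parameter (0 = uniform insertion positions).
#' @param pCodingChange,pPlantedRepeat,repeatLength,pLargeInsertion
#'   structural variant model; see [SimulationParams-class].
#' @param pMinusStrand probability a gene is written on the minus strand.
#' @param ancIntronsPerGene Poisson mean of ancestral introns.
#' @param meanCdsCodons typical CDS length in codons (log-normal location).
#' @param seed master RNG seed (identical seed, identical output bytes).
#' @return a [SimulationParams-class] object.
#' @export
simulationParams <- function(nGenes = 500L, tree = NULL,
                             gainRate = 2.8, lossRate = 7,
                             meanIntronLength = 70, p3n = 1 / 3,
                             pCanonicalDonor = 0.45,
                             pCanonicalAcceptor = 0.6,
                             ptcDensity = 3 / 64, positionBeta = 1,
                             pCodingChange = 0.13, pPlantedRepeat = 0.02,
                             repeatLength = 10L, pLargeInsertion = 0.05,
                             pMinusStrand = 0.5, ancIntronsPerGene = 2.45,
                             meanCdsCodons = 450, seed = 1L) {
  if (is.null(tree)) tree <- readSpeciesTree(fixtureTreePath())
  new("SimulationParams", nGenes = as.integer(nGenes),
      tree = ensureNodeLabels(tree), gainRate = gainRate, lossRate = lossRate,
      meanIntronLength = meanIntronLength, p3n = p3n,
      pCanonicalDonor = pCanonicalDonor,
      pCanonicalAcceptor = pCanonicalAcceptor, ptcDensity = ptcDensity,
      positionBeta = positionBeta, pCodingChange = pCodingChange,
      pPlantedRepeat = pPlantedRepeat, repeatLength = as.integer(repeatLength),
      pLargeInsertion = pLargeInsertion, pMinusStrand = pMinusStrand,
      ancIntronsPerGene = ancIntronsPerGene, meanCdsCodons = meanCdsCodons,
      seed = as.integer(seed))
}

#' Draw relative insertion positions from the 5'-skew law
#'
#' Density proportional to `(1 - r)^beta` on [0, 1); `beta = 0` is uniform
#' and larger beta shifts mass towards the 5' end (the ECDF stochastically
#' dominates the uniform). Drawn by inverse CDF.
#'
#' @param n number of draws.
#' @param beta skew parameter (>= 0).
#' @return numeric vector in [0, 1).
#' @export
drawRelativePosition <- function(n, beta) {
  stopifnot(beta >= 0)
  1 - (1 - runif(n))^(1 / (beta + 1))
}

#' Draw one intron sequence from the motif/PTC model
#'
#' The sequence always begins `GT` and ends `AG`. The donor 6-mer matches
#' GT(A/G)AGT with probability `pCanonicalDonor`; the acceptor 3-mer is CAG
#' with probability `pCanonicalAcceptor`. Length follows a shifted geometric
#' law with floor 45 nt, adjusted into or out of the 3n class according to
#' `want3n`. Retention-frame codons wholly inside the sequence (clear of the
#' fixed donor/acceptor bases) are stop codons with probability `ptcDensity`.
#' Note that a canonical donor under phase 2 necessarily places TAA or TGA as
#' the first retained-frame codon regardless of `ptcDensity`.
#'
#' @param params a [SimulationParams-class].
#' @param phase intron phase (0/1/2).
#' @param want3n logical: force length to (not) be a multiple of 3.
#' @return character scalar (uses the current RNG stream).
#' @export
drawIntronSequence <- function(params, phase, want3n) {
  len <- 45L + rgeom(1L, 1 / (params@meanIntronLength - 44))
  mod <- len %% 3L
  if (want3n) {
    if (mod != 0L) len <- len + (3L - mod)
  } else if (mod == 0L) {
    len <- len + sample(1:2, 1L)
  }

  donor <- if (runif(1) < params@pCanonicalDonor) {
    sample(CANONICAL_DONORS, 1L)
  } else {
    repeat {
      d <- paste0("GT", randomDna(4L))
      if (!d %in% CANONICAL_DONORS) break
    }
    d
  }
  accN <- if (runif(1) < params@pCanonicalAcceptor) "C"
          else sample(c("A", "G", "T"), 1L)
  acceptor <- paste0(accN, "AG")

  body <- chars(paste0(donor, randomDna(len - 9L), acceptor))
  ## impose retention-frame stop density on codons clear of the fixed ends
  off0 <- retentionFrameOffset(phase)
  starts <- seq.int(off0 + 1L, by = 3L,
                    length.out = max(0L, (len - off0) %/% 3L))
  starts <- starts[starts > 6L & starts + 2L < len - 2L]
  for (st in starts) {
    codon <- if (runif(1) < params@ptcDensity) sample(STOP_CODONS, 1L)
             else sample(SENSE_CODONS, 1L)
    body[st:(st + 2L)] <- chars(codon)
  }
  paste(body, collapse = "")
}

## Rewrite an intron so that a perfect direct repeat of length r spans both
## junctions: copy A = intron[1..r] (covers the first intron base), copy B =
## intron[(len-r+3)..len] plus the first two exon bases after the intron.
## Preserves length and the drawn donor6; the terminal AG is kept.
plantJunctionRepeat <- function(seq, exon3TwoBases, r = 10L) {
  len <- nchar(seq)
  if (len < 2L * r) return(NULL)
  head8 <- paste0(substr(seq, 1L, r - 4L), "AG")       # "GT....AG", r-2 chars
  copyA <- paste0(head8, exon3TwoBases)                # r chars
  mid <- substr(seq, r + 1L, len - (r - 2L))
  list(seq = paste0(copyA, mid, head8),
       aStart = 1L, aEnd = r, bStart = len - (r - 2L) + 1L, bEnd = len + 2L)
}

#' Simulate intron turnover with known ground truth
#'
#' Generates per-species gene models, per-group protein alignments, and a
#' ground-truth event table under the study conditions in `params`. Gains are
#' a Poisson process on each branch (rate x genes x branch length), each gain
#' drawing an insertion point from the 5'-skew law and a sequence from the
#' motif/PTC model; losses thin the carried introns branch by branch. Each
#' site is gained exactly once (colliding positions are re-drawn), so the
#' truth is Dollo-consistent by construction. Identical seeds give identical
#' output.
#'
#' @param params a [SimulationParams-class].
#' @return an object of class `intronSimulation`: list with `models` (per
#'   species, named lists of [GeneModel-class]), `msas` (per group,
#'   `AAStringSet`), `tree`, `truth` (list of `sites` and `insertions`
#'   data.frames) and `params`.
#' @export
simulateTurnover <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  withr::with_seed(params@seed, simulateTurnoverImpl(params))
}

rateFor <- function(rates, branchName) {
  if (!is.null(names(rates)) && branchName %in% names(rates))
    unname(rates[branchName])
  else unname(rates[1])
}

simulateTurnoverImpl <- function(params) {
  tree <- ensureNodeLabels(params@tree)
  tips <- tree$tip.label
  nTip <- length(tips)
  nGenes <- params@nGenes
  geneIds <- sprintf("g%04d", seq_len(nGenes))

  ## homoplasy-risk warning: expected gains per gene per branch above 1
  for (k in seq_len(nrow(tree$edge))) {
    br <- nodeName(tree, tree$edge[k, 2])
    if (rateFor(params@gainRate, br) * tree$edge.length[k] / 1000 > 1)
      warning("branch '", br, "': expected >1 gain per gene; colliding ",
              "sites are re-drawn but homoplasy pressure is high",
              call. = FALSE)
  }

  ## --- ancestral genes -----------------------------------------------------
  nCodons <- pmin(2000L, pmax(100L, round(rlnorm(nGenes,
                                                 log(params@meanCdsCodons),
                                                 0.3))))
  cds0 <- vapply(nCodons, function(nc)
    paste0("ATG", randomSenseCodons(nc - 1L)), character(1))
  geneStrand <- ifelse(runif(nGenes) < params@pMinusStrand, "-", "+")
  flank5 <- vapply(seq_len(nGenes), function(i) randomDna(30L), character(1))
  flank3 <- vapply(seq_len(nGenes), function(i) randomDna(30L), character(1))

  ## --- site registry -------------------------------------------------------
  sites <- list()           # siteId -> record
  usedOffsets <- new.env(parent = emptyenv())

  drawOffset <- function(gene) {
    nc <- nCodons[match(gene, geneIds)]
    for (try in 1:100) {
      r <- drawRelativePosition(1L, params@positionBeta)
      off <- 3L + floor(r * (3L * nc - 6L))
      key <- paste0(gene, "@", off)
      if (is.null(usedOffsets[[key]])) {
        usedOffsets[[key]] <- TRUE
        return(off)
      }
    }
    stop("could not place a unique intron site in gene ", gene)
  }

  newSite <- function(gene, gainBranch, allowCodingChange) {
    off <- drawOffset(gene)
    phase <- off %% 3L
    want3n <- runif(1) < params@p3n
    seq <- drawIntronSequence(params, phase, want3n)
    ccK <- 0L
    if (allowCodingChange && runif(1) < params@pCodingChange)
      ccK <- sample(1:3, 1L)
    planted <- FALSE
    rep <- list(aStart = NA_integer_, aEnd = NA_integer_,
                bStart = NA_integer_, bEnd = NA_integer_)
    if (runif(1) < params@pPlantedRepeat) {
      e3 <- substr(cds0[match(gene, geneIds)], off + 1L, off + 2L)
      pr <- plantJunctionRepeat(seq, e3, params@repeatLength)
      if (!is.null(pr)) {
        seq <- pr$seq
        planted <- TRUE
        rep <- pr
      }
    }
    id <- paste0(gene, "@", off)
    sites[[id]] <<- list(id = id, gene = gene, offset = off, phase = phase,
                         is3n = nchar(seq) %% 3L == 0L, seq = seq,
                         gainBranch = gainBranch, lossBranches = character(0),
                         ccK = ccK, planted = planted, rep = rep,
                         present = character(0))
    id
  }

  ## ancestral sites (gain branch "ROOT")
  nAnc <- rpois(nGenes, params@ancIntronsPerGene)
  for (i in seq_len(nGenes)) {
    for (j in seq_len(nAnc[i])) newSite(geneIds[i], "ROOT", FALSE)
  }
  rootCarried <- names(sites)

  ## --- branch-by-branch turnover ------------------------------------------
  childrenOf <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  edgeLen <- function(child) tree$edge.length[match(child, tree$edge[, 2])]

  walk <- function(node, carried) {
    if (node <= nTip) {
      for (id in carried)
        sites[[id]]$present <<- c(sites[[id]]$present, tips[node])
      return(invisible())
    }
    for (child in childrenOf(node)) {
      brName <- nodeName(tree, child)
      t <- edgeLen(child)
      nLoss <- rpois(1L, rateFor(params@lossRate, brName) * nGenes * t / 1000)
      nLoss <- min(nLoss, length(carried))
      lost <- if (nLoss > 0L) sample(carried, nLoss) else character(0)
      for (id in lost)
        sites[[id]]$lossBranches <<- c(sites[[id]]$lossBranches, brName)
      kept <- setdiff(carried, lost)
      nGain <- rpois(1L, rateFor(params@gainRate, brName) * nGenes * t / 1000)
      gained <- character(nGain)
      for (gi in seq_len(nGain))
        gained[gi] <- newSite(sample(geneIds, 1L), brName, TRUE)
      walk(child, c(kept, gained))
    }
  }
  walk(nTip + 1L, rootCarried)

  ## observable sites only
  sites <- Filter(function(s) length(s$present) > 0L, sites)

  ## --- insertion events (alignment structure) ------------------------------
  ## carriers of a coding change = all tips under the gain branch
  idx <- treeIndex(tree)
  tipsUnderName <- function(name) {
    node <- nodeNumber(tree, name)
    tips[idx$tipsUnder[node, ]]
  }
  insEvents <- lapply(geneIds, function(g) list())
  names(insEvents) <- geneIds
  evCounter <- 0L
  addEvent <- function(gene, anchor, k, carriers, kind, siteId = NA_character_) {
    evCounter <<- evCounter + 1L
    ev <- list(id = evCounter, anchor = anchor, k = k, carriers = carriers,
               codons = randomSenseCodons(k), kind = kind, siteId = siteId)
    insEvents[[gene]][[length(insEvents[[gene]]) + 1L]] <<- ev
    ev
  }
  for (id in names(sites)) {
    s <- sites[[id]]
    if (s$ccK > 0L) {
      carriers <- tipsUnderName(if (s$gainBranch == "ROOT")
        nodeName(tree, nTip + 1L) else s$gainBranch)
      addEvent(s$gene, s$offset %/% 3L, s$ccK, carriers, "coding_change", id)
    }
  }
  ## species-private large unspliced insertions
  siteResidues <- lapply(geneIds, function(g) integer(0))
  names(siteResidues) <- geneIds
  for (id in names(sites)) {
    s <- sites[[id]]
    siteResidues[[s$gene]] <- c(siteResidues[[s$gene]], s$offset %/% 3L)
  }
  insertionTruth <- list()
  for (i in seq_len(nGenes)) {
    g <- geneIds[i]
    for (sp in tips) {
      if (runif(1) >= params@pLargeInsertion) next
      k <- sample(15:40, 1L)
      banned <- unique(c(outer(siteResidues[[g]], -4:4, `+`),
                         vapply(insEvents[[g]], `[[`, numeric(1), "anchor")))
      pool <- setdiff(2:(nCodons[i] - 2L), banned)
      if (!length(pool)) next
      anchor <- if (length(pool) == 1L) pool else sample(pool, 1L)
      addEvent(g, anchor, k, sp, "large_insertion")
      insertionTruth[[length(insertionTruth) + 1L]] <-
        data.frame(group = g, species = sp, anchor_residue = anchor,
                   length_aa = k, stringsAsFactors = FALSE)
    }
  }

  ## --- assemble alignments, gene models, truth -----------------------------
  sitesByGene <- split(names(sites),
                       vapply(sites, `[[`, character(1), "gene")[names(sites)])
  msas <- list()
  models <- lapply(tips, function(sp) list())
  names(models) <- tips
  truthRows <- list()

  for (i in seq_len(nGenes)) {
    g <- geneIds[i]
    nc <- nCodons[i]
    baseAA <- chars(translateCds(cds0[i]))
    baseCodons <- substring(cds0[i], seq(1L, 3L * nc, by = 3L),
                            seq(3L, 3L * nc, by = 3L))
    evs <- insEvents[[g]]
    if (length(evs)) {
      ord <- order(vapply(evs, `[[`, numeric(1), "anchor"),
                   vapply(evs, `[[`, numeric(1), "id"))
      evs <- evs[ord]
    }
    evAnchor <- vapply(evs, `[[`, numeric(1), "anchor")
    evK <- vapply(evs, function(e) e$k, numeric(1))

    ## alignment columns: events (anchor order, then id) sit immediately
    ## before their anchor residue; layout is shared by all rows
    nCol <- nc + sum(evK)
    if (length(evs)) {
      ksum <- cumsum(evK)
      nInsBefore <- c(0, ksum)[findInterval(0:(nc - 1L), evAnchor) + 1L]
      colOfBase <- seq_len(nc) + as.integer(nInsBefore)
      evColStart <- as.integer(evAnchor + c(0L, ksum[-length(ksum)]) + 1L)
      evCols <- lapply(seq_along(evs), function(ei)
        evColStart[ei] + 0:(evK[ei] - 1L))
    } else {
      colOfBase <- seq_len(nc)
      evCols <- list()
    }
    evAA <- lapply(evs, function(e) chars(translateCds(e$codons)))
    template <- rep("-", nCol)
    template[colOfBase] <- baseAA
    rows <- list(); rowMaps <- list()
    for (sp in tips) {
      carried <- if (length(evs))
        which(vapply(evs, function(e) sp %in% e$carriers, logical(1)))
      else integer(0)
      row <- template
      for (ei in carried) row[evCols[[ei]]] <- evAA[[ei]]
      rows[[sp]] <- paste(row, collapse = "")
      rowMaps[[sp]] <- sort(c(colOfBase, unlist(evCols[carried])))
    }
    msas[[g]] <- Biostrings::AAStringSet(unlist(rows))

    ## per-species CDS and intron offsets
    gSiteIds <- sitesByGene[[g]]
    gSites <- sites[gSiteIds]
    for (sp in tips) {
      carriedEv <- if (length(evs))
        which(vapply(evs, function(e) sp %in% e$carriers, logical(1)))
      else integer(0)
      cdsSp <- {
        cod <- baseCodons
        if (length(carriedEv)) {
          ## splice event codons in, highest anchor first to keep indices valid
          for (ei in rev(carriedEv[order(evAnchor[carriedEv])])) {
            a <- evAnchor[ei]
            cod <- append(cod, substring(
              evs[[ei]]$codons,
              seq(1L, 3L * evK[ei], by = 3L), seq(3L, 3L * evK[ei], by = 3L)),
              after = a)
          }
        }
        paste(cod, collapse = "")
      }
      ## introns present in this species, with shifted offsets
      offs <- integer(0); seqs <- character(0); ids <- character(0)
      for (id in gSiteIds) {
        s <- gSites[[id]]
        if (!sp %in% s$present) next
        shift <- 0L
        for (ei in carriedEv) {
          e <- evs[[ei]]
          before <- if (identical(e$siteId, id)) TRUE
                    else 3L * e$anchor < s$offset
          if (before) shift <- shift + 3L * e$k
        }
        offs <- c(offs, s$offset + shift)
        seqs <- c(seqs, s$seq)
        ids <- c(ids, id)
      }
      o <- order(offs)
      offs <- offs[o]; seqs <- seqs[o]
      ## assemble contig in coding orientation
      cuts <- c(0L, offs, nchar(cdsSp))
      exonPieces <- substring(cdsSp, head(cuts, -1L) + 1L, cuts[-1L])
      ## drop the duplicated first cut when there are no introns
      if (length(offs)) {
        body <- paste0(paste0(exonPieces[seq_along(offs)], seqs,
                              collapse = ""),
                       exonPieces[length(exonPieces)])
      } else {
        body <- cdsSp
      }
      contigPlus <- paste0(flank5[i], body, flank3[i])
      ## exon coordinates in coding orientation
      exStarts <- integer(length(offs) + 1L)
      exEnds <- integer(length(offs) + 1L)
      pos <- nchar(flank5[i])
      for (ex in seq_along(exonPieces)) {
        exStarts[ex] <- pos + 1L
        pos <- pos + nchar(exonPieces[ex])
        exEnds[ex] <- pos
        if (ex <= length(offs)) pos <- pos + nchar(seqs[ex])
      }
      strand <- geneStrand[i]
      if (strand == "+") {
        contig <- contigPlus
        exons <- cbind(exStarts, exEnds)
      } else {
        contig <- revComp(contigPlus)
        L <- nchar(contigPlus)
        exons <- cbind(L - exEnds + 1L, L - exStarts + 1L)
        exons <- exons[order(exons[, 1]), , drop = FALSE]
      }
      models[[sp]][[g]] <- geneModelFromContig(g, sp, paste0("ctg_", g),
                                               strand, exons, contig)
    }

    ## truth rows for this gene's sites
    for (id in gSiteIds) {
      s <- gSites[[id]]
      carrier <- s$present[1]
      carriedEv <- if (length(evs))
        which(vapply(evs, function(e) carrier %in% e$carriers, logical(1)))
      else integer(0)
      shift <- 0L
      for (ei in carriedEv) {
        e <- evs[[ei]]
        if (identical(e$siteId, id) || 3L * e$anchor < s$offset)
          shift <- shift + 3L * e$k
      }
      resIdx <- (s$offset + shift) %/% 3L          # 0-based carrier residue
      column <- rowMaps[[carrier]][resIdx + 1L]
      presence <- paste(as.integer(tips %in% s$present), collapse = "")
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        site_id = id, group = g, ancestral_offset = s$offset,
        phase = s$phase, column = column, gain_branch = s$gainBranch,
        loss_branches = joinField(sort(s$lossBranches)), presence = presence,
        n_present = length(s$present), is_3n = s$is3n,
        length = nchar(s$seq), coding_change_aa = s$ccK,
        planted_repeat = s$planted,
        repeat_a_start = s$rep$aStart, repeat_a_end = s$rep$aEnd,
        repeat_b_start = s$rep$bStart, repeat_b_end = s$rep$bEnd,
        stringsAsFactors = FALSE)
    }
  }

  truthSites <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(site_id = character(0), group = character(0),
               ancestral_offset = integer(0), phase = integer(0),
               column = integer(0), gain_branch = character(0),
               loss_branches = character(0), presence = character(0),
               n_present = integer(0), is_3n = logical(0),
               length = integer(0), coding_change_aa = integer(0),
               planted_repeat = logical(0), repeat_a_start = integer(0),
               repeat_a_end = integer(0), repeat_b_start = integer(0),
               repeat_b_end = integer(0))
  truthSites <- truthSites[order(truthSites$group,
                                 truthSites$ancestral_offset), ]
  rownames(truthSites) <- NULL
  truthIns <- if (length(insertionTruth)) do.call(rbind, insertionTruth) else
    data.frame(group = character(0), species = character(0),
               anchor_residue = integer(0), length_aa = integer(0))

  structure(list(models = models, msas = msas, tree = tree,
                 truth = list(sites = truthSites, insertions = truthIns),
                 params = params),
            class = "intronSimulation")
}

#' @export
print.intronSimulation <- function(x, ...) {
  cat("intronSimulation:", length(x$msas), "groups x",
      length(x$models), "species;", nrow(x$truth$sites), "intron sites (",
      sum(x$truth$sites$gain_branch != "ROOT"), "gained ),",
      nrow(x$truth$insertions), "large insertions\n")
  invisible(x)
}

#' Ground-truth event rows of a simulation
#'
#' Sites that represent a turnover event: gained on a non-root branch, or
#' lost on at least one branch. With all rates at zero this table is empty.
#'
#' @param sim an `intronSimulation`.
#' @return subset of the truth sites table.
#' @export
truthEvents <- function(sim) {
  s <- sim$truth$sites
  s[s$gain_branch != "ROOT" | nzchar(s$loss_branches), , drop = FALSE]
}

#' Write a simulation to disk
#'
#' Emits per-species GFF3 + genome FASTA, per-group aligned protein FASTA
#' (under `msa/`), the newick tree, truth TSVs, and a parameter echo
#' (`params.yaml`). Output is deterministic given the simulation.
#'
#' @param sim an `intronSimulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "msa"), showWarnings = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  for (sp in names(sim$models)) {
    mods <- sim$models[[sp]]
    writeGeneModels(mods, file.path(dir, paste0(sp, ".gff3")))
    contigs <- vapply(mods, contigSequence, character(1))
    names(contigs) <- vapply(mods, function(gm) gm@contig, character(1))
    writeGenomeFasta(contigs, file.path(dir, paste0(sp, ".fa")))
  }
  for (g in names(sim$msas))
    writeProteinMSA(sim$msas[[g]], file.path(dir, "msa", paste0(g, ".faa")))
  writeTsv(sim$truth$sites, file.path(dir, "truth_sites.tsv"))
  writeTsv(sim$truth$insertions, file.path(dir, "truth_insertions.tsv"))
  p <- sim$params
  yaml::write_yaml(list(
    nGenes = p@nGenes, gainRate = as.list(p@gainRate),
    lossRate = as.list(p@lossRate), meanIntronLength = p@meanIntronLength,
    p3n = p@p3n, pCanonicalDonor = p@pCanonicalDonor,
    pCanonicalAcceptor = p@pCanonicalAcceptor, ptcDensity = p@ptcDensity,
    positionBeta = p@positionBeta, pCodingChange = p@pCodingChange,
    pPlantedRepeat = p@pPlantedRepeat, repeatLength = p@repeatLength,
    pLargeInsertion = p@pLargeInsertion, pMinusStrand = p@pMinusStrand,
    ancIntronsPerGene = p@ancIntronsPerGene, meanCdsCodons = p@meanCdsCodons,
    seed = p@seed), file.path(dir, "params.yaml"))
  invisible(dir)
}
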