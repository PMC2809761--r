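## Dollo-parsimony reconstruction of intron gain and loss events.
##
## Under Dollo parsimony each intron site is gained exactly once; the gain
## node is the MRCA of the species carrying the intron, and losses are the
## topmost edges of the maximal all-absent subtrees inside the gain clade.
## Sites whose gain node is the tree root cannot be polarized (the intron may
## be ancestral), so their root event is reported separately and never counted
## on either root-child branch; their losses are still losses.

## Precompute per-node tip sets and children for fast repeated queries.
treeIndex <- function(tree) {
  nTip <- ape::Ntip(tree)
  nNode <- nTip + tree$Nnode
  children <- vector("list", nNode)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    children[[p]] <- c(children[[p]], tree$edge[k, 2])
  }
  ## tips under each node (node x tip); postorder guarantees children first
  tipsUnder <- matrix(FALSE, nNode, nTip)
  tipsUnder[cbind(seq_len(nTip), seq_len(nTip))] <- TRUE
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    tipsUnder[eo[k, 1], ] <- tipsUnder[eo[k, 1], ] | tipsUnder[eo[k, 2], ]
  }
  list(tree = tree, nTip = nTip, root = nTip + 1L, children = children,
       tipsUnder = tipsUnder, cladeSize = rowSums(tipsUnder))
}

## Internal single-site Dollo reconstruction on a prebuilt index.
dolloOne <- function(idx, presentTips) {
  if (!length(presentTips)) stop("all-absent presence vector: no site")
  if (length(presentTips) == 1L) {
    gain <- presentTips
  } else {
    mask <- rep(FALSE, idx$nTip)
    mask[presentTips] <- TRUE
    ok <- which(idx$tipsUnder[, presentTips[1]] &
                  rowSums(idx$tipsUnder[, mask, drop = FALSE]) ==
                  length(presentTips))
    gain <- ok[which.min(idx$cladeSize[ok])]
  }
  ## losses: maximal all-absent subtrees inside the gain clade
  losses <- integer(0)
  if (idx$cladeSize[gain] > length(presentTips)) {
    stack <- gain
    presMask <- rep(FALSE, idx$nTip)
    presMask[presentTips] <- TRUE
    while (length(stack)) {
      node <- stack[[1]]; stack <- stack[-1]
      for (ch in idx$children[[node]]) {
        nPres <- sum(idx$tipsUnder[ch, ] & presMask)
        if (nPres == 0L) losses <- c(losses, ch)
        else if (nPres < idx$cladeSize[ch]) stack <- c(stack, ch)
      }
    }
  }
  list(gain = gain, losses = losses, rootAmbiguous = gain == idx$root)
}

#' Dollo reconstruction for one intron site
#'
#' The gain node is the MRCA of the present species; losses are the root
#' edges (identified by their child node) of the maximal all-absent subtrees
#' within the gain clade. If the gain node is the tree root the site is
#' root-ambiguous: the event at the root cannot be classified as a gain
#' (versus an ancestral intron), so it is not assigned to any branch.
#'
#' @param presentSpecies character vector of tip labels carrying the intron
#'   (at least one).
#' @param tree rooted `ape::phylo` with unique tip labels.
#' @return list with `gainNode` (node name), `rootAmbiguous` (logical) and
#'   `lossBranches` (character vector of child-node names).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
#' inferSiteDollo(c("A", "B"), tr)   # gain on the (A,B) clade, no losses
#' inferSiteDollo(c("A", "C"), tr)$rootAmbiguous  # TRUE
#' @export
inferSiteDollo <- function(presentSpecies, tree) {
  tree <- ensureNodeLabels(tree)
  idx <- treeIndex(tree)
  tips <- match(presentSpecies, tree$tip.label)
  if (anyNA(tips)) stop("unknown species: ",
                        paste(presentSpecies[is.na(tips)], collapse = ", "))
  r <- dolloOne(idx, tips)
  list(gainNode = nodeName(tree, r$gain),
       rootAmbiguous = r$rootAmbiguous,
       lossBranches = nodeName(tree, r$losses))
}

#' Reconstruct gain/loss events for a set of intron sites
#'
#' Applies Dollo parsimony per site and tallies per-branch gain and loss
#' counts and rates (events/gene/Bya, using `nGenes` as fixed denominator and
#' branch lengths in My). The unplaceable root events of root-ambiguous sites
#' are counted separately.
#'
#' @param sites an [IntronSiteSet-class], or a data.frame with columns
#'   `site_id`, `group`, `column`, `phase`, `presence` (0/1 string in
#'   `species` order).
#' @param tree rooted `ape::phylo`, branch lengths in My.
#' @param nGenes analyzed-gene denominator for rates.
#' @param species species order of the presence strings (taken from the
#'   `IntronSiteSet` when omitted).
#' @return an [EventReconstruction-class] object.
#' @export
reconstructEvents <- function(sites, tree, nGenes, species = NULL) {
  if (is(sites, "IntronSiteSet")) {
    species <- sites@species
    sites <- sites@sites
  }
  if (is.null(species)) stop("species order must be supplied")
  tree <- ensureNodeLabels(tree)
  if (!setequal(species, tree$tip.label))
    stop("species in presence vectors must match tree tip labels")
  idx <- treeIndex(tree)
  tipOf <- match(species, tree$tip.label)

  n <- nrow(sites)
  gainNode <- character(n); rootAmb <- logical(n)
  lossBr <- character(n); nLoss <- integer(n)
  presMat <- if (n) do.call(rbind, lapply(strsplit(sites$presence, ""),
                                          as.integer)) else
    matrix(0L, 0, length(species))
  for (i in seq_len(n)) {
    tips <- tipOf[presMat[i, ] == 1L]
    r <- dolloOne(idx, tips)
    gainNode[i] <- nodeName(tree, r$gain)
    rootAmb[i] <- r$rootAmbiguous
    lossBr[i] <- joinField(nodeName(tree, r$losses))
    nLoss[i] <- length(r$losses)
  }
  siteDf <- data.frame(sites[, c("site_id", "group", "column", "phase",
                                 "presence")],
                       gain_node = gainNode, root_ambiguous = rootAmb,
                       loss_branches = lossBr, n_losses = nLoss,
                       stringsAsFactors = FALSE)
  branches <- branchRateTable(siteDf, tree, nGenes)
  new("EventReconstruction", sites = siteDf, branches = branches, tree = tree,
      species = species, nGenes = as.integer(nGenes),
      nRootAmbiguous = sum(rootAmb))
}

## Per-branch count/rate table (branch id = child-node name), with TOTAL row.
branchRateTable <- function(siteDf, tree, nGenes) {
  stopifnot(nGenes > 0)
  nTip <- ape::Ntip(tree)
  childNodes <- tree$edge[, 2]
  branch <- nodeName(tree, childNodes)
  lengthMy <- tree$edge.length
  gains <- table(factor(siteDf$gain_node[!siteDf$root_ambiguous],
                        levels = branch))
  losses <- table(factor(unlist(lapply(siteDf$loss_branches, splitField)),
                         levels = branch))
  nG <- as.integer(gains); nL <- as.integer(losses)
  rate <- function(nEv, len) {
    r <- nEv / nGenes / (len / 1000)
    bad <- len == 0 & nEv > 0
    if (any(bad)) {
      warning("zero-length branch with events: rate reported as Inf",
              call. = FALSE)
      r[bad] <- Inf
    }
    r[len == 0 & nEv == 0] <- 0
    r
  }
  df <- data.frame(branch = branch, length_my = lengthMy,
                   n_gains = nG, n_losses = nL,
                   gain_rate = rate(nG, lengthMy),
                   loss_rate = rate(nL, lengthMy),
                   stringsAsFactors = FALSE)
  df <- df[order(df$branch), ]
  tot <- data.frame(branch = "TOTAL", length_my = sum(lengthMy),
                    n_gains = sum(nG), n_losses = sum(nL),
                    gain_rate = rate(sum(nG), sum(lengthMy)),
                    loss_rate = rate(sum(nL), sum(lengthMy)),
                    stringsAsFactors = FALSE)
  rbind(df, tot)
}

#' @rdname accessors
#' @export
setMethod("siteEvents", "EventReconstruction", function(x) x@sites)

#' @rdname accessors
#' @export
setMethod("branchRates", "EventReconstruction", function(x) x@branches)

#' @rdname accessors
#' @export
setMethod("rootAmbiguousCount", "EventReconstruction",
          function(x) x@nRootAmbiguous)

setMethod("show", "EventReconstruction", function(object) {
  s <- object@sites
  cat("EventReconstruction over", nrow(s), "sites,", object@nGenes,
      "genes\n")
  cat("  gains (non-root):", sum(!s$root_ambiguous),
      " losses:", sum(s$n_losses),
      " root-ambiguous:", object@nRootAmbiguous, "\n")
})

#' Ortholog groups with both intron gain and loss
#'
#' A group qualifies when it carries at least one gained (non-root-ambiguous)
#' site and at least one site with at least one loss branch.
#'
#' @param recon an [EventReconstruction-class].
#' @return sorted character vector of group ids.
#' @export
genesWithBoth <- function(recon) {
  s <- siteEvents(recon)
  gained <- unique(s$group[!s$root_ambiguous])
  lost <- unique(s$group[s$n_losses > 0L])
  sort(intersect(gained, lost))
}

#' Write event and rate tables
#'
#' @param recon an [EventReconstruction-class].
#' @param eventsPath,ratesPath output TSV paths.
#' @export
writeEventTables <- function(recon, eventsPath, ratesPath) {
  s <- siteEvents(recon)
  out <- data.frame(
    site_id = s$site_id, group = s$group, column = s$column, phase = s$phase,
    presence = s$presence,
    gain_branch = ifelse(s$root_ambiguous, "ROOT_AMBIGUOUS", s$gain_node),
    loss_branches = s$loss_branches, stringsAsFactors = FALSE)
  writeTsv(out, eventsPath)
  writeTsv(branchRates(recon), ratesPath)
  invisible(recon)
}
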