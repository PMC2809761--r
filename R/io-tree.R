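## Rooted species-tree input.

#' Read a rooted species tree with branch lengths in My
#'
#' Wraps [ape::read.tree()] with the checks the pipeline needs: the tree must
#' be rooted (a root with more than two children is accepted only when
#' `allowMultifurcating = TRUE`), and every edge must carry a non-negative
#' branch length. Internal nodes without labels are assigned stable labels
#' (`n<number>`) so that branches (identified by their child node) can be
#' named in outputs.
#'
#' @param newickPath path to a newick file.
#' @param allowMultifurcating accept a root with >2 children.
#' @return an `ape::phylo` object.
#' @export
readSpeciesTree <- function(newickPath, allowMultifurcating = FALSE) {
  tree <- tryCatch(ape::read.tree(newickPath),
                   error = function(e) stop("newick parse error in '",
                                            newickPath, "': ",
                                            conditionMessage(e)))
  if (is.null(tree))
    stop("newick parse error in '", newickPath, "': no tree found")
  checkSpeciesTree(tree, allowMultifurcating)
  ensureNodeLabels(tree)
}

checkSpeciesTree <- function(tree, allowMultifurcating = FALSE) {
  rootNode <- ape::Ntip(tree) + 1L
  rootDeg <- sum(tree$edge[, 1] == rootNode)
  if (rootDeg > 2L && !allowMultifurcating)
    stop("root has ", rootDeg, " children (unrooted?); set ",
         "allowMultifurcating = TRUE to accept")
  if (rootDeg <= 2L && !ape::is.rooted(tree))
    stop("tree is unrooted; a rooted tree is required")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("every branch must carry a branch length (My)")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label)) stop("leaf names must be unique")
  invisible(tree)
}

ensureNodeLabels <- function(tree) {
  nNode <- tree$Nnode
  if (is.null(tree$node.label)) tree$node.label <- rep("", nNode)
  blank <- !nzchar(tree$node.label) | is.na(tree$node.label)
  tree$node.label[blank] <- paste0("n", which(blank))
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("duplicated node labels after assignment")
  tree
}

## Name of a node (tip or internal) by its ape node number.
nodeName <- function(tree, node) {
  nTip <- ape::Ntip(tree)
  out <- character(length(node))
  isTip <- node <= nTip
  out[isTip] <- tree$tip.label[node[isTip]]
  out[!isTip] <- tree$node.label[node[!isTip] - nTip]
  out
}

## ape node number from a name.
nodeNumber <- function(tree, name) {
  nTip <- ape::Ntip(tree)
  i <- match(name, tree$tip.label)
  j <- match(name, tree$node.label)
  out <- ifelse(is.na(i), j + nTip, i)
  if (anyNA(out)) stop("unknown node name(s): ",
                       paste(name[is.na(out)], collapse = ", "))
  out
}

#' Path to the packaged 9-taxon dated tree
#'
#' A rooted, ultrametric 9-species tree (root depth 40 My) with the standard
#' Drosophila topology: the melanogaster subgroup (*D. melanogaster*,
#' *D. erecta*, *D. yakuba*), *D. ananassae*, *D. pseudoobscura*,
#' *D. willistoni*, and the subgenus Drosophila (*D. virilis*,
#' *D. mojavensis*, *D. grimshawi*).
#'
#' @return file path to the newick fixture.
#' @export
fixtureTreePath <- function() {
  system.file("extdata", "nine_taxon_tree.nwk", package = "intronTurnover",
              mustWork = TRUE)
}
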