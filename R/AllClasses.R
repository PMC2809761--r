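#' GeneModel: one species' coding gene with exons and derived introns
#'
#' Represents the coding structure of a single gene in a single species.
#' Exon coordinates are stored in contig coordinates (1-based, inclusive,
#' ascending). Minus-strand genes are normalized at construction so that
#' `cdsSeq` and the intron table are always reported 5'->3' on the coding
#' strand; downstream modules are therefore strand-agnostic.
#'
#' The intron table has one row per intron in transcription order with columns
#' `gene_id`, `species`, `index` (1-based, 5'->3'), `start`, `end` (1-based
#' inclusive, coding-strand orientation), `length`, `phase` (number of coding
#' nt of the interrupted codon preceding the intron), `seq`, `donor6` (intron
#' positions +1..+6), `acceptor3` (intron positions -3..-1), `cds_offset`
#' (coding nt upstream of the insertion point) and `cds_length`.
#'
#' @slot geneID character, gene identifier.
#' @slot species character, species label (must match tree tip labels).
#' @slot contig character, contig/scaffold name.
#' @slot strand character, "+" or "-".
#' @slot exons integer matrix with columns start, end (contig coordinates,
#'   1-based inclusive, sorted ascending, non-overlapping).
#' @slot contigLength integer, length of the contig (needed to flip
#'   minus-strand coordinates).
#' @slot contigSeq character, the full contig sequence (plus strand), kept so
#'   genomes can be re-emitted and junction neighbourhoods extracted.
#' @slot cdsSeq character, concatenated coding sequence on the coding strand,
#'   alphabet A/C/G/T/N, length divisible by 3.
#' @slot intronTable data.frame as described above.
#'
#' @examples
#' ctg <- paste0("ATGAAAGGG", "GTAAAG", "CCCTTTACG")
#' gm <- geneModelFromContig("g1", "spA", "ctg1", "+",
#'                           cbind(c(1, 16), c(9, 24)), ctg)
#' introns(gm)
#' @export
setClass("GeneModel",
  representation(
    geneID = "character",
    species = "character",
    contig = "character",
    strand = "character",
    exons = "matrix",
    contigLength = "integer",
    contigSeq = "character",
    cdsSeq = "character",
    intronTable = "data.frame"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character(0)
  ex <- object@exons
  if (!is.numeric(ex) || ncol(ex) != 2L || nrow(ex) < 1L)
    msg <- c(msg, "exons must be a numeric matrix with >= 1 row and 2 columns")
  else {
    if (any(ex[, 2] < ex[, 1])) msg <- c(msg, "exon end before start")
    if (is.unsorted(ex[, 1], strictly = TRUE) && nrow(ex) > 1L)
      msg <- c(msg, "exons must be sorted by start")
    if (nrow(ex) > 1L && any(ex[-1L, 1] <= ex[-nrow(ex), 2]))
      msg <- c(msg, "exons must be non-overlapping")
    if (any(ex[, 1] < 1L) || any(ex[, 2] > object@contigLength))
      msg <- c(msg, "exon coordinates outside contig")
    if (nchar(object@cdsSeq) != sum(ex[, 2] - ex[, 1] + 1))
      msg <- c(msg, "cdsSeq length does not match summed exon widths")
  }
  if (nchar(object@contigSeq) != object@contigLength)
    msg <- c(msg, "contigSeq length does not match contigLength")
  if (nchar(object@cdsSeq) %% 3L != 0L)
    msg <- c(msg, "CDS length not divisible by 3")
  if (grepl("[^ACGTN]", object@cdsSeq))
    msg <- c(msg, "cdsSeq contains characters outside A/C/G/T/N")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  it <- object@intronTable
  if (nrow(it) > 0L) {
    if (any(it$length != it$end - it$start + 1L))
      msg <- c(msg, "intron length != end - start + 1")
    if (any(it$length != nchar(it$seq)))
      msg <- c(msg, "intron length != nchar(seq)")
    if (any(it$phase != it$cds_offset %% 3L))
      msg <- c(msg, "intron phase != cds_offset mod 3")
    if (any(it$cds_offset < 0L) || any(it$cds_offset > it$cds_length))
      msg <- c(msg, "cds_offset outside [0, cds_length]")
  }
  if (length(msg)) msg else TRUE
})

#' IntronSiteSet: homologized intron positions with presence/absence vectors
#'
#' A collection of intron sites for a set of complete ortholog groups. Each
#' site is one homologized intron position: a protein-alignment column (the
#' column of the residue whose codon contains or follows the insertion point),
#' an intron phase, and a presence/absence call for every species.
#'
#' @slot sites data.frame with columns `site_id`, `group`, `column` (1-based
#'   alignment column), `phase`, `presence` (string of 0/1 in `species` order)
#'   and `n_present`.
#' @slot species character vector giving the species order used by the
#'   presence strings.
#' @slot members list (parallel to rows of `sites`) of data.frames of member
#'   introns (columns species, gene_id, index, cds_offset, cds_length, length,
#'   seq, donor6, acceptor3).
#' @export
setClass("IntronSiteSet",
  representation(sites = "data.frame", species = "character", members = "list")
)

setValidity("IntronSiteSet", function(object) {
  msg <- character(0)
  if (nrow(object@sites) != length(object@members))
    msg <- c(msg, "members list must parallel the sites table")
  if (nrow(object@sites) > 0L) {
    if (any(nchar(object@sites$presence) != length(object@species)))
      msg <- c(msg, "presence strings must cover every species")
    if (!all(object@sites$phase %in% 0:2))
      msg <- c(msg, "phase must be in {0,1,2}")
  }
  if (length(msg)) msg else TRUE
})

#' EventReconstruction: Dollo gains, losses, and per-branch rates
#'
#' The result of Dollo-parsimony reconstruction over a set of intron sites.
#' Each site receives a gain node (the MRCA of the species carrying it) and a
#' set of loss branches (the topmost edges of the maximal all-absent subtrees
#' within the gain clade). Sites whose gain node is the tree root cannot be
#' polarized as gains (the state may be ancestral) and are flagged
#' root-ambiguous; their unplaceable root event is reported separately, while
#' their losses are still tallied.
#'
#' Branches are identified by their child-node name. Rates are events per gene
#' per Bya using the fixed analyzed-gene count as denominator.
#'
#' @slot sites data.frame with columns `site_id`, `group`, `column`, `phase`,
#'   `presence`, `gain_node`, `root_ambiguous`, `loss_branches`
#'   (comma-separated child-node names; "" if none) and `n_losses`.
#' @slot branches data.frame with columns `branch`, `length_my`, `n_gains`,
#'   `n_losses`, `gain_rate`, `loss_rate`, plus a TOTAL row.
#' @slot tree the `ape::phylo` tree used (node labels assigned if absent).
#' @slot species character, tip-label order used by presence strings.
#' @slot nGenes integer, analyzed-gene denominator for rates.
#' @slot nRootAmbiguous integer, count of root-ambiguous sites.
#' @export
setClass("EventReconstruction",
  representation(
    sites = "data.frame",
    branches = "data.frame",
    tree = "ANY",
    species = "character",
    nGenes = "integer",
    nRootAmbiguous = "integer"
  )
)

setValidity("EventReconstruction", function(object) {
  msg <- character(0)
  s <- object@sites
  if (nrow(s) > 0L) {
    if (any(!s$root_ambiguous & (is.na(s$gain_node) | !nzchar(s$gain_node))))
      msg <- c(msg, "non-ambiguous sites must carry exactly one gain node")
    if (any(s$n_losses != lengths(lapply(s$loss_branches, splitField))))
      msg <- c(msg, "n_losses inconsistent with loss_branches")
  }
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(msg)) msg else TRUE
})

#' BootstrapSummary: percentile-bootstrap summary for a splice statistic
#'
#' @slot statistic character, one of "donor_consensus_frac",
#'   "acceptor_consensus_frac", "distinct_donor_motifs".
#' @slot observedFocal numeric, statistic on the focal set.
#' @slot observedReference numeric, statistic on the reference set.
#' @slot B integer, bootstrap replicate count.
#' @slot ciLow,ciHigh numeric, 2.5th/97.5th percentiles of the resampled
#'   statistic (reference resampling at the focal sample size).
#' @slot significant logical, focal value outside the reference interval.
#' @slot focalCiLow,focalCiHigh numeric, optional focal-resampling interval
#'   (NA unless requested).
#' @slot seed integer, RNG seed used.
#' @slot focalN integer, resample size.
#' @export
setClass("BootstrapSummary",
  representation(
    statistic = "character",
    observedFocal = "numeric",
    observedReference = "numeric",
    B = "integer",
    ciLow = "numeric",
    ciHigh = "numeric",
    significant = "logical",
    focalCiLow = "numeric",
    focalCiHigh = "numeric",
    seed = "integer",
    focalN = "integer"
  )
)

setValidity("BootstrapSummary", function(object) {
  msg <- character(0)
  if (object@ciLow > object@ciHigh) msg <- c(msg, "ciLow > ciHigh")
  if (object@B < 1L) msg <- c(msg, "B must be positive")
  if (grepl("frac", object@statistic) &&
      (object@observedFocal < 0 || object@observedFocal > 1))
    msg <- c(msg, "fractions must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' SimulationParams: study conditions for the turnover simulator
#'
#' Defaults emulate a nine-species *Drosophila*-like study: a dated 9-taxon
#' tree (root depth 40 My), intron gains as a Poisson process on branches,
#' Dollo-consistent losses, intron lengths >= 45 nt with a controllable 3n
#' class mix, donor/acceptor motif frequencies, phase-dependent in-frame PTC
#' density, a 5'-biased positional law, occasional coding-sequence changes at
#' gains, species-private large unspliced insertions, and optionally planted
#' direct repeats spanning both splice junctions.
#'
#' @slot nGenes integer, ortholog groups to simulate.
#' @slot tree `ape::phylo`, rooted, branch lengths in My.
#' @slot gainRate,lossRate numeric, events/gene/Bya; either scalars or vectors
#'   named by branch (child-node name).
#' @slot meanIntronLength numeric, mean of the shifted-geometric intron length
#'   law (floor 45 nt).
#' @slot p3n numeric, probability an intron length is a multiple of 3.
#' @slot pCanonicalDonor numeric, probability donor6 matches GT(A/G)AGT.
#' @slot pCanonicalAcceptor numeric, probability acceptor3 is CAG.
#' @slot ptcDensity numeric, per-codon stop probability in the retention frame.
#' @slot positionBeta numeric, beta of the 5'-skew law with density
#'   proportional to (1-r)^beta on [0,1); 0 = uniform.
#' @slot pCodingChange numeric, probability a gain adds 1-3 flanking codons in
#'   carrier species.
#' @slot pPlantedRepeat numeric, probability a gained intron carries a perfect
#'   direct repeat overlapping both junctions.
#' @slot repeatLength integer, length of planted repeats.
#' @slot pLargeInsertion numeric, per-gene, per-species probability of a large
#'   (>= 15 aa) unspliced coding insertion.
#' @slot pMinusStrand numeric, probability a simulated gene is written on the
#'   minus strand of its contig.
#' @slot ancIntronsPerGene numeric, Poisson mean of ancestral introns per gene.
#' @slot meanCdsCodons numeric, log-normal location of CDS length in codons.
#' @slot seed integer, master seed; identical seeds give byte-identical output.
#' @export
setClass("SimulationParams",
  representation(
    nGenes = "integer",
    tree = "ANY",
    gainRate = "numeric",
    lossRate = "numeric",
    meanIntronLength = "numeric",
    p3n = "numeric",
    pCanonicalDonor = "numeric",
    pCanonicalAcceptor = "numeric",
    ptcDensity = "numeric",
    positionBeta = "numeric",
    pCodingChange = "numeric",
    pPlantedRepeat = "numeric",
    repeatLength = "integer",
    pLargeInsertion = "numeric",
    pMinusStrand = "numeric",
    ancIntronsPerGene = "numeric",
    meanCdsCodons = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character(0)
  probs <- c(object@p3n, object@pCanonicalDonor, object@pCanonicalAcceptor,
             object@ptcDensity, object@pCodingChange, object@pPlantedRepeat,
             object@pLargeInsertion, object@pMinusStrand)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0,1]")
  if (any(c(object@gainRate, object@lossRate) < 0))
    msg <- c(msg, "rates must be >= 0")
  if (object@meanIntronLength < 45)
    msg <- c(msg, "mean intron length must be >= 45 nt")
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo object")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@positionBeta < 0) msg <- c(msg, "positionBeta must be >= 0")
  if (length(msg)) msg else TRUE
})
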