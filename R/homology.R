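## Homologizing introns across species via protein alignments.
##
## An intron interrupting a coding sequence at cds_offset nucleotides lies in
## the codon of residue floor(cds_offset / 3); mapping that residue through
## the species' alignment row yields a (column, phase) pair shared by
## homologous introns, which become presence/absence sites over the species
## set.

#' Map one intron to its protein-alignment (column, phase)
#'
#' @param cdsOffset coding nucleotides upstream of the insertion point.
#' @param cdsLength CDS length (nt) of the gene in that species.
#' @param rowMap integer vector mapping 1-based residue index to 1-based
#'   alignment column for the species' row (see [msaRowMap()]).
#' @return list with `column` (1-based) and `phase` (0/1/2).
#' @export
mapIntron <- function(cdsOffset, cdsLength, rowMap) {
  if (cdsOffset >= cdsLength)
    stop("cds_offset ", cdsOffset, " beyond CDS (length ", cdsLength, ")")
  if (cdsOffset < 0L) stop("negative cds_offset")
  res <- cdsOffset %/% 3L + 1L
  if (res > length(rowMap))
    stop("residue index ", res, " beyond alignment row (", length(rowMap),
         " residues)")
  list(column = rowMap[[res]], phase = as.integer(cdsOffset %% 3L))
}

#' Build homologized intron sites from per-species gene models and alignments
#'
#' Groups must have exactly one gene per species; groups missing a species
#' are dropped (a message reports the count). Introns are clustered by exact
#' (column, phase); with `slack > 0`, clusters of equal phase whose columns
#' lie within `slack` of each other are chained together (the reported
#' column is the most populated member column, ties to the smallest). Two
#' introns of one gene mapping to one site is an annotation defect and an
#' error.
#'
#' @param models named list (species -> named list of [GeneModel-class]).
#' @param msas named list (group -> `AAStringSet`, rows named by species).
#' @param slack column tolerance for merging clusters (default 0).
#' @param species species order for presence vectors (default
#'   `names(models)`; pass the tree tip order for downstream Dollo use).
#' @return an [IntronSiteSet-class].
#' @export
buildIntronSites <- function(models, msas, slack = 0L, species = NULL) {
  if (is.null(species)) species <- names(models)
  stopifnot(setequal(species, names(models)))
  dropped <- 0L
  siteRows <- list(); memberList <- list()

  for (g in names(msas)) {
    have <- vapply(species, function(sp) !is.null(models[[sp]][[g]]),
                   logical(1))
    if (!all(have)) { dropped <- dropped + 1L; next }
    aln <- msas[[g]]
    if (!setequal(names(aln), species))
      stop("alignment rows of group '", g, "' do not match the species set")
    maps <- msaRowMap(aln)

    mem <- list()
    for (sp in species) {
      it <- introns(models[[sp]][[g]])
      if (!nrow(it)) next
      for (r in seq_len(nrow(it))) {
        mp <- mapIntron(it$cds_offset[r], it$cds_length[r], maps[[sp]])
        mem[[length(mem) + 1L]] <- data.frame(
          species = sp, gene_id = g, index = it$index[r],
          column = mp$column, phase = mp$phase,
          cds_offset = it$cds_offset[r], cds_length = it$cds_length[r],
          length = it$length[r], seq = it$seq[r], donor6 = it$donor6[r],
          acceptor3 = it$acceptor3[r], stringsAsFactors = FALSE)
      }
    }
    if (!length(mem)) next
    mem <- do.call(rbind, mem)
    if (anyDuplicated(mem[, c("species", "column", "phase")]))
      stop("two introns of one gene map to the same (column, phase) in ",
           "group '", g, "': annotation defect")

    ## exact clusters, then slack chaining within phase
    for (ph in sort(unique(mem$phase))) {
      sub <- mem[mem$phase == ph, , drop = FALSE]
      cols <- sort(unique(sub$column))
      grp <- cumsum(c(1L, diff(cols) > slack))
      for (cl in unique(grp)) {
        clCols <- cols[grp == cl]
        rows <- sub[sub$column %in% clCols, , drop = FALSE]
        if (anyDuplicated(rows$species))
          stop("slack merge joins two introns of one gene in group '", g,
               "' (phase ", ph, "): annotation defect")
        tab <- table(rows$column)
        col <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
        presence <- paste(as.integer(species %in% rows$species),
                          collapse = "")
        siteRows[[length(siteRows) + 1L]] <- data.frame(
          site_id = sprintf("%s:c%d:p%d", g, col, ph), group = g,
          column = col, phase = ph, presence = presence,
          n_present = nrow(rows), stringsAsFactors = FALSE)
        memberList[[length(memberList) + 1L]] <- rows
      }
    }
  }
  if (dropped > 0L)
    message(dropped, " group(s) dropped: missing a species")
  sitesDf <- if (length(siteRows)) do.call(rbind, siteRows) else
    data.frame(site_id = character(0), group = character(0),
               column = integer(0), phase = integer(0),
               presence = character(0), n_present = integer(0),
               stringsAsFactors = FALSE)
  o <- order(sitesDf$group, sitesDf$column, sitesDf$phase)
  sitesDf <- sitesDf[o, , drop = FALSE]
  rownames(sitesDf) <- NULL
  new("IntronSiteSet", sites = sitesDf, species = species,
      members = memberList[o])
}

#' @rdname accessors
#' @export
setMethod("siteTable", "IntronSiteSet", function(x) x@sites)

#' @rdname accessors
#' @export
setMethod("siteMembers", "IntronSiteSet", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("siteSpecies", "IntronSiteSet", function(x) x@species)

setMethod("show", "IntronSiteSet", function(object) {
  cat("IntronSiteSet:", nrow(object@sites), "sites over",
      length(object@species), "species (",
      length(unique(object@sites$group)), "groups )\n")
})

#' Classify the coding-sequence change beside each mixed-presence site
#'
#' For every site carried by some but not all species, compares the number
#' of residues within `window` alignment columns of the site column between
#' present-species rows and absent-species rows. The signed difference
#' (median over rows, rounded) estimates the amino acids gained (+) or lost
#' (-) next to the intron; classes follow the bins 0, 1-3, >=4.
#'
#' @param siteSet an [IntronSiteSet-class].
#' @param msas named list (group -> `AAStringSet`).
#' @param window columns on each side of the site column (default 10).
#' @return data.frame with `site_id`, `group`, `column`, `phase`,
#'   `n_aa_delta`, `change_class`, `window_truncated`.
#' @export
classifyCodingChange <- function(siteSet, msas, window = 10L) {
  st <- siteTable(siteSet)
  species <- siteSpecies(siteSet)
  out <- list()
  for (i in seq_len(nrow(st))) {
    pres <- chars(st$presence[i]) == "1"
    if (all(pres) || !any(pres)) next
    aln <- msas[[st$group[i]]]
    w <- Biostrings::width(aln)[1]
    lo <- st$column[i] - window; hi <- st$column[i] + window
    truncated <- lo < 1L || hi > w
    lo <- max(1L, lo); hi <- min(w, hi)
    seg <- as.character(Biostrings::subseq(aln, lo, hi))[species]
    nRes <- nchar(gsub("-", "", seg, fixed = TRUE))
    delta <- round(stats::median(nRes[pres]) - stats::median(nRes[!pres]))
    cls <- if (abs(delta) == 0) "0" else if (abs(delta) <= 3) "1-3" else ">=4"
    out[[length(out) + 1L]] <- data.frame(
      site_id = st$site_id[i], group = st$group[i], column = st$column[i],
      phase = st$phase[i], n_aa_delta = as.integer(delta),
      change_class = cls, window_truncated = truncated,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site_id = character(0), group = character(0),
                      column = integer(0), phase = integer(0),
                      n_aa_delta = integer(0), change_class = character(0),
                      window_truncated = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect large single-species unspliced insertions in alignments
#'
#' Finds maximal runs of alignment columns in which exactly one species has
#' residues and all others have gaps, of at least `minAa` residues, not
#' overlapping any intron site column. At the default `minAa = 15` these are
#' the coding insertions long enough (45 nt) to become an intron.
#'
#' @param msas named list (group -> `AAStringSet`).
#' @param minAa minimum insertion length in residues.
#' @param siteSet optional [IntronSiteSet-class] whose site columns must not
#'   be overlapped.
#' @return data.frame with `group`, `species`, `start_col`, `end_col`,
#'   `length_aa`.
#' @export
detectUnsplicedInsertions <- function(msas, minAa = 15L, siteSet = NULL) {
  siteCols <- if (is.null(siteSet)) NULL else
    split(siteTable(siteSet)$column, siteTable(siteSet)$group)
  out <- list()
  for (g in names(msas)) {
    aln <- msas[[g]]
    mat <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(mat) <- names(aln)
    isRes <- mat != "-"
    nRes <- colSums(isRes)
    ## owner of a column: the single species with a residue, else 0
    owner <- integer(ncol(mat))
    single <- nRes == 1L
    owner[single] <- apply(isRes[, single, drop = FALSE], 2L, which)
    r <- rle(owner)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L || r$lengths[k] < minAa) next
      if (!is.null(siteCols) && !is.null(siteCols[[g]]) &&
          any(siteCols[[g]] >= starts[k] & siteCols[[g]] <= ends[k])) next
      out[[length(out) + 1L]] <- data.frame(
        group = g, species = rownames(mat)[r$values[k]],
        start_col = starts[k], end_col = ends[k],
        length_aa = r$lengths[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(0), species = character(0),
                      start_col = integer(0), end_col = integer(0),
                      length_aa = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
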