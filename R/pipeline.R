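## Stage orchestration: simulate -> homology -> events -> splice -> nmd ->
## repeats -> position, chained through on-disk artifacts so each stage can
## be re-run independently and reruns are byte-identical given the seeds.

defaultRunConfig <- function() {
  list(
    outdir = "intronTurnover_run",
    paths = list(annotations = NULL, genomes = NULL, msas = NULL,
                 tree = NULL, codon_usage = NULL),
    simulate = list(n_genes = 200L, seed = 1L),
    homology = list(slack = 0L, window = 10L, min_aa = 15L),
    splice = list(B = 10000L, seed = 101L),
    nmd = list(include_boundary = FALSE, log_length = FALSE),
    repeats = list(flank = 50L, word = 8L, max_mismatches = 2L),
    position = list(n_bins = 2L)
  )
}

#' Read and validate a pipeline run configuration
#'
#' @param config a YAML file path or a (possibly partial) named list;
#'   unspecified entries take the package defaults.
#' @return the merged configuration list.
#' @export
readRunConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- modifyList(defaultRunConfig(), config)
  given <- Filter(Negate(is.null), cfg$paths)
  missing <- given[!vapply(given, file.exists, logical(1))]
  if (length(missing))
    stop("configured path(s) do not exist: ",
         paste(unlist(missing), collapse = ", "))
  cfg
}

writeManifest <- function(dir, stage, params) {
  jsonlite::write_json(
    list(package = "intronTurnover",
         version = as.character(packageVersion("intronTurnover")),
         stage = stage, params = params),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
}

needArtifact <- function(path, priorStage) {
  if (!file.exists(path))
    stop("missing artifact '", path, "': run the '", priorStage,
         "' stage first", call. = FALSE)
  path
}

## Resolve stage inputs: simulated data in the run directory wins, otherwise
## user-supplied paths from the config.
resolveInputs <- function(cfg) {
  simDir <- file.path(cfg$outdir, "simulate")
  if (dir.exists(simDir)) {
    treePath <- file.path(simDir, "tree.nwk")
    tree <- readSpeciesTree(treePath)
    list(tree = tree,
         gff3 = setNames(file.path(simDir, paste0(tree$tip.label, ".gff3")),
                         tree$tip.label),
         fasta = setNames(file.path(simDir, paste0(tree$tip.label, ".fa")),
                          tree$tip.label),
         msaDir = file.path(simDir, "msa"))
  } else {
    if (is.null(cfg$paths$tree))
      stop("no simulated data and no configured tree: run the 'simulate' ",
           "stage first or configure paths", call. = FALSE)
    tree <- readSpeciesTree(cfg$paths$tree)
    list(tree = tree,
         gff3 = setNames(file.path(cfg$paths$annotations,
                                   paste0(tree$tip.label, ".gff3")),
                         tree$tip.label),
         fasta = setNames(file.path(cfg$paths$genomes,
                                    paste0(tree$tip.label, ".fa")),
                          tree$tip.label),
         msaDir = cfg$paths$msas)
  }
}

stageSimulate <- function(cfg) {
  sc <- cfg$simulate
  args <- sc[setdiff(names(sc), c("n_genes", "seed"))]
  names(args) <- gsub("_(\\w)", "\\U\\1", names(args), perl = TRUE)
  params <- do.call(simulationParams,
                    c(list(nGenes = sc$n_genes, seed = sc$seed), args))
  sim <- simulateTurnover(params)
  dir <- file.path(cfg$outdir, "simulate")
  writeSimulation(sim, dir)
  writeManifest(dir, "simulate", cfg$simulate)
  invisible(sim)
}

stageHomology <- function(cfg) {
  io <- resolveInputs(cfg)
  for (f in c(io$gff3, io$fasta))
    needArtifact(f, "simulate")
  models <- lapply(io$tree$tip.label, function(sp)
    readGeneModels(io$gff3[[sp]], io$fasta[[sp]], sp))
  names(models) <- io$tree$tip.label
  msaFiles <- sort(list.files(io$msaDir, pattern = "\\.faa$",
                              full.names = TRUE))
  if (!length(msaFiles)) stop("no alignments found under '", io$msaDir, "'")
  msas <- lapply(msaFiles, readProteinMSA)
  names(msas) <- sub("\\.faa$", "", basename(msaFiles))

  sites <- buildIntronSites(models, msas, slack = cfg$homology$slack,
                            species = io$tree$tip.label)
  dir <- file.path(cfg$outdir, "homology")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(siteTable(sites), file.path(dir, "sites.tsv"))

  members <- do.call(rbind, lapply(seq_along(siteMembers(sites)), function(i)
    cbind(site_id = siteTable(sites)$site_id[i], siteMembers(sites)[[i]],
          stringsAsFactors = FALSE)))
  writeTsv(members, file.path(dir, "site_members.tsv"))

  ## pooled intron table with contig context for the repeats stage
  pooled <- do.call(rbind, lapply(io$tree$tip.label, function(sp) {
    tab <- intronTableOf(models[[sp]])
    if (!nrow(tab)) return(NULL)
    tab$contig <- vapply(models[[sp]][tab$gene_id], function(m) m@contig,
                         character(1))
    tab$strand <- vapply(models[[sp]][tab$gene_id], function(m) m@strand,
                         character(1))
    tab
  }))
  writeTsv(pooled, file.path(dir, "introns.tsv"))

  writeTsv(classifyCodingChange(sites, msas, cfg$homology$window),
           file.path(dir, "coding_changes.tsv"))
  writeTsv(detectUnsplicedInsertions(msas, cfg$homology$min_aa, sites),
           file.path(dir, "insertions.tsv"))
  writeManifest(dir, "homology",
                c(cfg$homology, n_groups = length(msas),
                  n_groups_complete = length(unique(siteTable(sites)$group))))
  invisible(sites)
}

stageEvents <- function(cfg) {
  io <- resolveInputs(cfg)
  hdir <- file.path(cfg$outdir, "homology")
  sitesDf <- readTsv(needArtifact(file.path(hdir, "sites.tsv"), "homology"),
                     colClasses = c(presence = "character"))
  manifest <- jsonlite::read_json(file.path(hdir, "manifest.json"))
  nGenes <- as.integer(manifest$params$n_groups)
  recon <- reconstructEvents(sitesDf, io$tree, nGenes,
                             species = io$tree$tip.label)
  dir <- file.path(cfg$outdir, "events")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeEventTables(recon, file.path(dir, "events.tsv"),
                   file.path(dir, "rates.tsv"))
  writeTsv(data.frame(group = genesWithBoth(recon)),
           file.path(dir, "genes_with_both.tsv"))
  writeManifest(dir, "events",
                list(n_genes = nGenes,
                     n_root_ambiguous = rootAmbiguousCount(recon)))
  invisible(recon)
}

## Split member introns into novel (non-root gain sites) and conserved
## (root-ambiguous sites) using the events table.
memberClasses <- function(cfg) {
  hdir <- file.path(cfg$outdir, "homology")
  edir <- file.path(cfg$outdir, "events")
  members <- readTsv(needArtifact(file.path(hdir, "site_members.tsv"),
                                  "homology"))
  events <- readTsv(needArtifact(file.path(edir, "events.tsv"), "events"))
  events$class <- ifelse(events$gain_branch == "ROOT_AMBIGUOUS",
                         "conserved", "novel")
  members$class <- events$class[match(members$site_id, events$site_id)]
  members$lost <- nzchar(ifelse(is.na(events$loss_branches[
    match(members$site_id, events$site_id)]), "",
    events$loss_branches[match(members$site_id, events$site_id)]))
  members
}

stageSplice <- function(cfg) {
  members <- memberClasses(cfg)
  focal <- members[members$class == "novel", ]
  reference <- members[members$class == "conserved", ]
  if (!nrow(focal) || !nrow(reference))
    stop("need both novel and conserved introns for the splice stage")
  res <- lapply(c("donor_consensus_frac", "acceptor_consensus_frac",
                  "distinct_donor_motifs"), function(st)
    bootstrapStatistic(reference, focal, st, B = cfg$splice$B,
                       seed = cfg$splice$seed))
  dir <- file.path(cfg$outdir, "splice")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(bootstrapTable(res), file.path(dir, "bootstrap.tsv"))
  writeManifest(dir, "splice", cfg$splice)
  invisible(res)
}

stageNmd <- function(cfg) {
  members <- memberClasses(cfg)
  ann <- annotateNMD(members, includeBoundary = cfg$nmd$include_boundary)
  ann$group <- ann$class
  dir <- file.path(cfg$outdir, "nmd")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(ann[, c("site_id", "species", "gene_id", "class", "length",
                   "phase", "length_mod3", "is_3n", "has_ptc",
                   "first_ptc_offset", "nmd_visible")],
           file.path(dir, "annotations.tsv"))
  fit <- tryCatch(fitPTCModel(ann, logLength = cfg$nmd$log_length),
                  error = function(e) {
                    warning("PTC model not fitted: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
  if (!is.null(fit)) {
    writeTsv(fit$coefTable, file.path(dir, "model_coefficients.tsv"))
    if (!is.null(fit$waldTests))
      writeTsv(fit$waldTests, file.path(dir, "model_wald.tsv"))
    writeTsv(fit$contrasts, file.path(dir, "contrasts.tsv"))
  }
  writeManifest(dir, "nmd", cfg$nmd)
  invisible(fit)
}

stageRepeats <- function(cfg) {
  io <- resolveInputs(cfg)
  hdir <- file.path(cfg$outdir, "homology")
  members <- memberClasses(cfg)
  pooled <- readTsv(needArtifact(file.path(hdir, "introns.tsv"), "homology"))
  novel <- members[members$class == "novel", ]
  dir <- file.path(cfg$outdir, "repeats")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  genomes <- lapply(io$fasta, function(f) {
    g <- Biostrings::readDNAStringSet(f)
    names(g) <- sub("\\s.*$", "", names(g))
    g
  })
  for (i in seq_len(nrow(novel))) {
    row <- pooled[pooled$species == novel$species[i] &
                    pooled$gene_id == novel$gene_id[i] &
                    pooled$index == novel$index[i], ]
    if (nrow(row) != 1L) next
    ctg <- as.character(genomes[[row$species]][[row$contig]])
    if (row$strand == "-") ctg <- revComp(ctg)   # coords are coding-strand
    hits <- findJunctionRepeats(ctg, row$start, row$end,
                                flank = cfg$repeats$flank,
                                word = cfg$repeats$word,
                                maxMismatches = cfg$repeats$max_mismatches)
    if (nrow(hits))
      out[[length(out) + 1L]] <- cbind(
        site_id = novel$site_id[i], species = row$species,
        gene_id = row$gene_id, hits, stringsAsFactors = FALSE)
  }
  hitsDf <- if (length(out)) do.call(rbind, out) else
    data.frame(site_id = character(0), species = character(0),
               gene_id = character(0))
  writeTsv(hitsDf, file.path(dir, "repeats.tsv"))
  writeManifest(dir, "repeats", cfg$repeats)
  invisible(hitsDf)
}

stagePosition <- function(cfg) {
  members <- memberClasses(cfg)
  dir <- file.path(cfg$outdir, "position")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  members$relative_position <- members$cds_offset / members$cds_length
  perClass <- split(members$relative_position, members$class)
  lostPos <- members$relative_position[members$lost]

  rows <- list()
  for (cl in names(perClass)) {
    u <- uniformityChisq(perClass[[cl]], cfg$position$n_bins)
    rows[[cl]] <- data.frame(test = paste0("uniformity_", cl),
                             chisq = u$chisq, df = u$df, p = u$p,
                             stringsAsFactors = FALSE)
  }
  if (length(lostPos) >= 5) {
    u <- uniformityChisq(lostPos, cfg$position$n_bins)
    rows$lost <- data.frame(test = "uniformity_lost", chisq = u$chisq,
                            df = u$df, p = u$p, stringsAsFactors = FALSE)
  }
  if (all(c("novel", "conserved") %in% names(perClass))) {
    tw <- twoSampleChisq(perClass$novel, perClass$conserved)
    rows$two <- data.frame(test = "novel_vs_conserved", chisq = tw$chisq,
                           df = tw$df, p = tw$p, stringsAsFactors = FALSE)
  }
  writeTsv(do.call(rbind, rows), file.path(dir, "position_tests.tsv"))

  novel <- members[members$class == "novel", ]
  if (nrow(novel)) {
    usage <- intronCodonUsage(novel)
    ref <- if (is.null(cfg$paths$codon_usage)) syntheticCodonUsagePath()
           else cfg$paths$codon_usage
    corr <- usageCorrelation(usage, ref)
    writeTsv(data.frame(codon = names(usage), per_1000 = as.numeric(usage)),
             file.path(dir, "novel_codon_usage.tsv"))
    writeTsv(data.frame(rho = corr$rho, p = corr$p),
             file.path(dir, "usage_correlation.tsv"))
  }
  writeManifest(dir, "position", cfg$position)
  invisible(rows)
}

#' Run pipeline stages
#'
#' Orchestrates the analysis stages over one run directory. `"simulate"`
#' writes a synthetic data set; the analysis stages (`"homology"`,
#' `"events"`, `"splice"`, `"nmd"`, `"repeats"`, `"position"`) consume the
#' simulated data (or externally configured annotation/genome/alignment/tree
#' paths) and each other's TSV outputs; `"all"` chains every stage. A
#' `manifest.json` with the package version and full parameter echo is
#' written per stage; reruns with the same configuration and seeds produce
#' byte-identical TSVs.
#'
#' @param config configuration list or YAML path (see [readRunConfig()]).
#' @param stage one of "all", "simulate", "homology", "events", "splice",
#'   "nmd", "repeats", "position".
#' @param outdir overrides `config$outdir` when given.
#' @return invisibly, the last stage's main object.
#' @export
runPipeline <- function(config = list(), stage = "all", outdir = NULL) {
  stages <- c("simulate", "homology", "events", "splice", "nmd", "repeats",
              "position")
  stage <- match.arg(stage, c("all", stages))
  cfg <- readRunConfig(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  fns <- list(simulate = stageSimulate, homology = stageHomology,
              events = stageEvents, splice = stageSplice, nmd = stageNmd,
              repeats = stageRepeats, position = stagePosition)
  torun <- if (stage == "all") stages else stage
  res <- NULL
  for (s in torun) {
    message("[", s, "] running")
    res <- fns[[s]](cfg)
  }
  invisible(res)
}
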