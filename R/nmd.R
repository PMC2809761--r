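## NMD visibility of retained introns and the logistic PTC model.
##
## A transcript that retains an intron is visible to nonsense-mediated decay
## (NMD) when retention shifts the reading frame (length not a multiple of 3)
## or introduces an in-frame premature termination codon (PTC). The reading
## frame inside a retained intron is set by the intron phase: the first codon
## lying fully inside the intron starts at intron offset (3 - phase) mod 3.
## A canonical phase-2 donor GT(A/G)A therefore forces that first codon to
## TAA (Ochre) or TGA (Opal).

#' Offset of the first full retention-frame codon inside an intron
#'
#' @param phase intron phase (0, 1, or 2).
#' @return 0-based nucleotide offset into the intron, `(3 - phase) %% 3`.
#' @examples
#' retentionFrameOffset(0) # 0
#' retentionFrameOffset(2) # 1: the first internal codon of GT(A/G)A... is T(A/G)A
#' @export
retentionFrameOffset <- function(phase) {
  stopifnot(all(phase %in% 0:2))
  (3L - as.integer(phase)) %% 3L
}

#' Scan a retained intron for premature termination codons
#'
#' Searches the stop codons TAA/TAG/TGA at retention-frame offsets strictly
#' inside the intron. With `includeBoundary = TRUE` the codons spanning the
#' 5' exon-intron and intron-3' exon junctions are checked as well (the
#' boundary-spanning 5' codon is reported at the negative offset `-phase`).
#' Codons containing ambiguous bases are skipped and counted.
#'
#' @param intronSeq intron sequence, 5'->3' coding strand.
#' @param phase intron phase (0/1/2).
#' @param flank5,flank3 exonic flanks (required when `includeBoundary`;
#'   `flank5` needs >= `phase` nt, `flank3` >= 2 nt).
#' @param includeBoundary also check junction-spanning codons.
#' @return list with `length`, `length_mod3`, `is_3n`, `has_ptc`,
#'   `first_ptc_offset` (0-based intron offset of the first retained-frame
#'   stop, NA when none), `n_ambiguous_skipped` and `nmd_visible`
#'   (`!is_3n || has_ptc`).
#' @examples
#' scanPTC("GTAAGTTTTCCAG", phase = 2)  # PTC at offset 1 (codon TAA)
#' @export
scanPTC <- function(intronSeq, phase, flank5 = "", flank3 = "",
                    includeBoundary = FALSE) {
  len <- nchar(intronSeq)
  stopifnot(len >= 1L)
  phase <- as.integer(phase)
  off0 <- retentionFrameOffset(phase)
  nSkip <- 0L
  firstPtc <- NA_integer_

  if (includeBoundary && phase > 0L) {
    if (nchar(flank5) < phase)
      stop("flank5 must provide at least 'phase' nucleotides")
    codon <- paste0(substr(flank5, nchar(flank5) - phase + 1L, nchar(flank5)),
                    substr(intronSeq, 1L, 3L - phase))
    if (nchar(codon) == 3L) {
      if (grepl("[^ACGT]", codon)) nSkip <- nSkip + 1L
      else if (codon %in% STOP_CODONS) firstPtc <- -phase
    }
  }

  if (is.na(firstPtc)) {
    starts <- seq.int(off0 + 1L, by = 3L,
                      length.out = max(0L, (len - off0) %/% 3L))
    if (length(starts)) {
      codons <- substring(intronSeq, starts, starts + 2L)
      bad <- grepl("[^ACGT]", codons)
      nSkip <- nSkip + sum(bad)
      hit <- which(!bad & codons %in% STOP_CODONS)
      if (length(hit)) firstPtc <- starts[hit[1]] - 1L   # 0-based offset
    }
  }

  if (includeBoundary && is.na(firstPtc)) {
    lastEnd <- off0 + 3L * ((len - off0) %/% 3L)   # nt consumed inside intron
    if (lastEnd < len) {
      need <- 3L - (len - lastEnd)
      if (nchar(flank3) < need)
        stop("flank3 must provide at least 2 nucleotides")
      codon <- paste0(substr(intronSeq, lastEnd + 1L, len),
                      substr(flank3, 1L, need))
      if (grepl("[^ACGT]", codon)) nSkip <- nSkip + 1L
      else if (codon %in% STOP_CODONS) firstPtc <- lastEnd
    }
  }

  hasPtc <- !is.na(firstPtc)
  is3n <- len %% 3L == 0L
  list(length = len, length_mod3 = len %% 3L, is_3n = is3n, has_ptc = hasPtc,
       first_ptc_offset = firstPtc, n_ambiguous_skipped = nSkip,
       nmd_visible = !is3n || hasPtc)
}

#' Annotate an intron table with NMD visibility
#'
#' Vectorized wrapper around [scanPTC()] for an intron data.frame (columns
#' `seq` and `phase`; optional `flank5`/`flank3` columns for boundary mode).
#'
#' @param intronTable intron data.frame.
#' @param includeBoundary also check junction-spanning codons.
#' @return the input with columns `length_mod3`, `is_3n`, `has_ptc`,
#'   `first_ptc_offset`, `nmd_visible` appended.
#' @export
annotateNMD <- function(intronTable, includeBoundary = FALSE) {
  n <- nrow(intronTable)
  f5 <- if ("flank5" %in% names(intronTable)) intronTable$flank5 else rep("", n)
  f3 <- if ("flank3" %in% names(intronTable)) intronTable$flank3 else rep("", n)
  res <- lapply(seq_len(n), function(i)
    scanPTC(intronTable$seq[i], intronTable$phase[i], f5[i], f3[i],
            includeBoundary))
  intronTable$length_mod3 <- vapply(res, `[[`, integer(1), "length_mod3")
  intronTable$is_3n <- vapply(res, `[[`, logical(1), "is_3n")
  intronTable$has_ptc <- vapply(res, `[[`, logical(1), "has_ptc")
  intronTable$first_ptc_offset <- vapply(res, `[[`, integer(1),
                                         "first_ptc_offset")
  intronTable$nmd_visible <- vapply(res, `[[`, logical(1), "nmd_visible")
  intronTable
}

#' Fraction of introns with an internal PTC, by phase/donor subset
#'
#' For phase-2 introns with a canonical donor the fraction is 1 by
#' construction: GT(A/G)A places TAA or TGA as the first retained-frame codon.
#'
#' @param intronTable intron data.frame with `seq`, `phase`, `donor6`.
#' @param phase restrict to this phase (NULL = all).
#' @param canonicalDonorOnly restrict to canonical donors.
#' @return fraction of selected introns whose scan finds an internal PTC.
#' @export
phaseStopConstraint <- function(intronTable, phase = NULL,
                                canonicalDonorOnly = FALSE) {
  sel <- rep(TRUE, nrow(intronTable))
  if (!is.null(phase)) sel <- sel & intronTable$phase == phase
  if (canonicalDonorOnly) sel <- sel & donorIsConsensus(intronTable$donor6)
  tab <- intronTable[sel, , drop = FALSE]
  if (!nrow(tab)) return(NA_real_)
  ann <- annotateNMD(tab)
  mean(ann$has_ptc)
}

#' Logistic model of PTC occurrence in novel versus conserved introns
#'
#' Fits a binomial GLM of PTC presence on intron length (bp, or log bp),
#' intron phase (3-level factor), and a 4-level factor crossing intron group
#' (novel/conserved) with 3n class (length divisible by 3 or not), treatment
#' coded with conserved non-3n as reference. Returns Wald chi-square tests
#' per term, McFadden pseudo-R2, per-cell counts, and the three odds-ratio
#' contrasts of interest:
#' novel 3n vs novel non-3n, conserved 3n vs conserved non-3n, and the
#' novel-vs-conserved ratio of those two odds ratios (delta-method 95% CI).
#' An odds ratio above 1 means 3n introns are more likely to carry a PTC,
#' i.e. a deficiency of 3n PTC-free introns.
#'
#' @param annot data.frame with columns `length` (bp), `phase` (0/1/2),
#'   `group` ("novel"/"conserved") and `has_ptc` (logical); `is_3n` is
#'   derived from `length` when absent.
#' @param logLength model log(length) instead of raw bp.
#' @return object of class `ptcRegression`: list with `fit`, `coefTable`,
#'   `waldTests`, `contrasts` (data.frame of odds ratios with 95% CI),
#'   `pseudoR2` (McFadden), `cellCounts`, `separation` flag.
#' @export
fitPTCModel <- function(annot, logLength = FALSE) {
  stopifnot(all(c("length", "phase", "group", "has_ptc") %in% names(annot)))
  if (nrow(annot) < 50L) stop("need n >= 50 observations")
  if (!"is_3n" %in% names(annot)) annot$is_3n <- annot$length %% 3L == 0L
  annot$group <- factor(annot$group, levels = c("conserved", "novel"))
  if (any(is.na(annot$group))) stop("group must be 'novel' or 'conserved'")
  if (nlevels(droplevels(annot$group)) < 2L ||
      length(unique(annot$is_3n)) < 2L)
    stop("need >= 2 levels in group and 3n class")
  g3n <- factor(paste(annot$group, ifelse(annot$is_3n, "3n", "non3n"),
                      sep = "_"),
                levels = c("conserved_non3n", "conserved_3n",
                           "novel_non3n", "novel_3n"))
  dat <- data.frame(
    y = as.integer(annot$has_ptc),
    len = if (logLength) log(annot$length) else annot$length,
    phase = factor(annot$phase, levels = 0:2),
    g3n = g3n)

  fit <- suppressWarnings(glm(y ~ len + phase + g3n, family = binomial(),
                              data = dat))
  ## (quasi-)separation: non-convergence, NA or runaway coefficients
  separation <- !fit$converged || any(is.na(coef(fit))) ||
    max(abs(coef(fit)), na.rm = TRUE) > 15
  if (separation) {
    ## ridge-penalized fallback keeps estimates finite; marked non-standard
    warning("perfect or quasi-separation detected; returning a ",
            "ridge-penalized fit marked non-standard", call. = FALSE)
    if (length(unique(dat$y)) > 1L) {
      X <- model.matrix(~ len + phase + g3n, data = dat)[, -1]
      pen <- glmnet::glmnet(X, dat$y, family = "binomial", alpha = 0,
                            lambda = 1e-3)
      b <- c(pen$a0, as.numeric(pen$beta))
      names(b) <- c("(Intercept)", rownames(pen$beta))
      fit$coefficients[names(b)] <- b
    }
  }

  b <- coef(fit); V <- vcov(fit)
  orRow <- function(name, contrast) {
    est <- sum(contrast * b)
    se <- sqrt(drop(t(contrast) %*% V %*% contrast))
    data.frame(contrast = name, odds_ratio = exp(est),
               ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
               log_or = est, se_log_or = se, stringsAsFactors = FALSE)
  }
  cn <- names(b)
  unit <- function(term) as.numeric(cn == term)
  contrasts <- rbind(
    orRow("novel_3n_vs_non3n", unit("g3nnovel_3n") - unit("g3nnovel_non3n")),
    orRow("conserved_3n_vs_non3n", unit("g3nconserved_3n")),
    orRow("novel_vs_conserved",
          unit("g3nnovel_3n") - unit("g3nnovel_non3n") -
            unit("g3nconserved_3n")))

  wald <- tryCatch({
    a <- car::Anova(fit, type = "II", test.statistic = "Wald")
    data.frame(term = rownames(a), wald_chisq = a[, "Chisq"],
               df = a[, "Df"], p = a[, "Pr(>Chisq)"],
               stringsAsFactors = FALSE, row.names = NULL)
  }, error = function(e) NULL)

  llFull <- as.numeric(logLik(fit))
  llNull <- as.numeric(logLik(suppressWarnings(
    glm(y ~ 1, family = binomial(), data = dat))))
  pseudoR2 <- 1 - llFull / llNull

  ct <- as.data.frame(table(group_3n = dat$g3n, has_ptc = dat$y))
  sm <- summary(fit)$coefficients
  coefTable <- data.frame(term = rownames(sm), estimate = sm[, 1],
                          se = sm[, 2], z = sm[, 3], p = sm[, 4],
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fit = fit, coefTable = coefTable, waldTests = wald,
                 contrasts = contrasts, pseudoR2 = pseudoR2,
                 pseudoR2Type = "McFadden", cellCounts = ct,
                 separation = separation, logLength = logLength),
            class = "ptcRegression")
}

#' @export
print.ptcRegression <- function(x, ...) {
  cat("Logistic PTC model (binomial GLM",
      if (x$logLength) ", log length" else ", raw length", ")\n", sep = "")
  cat(sprintf("  McFadden pseudo-R2: %.3f%s\n", x$pseudoR2,
              if (x$separation) "  [SEPARATION FLAGGED: estimates unstable]"
              else ""))
  print(x$contrasts[, c("contrast", "odds_ratio", "ci_low", "ci_high")],
        row.names = FALSE)
  invisible(x)
}

#' Simulate an annotation table with designed PTC odds ratios
#'
#' Generates novel/conserved intron annotations whose true within-group
#' 3n-vs-non-3n odds ratios for PTC occurrence are set by design; used for
#' parameter-recovery checks of [fitPTCModel()].
#'
#' @param nNovel,nConserved group sizes.
#' @param orNovel,orConserved designed within-group odds ratios.
#' @param meanLength mean of the shifted-geometric length law (floor 45).
#' @param p3n probability of the 3n class.
#' @param lengthCoef,phaseCoef,intercept nuisance coefficients of the
#'   generating model (log-odds scale; `phaseCoef` has one value per phase).
#' @param seed RNG seed.
#' @return data.frame with columns length, phase, group, is_3n, has_ptc.
#' @export
simulatePtcTable <- function(nNovel = 307L, nConserved = 8810L,
                             orNovel = 3.0, orConserved = 1.6,
                             meanLength = 70, p3n = 1 / 3,
                             lengthCoef = 0.01,
                             phaseCoef = c(0, 0.2, 1.5),
                             intercept = -1.0, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n <- nNovel + nConserved
    group <- rep(c("novel", "conserved"), c(nNovel, nConserved))
    len <- 45L + rgeom(n, 1 / (meanLength - 44))
    is3n <- runif(n) < p3n
    len <- len - len %% 3L + ifelse(is3n, 0L, sample(1:2, n, replace = TRUE))
    len <- pmax(len, 45L)
    is3n <- len %% 3L == 0L
    phase <- sample(0:2, n, replace = TRUE)
    eta <- intercept + lengthCoef * (len - 60) + phaseCoef[phase + 1L] +
      ifelse(group == "novel" & is3n, log(orNovel), 0) +
      ifelse(group == "conserved" & is3n, log(orConserved), 0)
    hasPtc <- runif(n) < plogis(eta)
    data.frame(length = len, phase = phase, group = group, is_3n = is3n,
               has_ptc = hasPtc, stringsAsFactors = FALSE)
  })
}
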