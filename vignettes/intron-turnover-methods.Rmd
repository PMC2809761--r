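---
title: "Methods: intron turnover, splice-site strength, and NMD visibility"
author: "intronTurnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intron turnover, splice-site strength, and NMD visibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Spliceosomal intron number varies enormously across eukaryotes, and in some
lineages — *Drosophila* prominently among them — intron gain is still an
active process. Comparing fully annotated orthologous genes across a dated
species phylogeny lets one polarize intron presence/absence patterns into
gain and loss events, measure per-branch turnover rates, and ask what
distinguishes newly gained introns from ancient, conserved ones: weaker
splice sites, in-frame premature termination codons (PTCs) that expose a
retained intron to nonsense-mediated decay (NMD), direct sequence repeats at
the splice junctions (a non-homologous end-joining signature), a 5'-biased
positional distribution, and a lack of codon-usage signal.

`intronTurnover` implements that comparative pipeline end to end, together
with a seeded simulator that generates genomes, annotations, protein
alignments, a dated tree, and a ground-truth event table, so that every
stage is testable without any external data.

# Conventions

All user-visible coordinates are 1-based and inclusive, the R/Bioconductor
idiom; GFF3 on disk is likewise 1-based inclusive and is read through
`rtracklayer`. Minus-strand genes are strand-normalized when a `GeneModel`
is constructed, so intron sequences, donors, and acceptors always read
5'→3' on the coding strand and every downstream module is strand-agnostic.
The quantity `cds_offset` — the number of coding nucleotides upstream of an
intron's insertion point — is convention-free; the intron phase is
`cds_offset mod 3`.

# Homologizing introns

An intron interrupting a coding sequence after `cds_offset` nucleotides
lies in (or immediately before) the codon of residue
`floor(cds_offset / 3)`. Mapping that residue through the species' row of
the group's protein alignment yields a (column, phase) pair; introns of
different species sharing that pair are homologous and become one
presence/absence *site*. The default column tolerance (`slack`) is 0:
exactness keeps the Dollo input unambiguous, and the simulator's alignments
are exact by construction. For noisy real annotations, `slack` can be
raised; clusters of equal phase within `slack` columns are then chained,
and a chain that would join two introns of one gene is reported as an
annotation defect rather than merged silently.

Only ortholog groups with one gene in every species are analyzed; groups
missing a species are dropped with a logged count. Coding-sequence changes
beside a site are classified by comparing residue counts between
present-species and absent-species rows in a window of `W = 10` columns on
each side of the site column (the bins are 0, 1–3, and ≥4 amino acids).
The window size is a design choice — wide enough to span the 1–3-residue
changes the classifier targets, narrow enough not to absorb neighbouring
indels. Large unspliced insertions are maximal runs of ≥15 single-species
residue columns (15 aa = 45 nt, the smallest insertion long enough to
become an intron) not overlapping any intron site; runs are detected for
single species, the clade generalization being left to the caller's
alignment preprocessing.

# Dollo parsimony

Each intron site is assumed to have been gained exactly once. The gain node
is the most recent common ancestor (MRCA) of the species carrying the
intron; losses are the topmost edges of the maximal all-absent subtrees
inside the gain clade. This reconstruction attains the minimum loss count
over all single-gain placements (verified exhaustively in the tests).

A site whose gain node is the tree root cannot be polarized: the intron may
be ancestral, or gained on the root itself. Such sites are flagged
root-ambiguous and their unplaceable root event is reported separately and
counted on neither root-child branch. Their *losses*, however, are ordinary
loss events and are tallied — losses of ancestral introns are real losses,
and treating them otherwise would empty the loss side of the analysis.

Rates are events per gene per Bya: `n_events / n_genes / (branch My /
1000)`, with the fixed analyzed-gene count as denominator for every branch
(no attempt to track branch-specific gene content). Zero-length branches
with events report an infinite rate with a warning. Dollo parsimony remains
biased towards inferring parallel losses as gains on long isolated
branches; no correction is applied, matching the method's standard form,
and the event-recovery test quantifies exactly which simulated sites are
recoverable (those whose present-leaf MRCA equals the true gain node and
whose loss branches each leave a present relative under their parent).

# Splice-site strength and motif diversity

Strength is the fraction of introns carrying the strong consensus motifs:
`GT(A/G)AGT` at donor positions +1..+6 and `CAG` at acceptor positions
−3..−1; ambiguous bases never match. Significance is assessed exactly as a
percentile bootstrap: `B` samples of the focal size are drawn with
replacement from the reference introns, the statistic is computed per
sample, and the 2.5th/97.5th empirical percentiles (linear interpolation
between order statistics; no BCa correction) form the interval. The focal
set is significantly different when its observed value falls outside.
Focal-set resampling is available as an option purely to display
within-focal variance. The reference set should exclude the focal introns;
the pipeline's splice stage uses the conserved (root-ambiguous) sites as
reference, which excludes novel introns by construction. The third
statistic, the number of distinct donor 6-mers per sample, measures motif
diversity.

# NMD visibility and the PTC model

A transcript retaining an intron is NMD-visible if retention shifts the
reading frame (intron length not a multiple of 3) or puts an in-frame stop
(TAA/TAG/TGA) inside the retained intron. The first full codon inside a
retained intron starts at intron offset `(3 − phase) mod 3`; a canonical
phase-2 donor `GT(A/G)A` therefore begins with TAA or TGA — every such
intron carries a PTC by construction, which is why phase dominates the
regression below. By default only codons wholly inside the intron are
scanned, since the phase-2 argument concerns "full" internal codons;
junction-spanning codons can be included for sensitivity analysis
(`includeBoundary = TRUE`). Frameshifts are assumed NMD-visible without
scanning downstream exons.

The PTC model is a binomial GLM of PTC presence on intron length (raw bp by
default; log-length optional), phase (3-level factor), and a 4-level factor
crossing intron group (novel/conserved) with 3n class, treatment-coded with
conserved non-3n as reference. Reported are Wald chi-square tests per term,
McFadden's pseudo-R² (the fit metric is a package choice and is labelled in
the output), per-cell counts, and three odds-ratio contrasts: novel 3n vs
novel non-3n, conserved 3n vs conserved non-3n, and their ratio
(delta-method 95% CI on the log scale). An odds ratio above 1 means 3n
introns are more likely to carry a PTC — a deficiency of 3n PTC-free
introns. Under perfect or quasi-separation the fit is flagged, a weakly
ridge-penalized fit replaces the runaway estimates, and the result is
marked non-standard.

`simulatePtcTable()` generates annotation tables from that same model
family with designed within-group odds ratios, so CI recovery can be
checked at realistic group sizes (307 novel vs 8,810 conserved).

# Junction direct repeats

`findJunctionRepeats()` is a dotplot-style seed-and-extend: window A covers
`flank = 50` bp on each side of the 5' splice site, window B the same
around the 3' site (both truncated at the intron midpoint when the intron
is shorter than two windows). Exact `word = 8` matches between the windows
seed diagonals; per diagonal, the inclusion-maximal gapless segment pairs
containing an exact 8-run with at most `maxMismatches` mismatches, trimmed
to match at both ends, are reported with identities such as `16/18`
(matches/span). With `maxMismatches = 0` the hit set is exactly the
exact-match dotplot; the mismatch-tolerant mode (default 2) reflects that
reported repeat identities in this literature are typically imperfect.
Only direct (same-strand) repeats are searched. A hit "overlaps the 5'
splice site" when copy A covers the first intron base, and "overlaps the
3' splice site" when copy B covers the first base after the intron — i.e.
the copies bracket the spliced segment the way an insertion-borne
duplication would. How neighbouring exact matches merge into one reported
identity is not standardized in the literature; the per-diagonal
inclusion-maximal chaining used here is one consistent choice and is
validated against a brute-force enumeration over all substring pairs.

# Positional bias and codon usage

Relative position is `cds_offset / cds_length` in [0, 1). The uniformity
test bins positions into `nBins` equal-width bins (default 2: the minimal
5'-half vs 3'-half reading, since published chi-squares of this kind rarely
state their binning) and computes the Pearson chi-square against uniform
expectation; below 5 expected per bin it warns and, for two bins, falls
back to an exact binomial. The two-sample comparison is the 2×2 Pearson
chi-square (no continuity correction). Intron "codon" usage reads codons in
the retention frame — the frame in which the PTC logic operates — pools
counts over introns, scales per 1,000 codons, and is compared to a
reference table by Spearman rank correlation (average ranks, two-sided).
A synthetic reference table ships for tests (`syntheticCodonUsagePath()`);
real analyses should supply an organism table.

# The simulator and what it does (not) emulate

`simulateTurnover()` draws, per gene, a CDS length (log-normal around 450
codons), a stop-free random CDS, and Poisson(2.45) ancestral introns; it
then walks the dated tree placing gains as a Poisson process
(`gainRate × genes × branch My / 1000`) and losses by thinning carried
introns at the analogous rate. Each site is gained exactly once — colliding
(gene, position) draws are re-drawn — so the truth is Dollo-consistent by
construction. Insertion positions follow the one-parameter 5'-skew law with
density ∝ (1−r)^β on [0, 1): β = 0 is uniform, larger β shifts the ECDF
left; β is a controllable stand-in for the empirically observed 5' bias,
chosen for invertibility. Intron lengths are shifted-geometric with floor
45 nt (mean 70 nt); the 3n class is forced by a ±1–2 nt adjustment after
the draw. Donors are canonical with probability `pCanonicalDonor`,
acceptors `CAG` with `pCanonicalAcceptor`; retention-frame codons clear of
the fixed ends are stops at rate `ptcDensity`.

Defaults are the package's study conditions, chosen once: a 9-taxon
ultrametric tree of root depth 40 My with the standard *Drosophila*
topology; gain and loss rates 2.8 and 7 events/gene/Bya (the gain rate is
the highest lineage rate reported in this literature, and the 2.8:7 ratio
mirrors the observed preponderance of losses over polarizable gains);
~2.45 ancestral introns per gene (8,810 introns / 3,593 genes); 45%
canonical donors and 60% canonical acceptors; stop density 3/64 (the
random-sequence expectation); β = 1; 13% of gains changing 1–3 flanking
codons (40/307); 5% per gene and species large insertions (~180/3,593); 2%
of gains carrying a planted perfect 10 bp repeat spanning both junctions
(~7/307 dotplot cases).

Structural variants are modelled as residue insertions: a coding-change
gain adds 1–3 codons immediately 5' of the intron in all descendants of the
gain node (persisting even if the intron is later lost — sequence change is
independent of splicing), and large unspliced insertions add 15–40
species-private codons. Planted repeats rewrite the intron's ends so that a
perfect copy of the first `repeatLength` intron bases reappears across the
3' junction, extending two bases into the exon; this preserves intron
length, the `GT`/`AG` ends, and the drawn donor, at the cost of sometimes
overriding the drawn acceptor base at −3.

What the simulator does **not** emulate: sequence evolution on exons (no
substitutions — alignments are exact), alignment error, annotation error,
paralogy, UTR introns, expression or EST data, and genuinely
homoplasious gains. Passing the round-trip tests therefore demonstrates
correctness of the inference machinery under clean homology, not
robustness to noisy gene prediction — the `slack` parameter and the
annotation-defect errors are the designed entry points for that noise.

# Numerical choices and degenerate inputs

* Longest isoform by amino-acid length, ties broken lexicographically by
  transcript id; genes with a CDS length not divisible by three or an
  internal stop are skipped with a warning (frameshifts, real or from
  sequencing error, are indistinguishable here and all are excluded).
* Bootstrap RNG: one seeded stream per summary, seed echoed in the output;
  every pipeline stage takes an explicit seed, and a rerun with the same
  configuration produces byte-identical TSVs.
* Percentile CIs use `quantile(type = 7)` (linear interpolation), the R
  default, applied to the resampled vector.
* All-absent presence vectors, empty intron sets, constant usage vectors,
  and zero marginals raise explicit errors rather than returning NA.
* Problem sizes in the shipped checks (500 simulated genes for event
  recovery, 10,000 scanner triples, 200 bootstrap replicates, 100
  regression replicates, 200 repeat windows, 1,000 calibration runs) were
  chosen to give tight Monte-Carlo error while keeping a full run in a few
  minutes on one core.

# Known limitations

* Dollo parsimony cannot see multiple independent losses collapsing to a
  sibling pair, nor distinguish parallel loss from gain on isolated long
  branches; the per-branch tables inherit that bias and the simulator's
  truth quantifies it.
* The coding-change classifier reports a net amino-acid delta only; it does
  not reconstruct unspliced remnants when insertion and intron boundaries
  differ.
* The NMD model has no "faux 3' UTR" distance term and no exon-junction
  complex rules; visibility is the frame/PTC dichotomy.
* The repeat finder searches direct repeats only; inverted repeats are out
  of scope.

# Running the pipeline

```r
library(intronTurnover)
cfg <- list(outdir = "run1",
            simulate = list(n_genes = 200, seed = 1),
            splice = list(B = 10000, seed = 101))
runPipeline(cfg, "all")
```

Each stage writes TSVs plus a `manifest.json` echoing the package version
and all parameters; the manifest plus the seeds suffice to reproduce any
output byte-identically. External data can be analyzed by configuring
`paths` (per-species GFF3 + FASTA named `<species>.gff3` / `<species>.fa`,
a directory of per-group aligned FASTA files, and a rooted newick tree with
branch lengths in My) and starting from the `homology` stage.
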