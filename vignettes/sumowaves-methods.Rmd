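---
title: "Methods: models, parameters and design choices in sumowaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sumowaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumowaves)
```

`sumowaves` post-processes four assay types collected over an adipocyte
differentiation time course — nascent transcription (SLAM-seq), total
mRNA (3'-end counting), endogenous SUMO-2/3 proteomics, and SUMO ChIP-seq
— and integrates them through stage-specific time-course modules. This
vignette is the package's own account of the models it implements, the
parameters that matter, and the choices made where the design was open.

## Nascent transcription from T>C conversions

Metabolic labeling with 4-thiouridine followed by alkylation converts a
fraction of the uridines of newly made transcripts so that reads from
labeled RNA show T>C mismatches against the reference. The package counts,
per 3'UTR and sample:

- `total_reads`: reads with at least one aligned base in the UTR. When a
  read overlaps several UTRs, the largest overlap wins and exact ties go
  to the lexicographically smaller gene id — a deterministic convention.
- `labeled_reads`: the subset with ≥ 1 transcript-strand T>C event, i.e.
  reference T → read C on plus-strand genes and reference A → read G on
  minus-strand genes, restricted to UTR positions, excluding masked
  positions (an externally supplied VCF of SNPs, since a homozygous SNP
  mimics a conversion in every read) and bases below the minimum base
  quality.

The base-quality default is Q27, the documented default of the standard
SLAM-seq counting pipeline; whether an SNP filter is applied, and with
which positions, is left to the caller because different upstream
pipelines resolve SNPs differently.

**Detection correction.** With per-T conversion probability `c` well
below 1 (a realistic value is a few percent), many labeled reads carry no
observable conversion, so the raw ratio `labeled/total` underestimates
the nascent fraction. For each gene we compute the exact detection
probability by enumerating all read windows over its UTR:

    P(detect | labeled) = mean over windows w of 1 - (1 - pC)^nT(w)

with `pC = c(1-e) + (1-c)e/3` for per-base error rate `e`, and the error
floor `P(detect | unlabeled)` from `pC = e/3`. The method-of-moments
estimate of the labeled fraction `f` then solves
`q = f·P_detect + (1-f)·P_error` for the observed rate `q`, clipped to
[0, 1]. Its delta-method standard error is reported alongside. This
estimator assumes reads start uniformly within the UTR — exactly the
generative model of the synthetic module — and will be slightly
mis-calibrated under strong coverage bias in real data.

## Median-of-ratios normalization

Size factors are the classical median-of-ratios:
`s_j = median_g ( k_gj / gm_g )` over genes `g` with positive counts in
every library, where `gm_g` is the geometric mean across libraries; the
median of an even-length list is the mean of the central pair. Estimation
fails loudly when no gene is positive everywhere. Because the
pseudo-reference `gm_g` is computed from the matrix itself, factors are
defined only up to a common scale: scaling one library by `c` multiplies
its factor *ratio* to every other library by exactly `c`, and that ratio
form is what the test suite asserts. The estimator also assumes most
genes are not differentially expressed; its consistency check therefore
runs on a flat-profile simulation, and users should expect composition
bias when a majority of features change.

Labeled (nascent) counts are normalized with the factors learned from the
total-RNA counts (`cross_normalize()`), never re-estimated from the
labeled counts themselves: the steady-state assay carries the global
normalization and the nascent assay inherits it.

## SUMO proteomics post-processing

The evidence table mirrors a modification-specific peptide export:
sequence, protein, peptide start, SUMO positions with localization
probabilities, delta score, decoy flag, observed diagnostic ions, a
SUMO-family flag for the source protein, and one intensity column per
(time point × replicate).

**Filtering.** A SUMO-modified record is accepted iff every localization
probability exceeds 0.75, at least one diagnostic remnant ion of the
DVFQQQTGG stub is observed (from the list b2-DV … b9-DVFQQQTGG, QQ, FQ,
FQQ; the count threshold is configurable), it is not a decoy, and — when
a SUMO site sits on the peptide's C-terminal lysine and the *next* residue
in the protein is neither Asp nor Glu — its delta score exceeds 40. The
next-residue reading of "not preceding an aspartic or glutamic acid"
follows the cleavage logic of the Asp-N/Glu-N digest: a C-terminal
lysine followed by D/E is an expected cleavage product, anything else
needs stronger score evidence. Protein sequences are therefore a required
input for this rule; a missing protein is an evidence error, and a
peptide at the protein C-terminus (no next residue) falls under the rule.
Each rejection carries exactly one reason — the first failing rule in the
order localization, diagnostic, decoy, delta — so rejection tallies are
unambiguous. The localization threshold applies to *each* site of a
multiply-modified peptide (the strict reading). Records without SUMO
modifications, e.g. peptides of SUMO itself, are subject only to the
decoy rule. Multiply-sumoylated peptides survive only when every one of
their sites is also evidenced by an accepted singly-modified peptide.

**Sites, density, equilibrium.** Site position is
`peptide_start + position-in-peptide − 1`; site intensity is the sum of
supporting peptide intensities; proteins with ≥ 1 site form the target
set. SUMO density divides the summed site intensity of each replicate by
that replicate's protein input (mg) and reports mean ± SD per time point.
The equilibrium partitions intensity per time point into six pools:
SUMO-modified peptides from SUMO-family proteins are **chains**; from any
other protein, **target conjugation**; unmodified SUMO-derived peptides
ending in QQTGG are **mature free** SUMO-2/3; containing but not ending
in QQTGG they are **immature SUMO-2** (propeptide tail starting VY) or
**immature SUMO-3** (tail starting SASRGSVPTPNRCP); everything else is
**internal**. A post-QQTGG tail matching neither propeptide is classed
internal and logged — it indicates a sequence the rule set does not know.
Fractions sum to 1 per time point by construction.

**LFQ summarization.** Replicate intensities are averaged per time point
with zeros treated as missing (an LFQ zero is a non-detection, not a
measured zero), log2-transformed, and missing values are imputed from a
downshifted Gaussian with width 0.3 × and downshift 1.8 × the row SD —
the conventional proteomics default for left-censored missingness —
falling back on the global SD when a row has fewer than two observations.
Imputation is seeded and reproducible. Rows with no observation are
dropped with a message. Row Z-scores finish the transform.

**Remnant mass.** `remnant_mass()` sums residue monoisotopic masses with
no terminal water, because the remnant is conjugated through an
isopeptide bond rather than being a free peptide; for DVFQQQTGG this
gives 960.4301 Da and C41H60N12O15, and the function is additive over
concatenation by construction.

## ChIP landscape

Union peaks merge overlapping *or bookended* intervals (BEDtools-merge
default) via `GenomicRanges::reduce`; the result is disjoint, sorted,
order-invariant and idempotent. Reads count toward the union peak
containing their 5'-most aligned base (leftmost for forward, rightmost
for reverse alignments), so a fragment spanning two peaks is counted
once.

Time-varying occupancy uses `nb_lrt()`: a negative-binomial likelihood
ratio between one-mean-per-time-point and grand-mean models with a shared
method-of-moments dispersion (`disp = max((s² − μ)/μ², 1e-8)` from the
pooled within-group variance), referred to χ² with (groups − 1) df,
BH-adjusted. This is a deliberate, documented stand-in for a
shrinkage-based GLM test: it claims calibration (type-I error at or below
nominal on null simulations, verified in the suite) and power on large
shifts, not numerical equality with any particular GLM implementation.
All-zero regions get p = 1; single-replicate designs are refused because
the dispersion is inestimable. The fold-change gate for flagging
(padj ≤ 0.05, FC > 1.5) uses max-over-time-points vs min of the
normalized means with a pseudocount of 1 — the contrast is a package
convention, chosen because it is symmetric in time and insensitive to
which time point is baseline.

Annotation classifies each summit with precedence promoter-TSS > exon >
intron > distant promoter > intergenic, with a promoter window of
−1000..+100 around the TSS (strand-aware) and a distant-promoter window
of −10000..−1000, both configurable; the nearest gene is by
summit-to-TSS distance with ties to the smaller gene id. Mean profiles
are computed in counts-per-million mapped reads at a fixed step (default
10 nt) around anchors, strand-obliviously; anchors nearer than half a
window to a contig edge are skipped and logged.

## Time-course modules and integration

Row Z-scoring flags constant rows and zeroes them rather than producing
NaNs. Clustering is Euclidean k-means with k-means++ seeding and ten
restarts keeping the lowest inertia, deterministic given the seed; the
hierarchical dendrogram often drawn next to such heatmaps is a display
device, and assignment never depends on it. Each module's stage is the
argmax of its centroid's mean over the stage's time points under the
stage map (default: first time point PA, last MA, middle CE), with exact
ties broken PA > CE > MA and warned about. The number of modules `k` is a
configuration parameter: real datasets in this field use k around 10–12,
while the synthetic default is `k = 3` matching the three planted stages.

Per-feature Pearson correlation between two datasets requires ≥ 3 shared
time points; features with zero variance in either profile have undefined
r and are excluded from the 10 equal-width bins over [−1, 1]
(right-closed, −1 in the lowest bin) but counted, rather than being
assigned r = 0 — an explicit decision to keep the bins interpretable.
Overrepresentation uses the exact hypergeometric upper tail
`P(X ≥ k)` and BH adjustment via `stats::p.adjust`.

## The synthetic-data module

The generators define the study conditions for all tests. Defaults: four
time points (d−2, d1, d3, d7) spanning PA/CE/MA, three replicates, 90
genes in three equal stage modules whose mean profiles (600 at the
module's stage time points, 60 elsewhere, with 0.15-SD per-gene
log-normal wobble and NB dispersion 0.05) put module centroids about four
within-module SDs apart on the z-score scale; labeled fraction 0.3,
conversion rate 0.02 per T (the per-T efficiency is not a settled
quantity in this system, so it is configurable and never asserted),
sequencing error 1e-3, 50-base reads, UTRs of 300–1500 bp on toy contigs
of ≤ 100 kb. Each generator draws from its own stream derived from the
master seed, so adding a generator never perturbs another's output, and
fixed seeds give byte-identical files. Read depth per gene is fixed at
`depth` rather than Poisson-distributed so fixture sizes are exact.
Ground truth travels in `truth_`-prefixed sidecar tables and never in the
analysis-facing files.

What the generators deliberately do not emulate: coverage bias and
fragment-length effects in reads, quality-score variation (all bases are
Q40; the quality filter is exercised with hand-built reads), isotope
envelopes or retention times in MS, correlated replicates, or chromatin
copy-number structure. Passing tests therefore demonstrate correctness of
the computations under the stated model, not robustness to every artifact
of real data.

Problem sizes in the shipped suite (90–300 genes, ≤ 1000 reads per
fixture, 500 null regions, 240-record peptide tables) were chosen so the
statistical assertions have adequate power while the whole suite runs in
about a minute.

## Known limitations

- The NB LRT stand-in shares no information across features; for small
  replicate numbers it is conservative relative to shrinkage GLMs.
- The labeled-fraction estimator assumes uniform read starts in the UTR.
- Median-of-ratios is composition-biased when most features change.
- Peak annotation uses summits only; a peak body spanning a TSS but
  summitting in an intron is called intron.
- The pipeline orchestrates the synthetic demonstration end to end; on
  real data the per-stage functions are the intended interface, fed from
  the upstream tools' outputs.
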