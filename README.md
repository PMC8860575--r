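# sumowaves

Multi-omics time-course analysis of the sumoylation pathway during
adipocyte differentiation.

During 3T3-L1 adipogenesis, cells move from a pre-adipocyte (PA) stage
through clonal expansion (CE) to mature adipocytes (MA), and the SUMO-2/3
pathway is remodeled in waves alongside the transcriptional program.
`sumowaves` provides the analysis layer for studying this process from
four assay types at once, for computational biologists who have already
run the upstream tools (aligner, peak caller, search engine) and need a
tested, reproducible post-processing pipeline:

- **SLAM-seq nascent transcription** — count total and labeled reads per
  3'UTR, where a *labeled read* carries ≥ 1 T>C conversion on the
  transcript strand (reference T→C on plus-strand genes, A→G on
  minus-strand genes), with SNP masking and base-quality filtering; then
  estimate the per-gene nascent fraction by deconvolving the observed
  labeled-read rate with the exact per-gene detection probability.
- **Normalization** — median-of-ratios size factors
  (`s_j = median_g ( k_gj / (prod_j' k_gj')^(1/m) )`, over genes positive
  in every library), and cross-normalization of labeled counts with the
  factors learned from the total-RNA assay.
- **Endogenous SUMO proteomics** — post-search filtering of
  modification-specific peptide evidence (localization probability > 75%,
  diagnostic remnant ions of the DVFQQQTGG stub, decoy removal, delta
  score > 40 for a C-terminal lysine not preceding Asp/Glu), resolution of
  multiply-sumoylated peptides against single-site evidence, site mapping,
  SUMO density (summed site intensity per mg input), and the SUMO
  equilibrium: partitioning intensity into target-conjugated, chain,
  mature free, immature SUMO-2, immature SUMO-3 and internal pools by the
  QQTGG rules.
- **SUMO ChIP landscapes** — union peak sets (BEDtools-merge semantics),
  5'-base read counting per union peak, a negative-binomial
  likelihood-ratio test for time-varying occupancy (padj ≤ 0.05 and
  fold change > 1.5), genomic annotation (promoter-TSS / exon / intron /
  distant promoter / intergenic) and CPM mean profiles around summits.
- **Integration** — row Z-scores, k-means stage modules (PA/CE/MA),
  per-gene Pearson correlation between datasets with 10-bin summaries,
  hypergeometric overrepresentation with Benjamini–Hochberg correction,
  and Venn overlap counts.

A first-class synthetic-data module generates every input format (FASTA,
BED, SAM with MD/NM tags, VCF masks, peptide TSVs, count matrices, peak
sets) with known ground truth, so the full pipeline is testable end to end
without any download.

## Worked example

```r
library(sumowaves)

remnant_mass("DVFQQQTGG")
# SUMO-2/3 remnant: 960.4301 Da (C41H60N12O15)

cfg <- sim_config(seed = 1)               # 90 genes, d-2/d1/d3/d7, 3 reps
tc  <- gen_timecourse_counts(cfg)
sf  <- size_factors(tc$counts)
round(sf[1:4], 3)
#> d-2_1 d-2_2 d-2_3  d1_1
#> 0.883 0.433 0.685 0.512

norm <- cross_normalize(tc$counts, sf)
tp   <- sub("_[0-9]+$", "", colnames(norm))
avg  <- sapply(unique(tp), function(t) rowMeans(norm[, tp == t]))
z    <- zscore_rows(log2(avg + 1))
mods <- assign_stages(cluster_modules(z$matrix, k = 3, seed = 1),
                      default_stage_map(cfg$time_points))
table(stage = mods$stage, truth = tc$truth$modules$truth_stage)
#>      truth
#> stage CE MA PA
#>    CE 30  0  0
#>    MA  0 30  0
#>    PA  0  0 30

pep <- gen_peptide_table(cfg)
acc <- resolve_multiply_sumoylated(
  filter_peptides(pep$table, pep$proteins)$accepted)
eq  <- classify_equilibrium(acc)
round(eq$fractions[, 1:2], 3)
#>                         d-2    d1
#> conjugated_to_targets 0.635 0.635
#> chains                0.068 0.073
#> free_mature           0.072 0.073
#> immature_sumo2        0.088 0.068
#> immature_sumo3        0.068 0.070
#> internal              0.069 0.081
```

The module table shows perfect recovery of the planted PA/CE/MA structure
(every gene lands in the module of its true stage), and the equilibrium
fractions sum to 1 per time point: most intensity sits in
target-conjugated SUMO, with the remainder split among chains, free
mature SUMO and the two immature propeptide forms.

The full pipeline (counts → modules, SLAM reads → conversion counts,
peptides → sites/density/equilibrium, peaks → union → differential
regions, plus a provenance manifest) runs from one YAML configuration:

```r
cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                   package = "sumowaves"))
cfg$out_dir <- "demo_out"
run_pipeline(cfg)
```

or from the shell via the thin wrapper
`inst/scripts/sumowaves.R run --config demo_config.yaml`.

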