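# igaseqr

Analysis of **IgA-SEQ** experiments in R. IgA-SEQ flow-sorts a microbial
community (fecal or salivary) into IgA-coated (IgA+) and uncoated (IgA−)
fractions and sequences the 16S rRNA gene of each; taxa preferentially bound
by secretory IgA are candidate immune-reactive organisms, even when their
overall relative abundance does not separate patients from controls. The
motivating application is axial spondyloarthritis (axSpA) versus healthy
controls, with the BASDAI score (0–10) as the disease-activity readout, but
the machinery is generic to any paired sorted-fraction design.

## What it computes

For a taxon with relative abundances *a⁺*, *a⁻* in a subject's two
fractions, the **IgA index**

> index = −(log *a⁺* − log *a⁻*) / (log *a⁺* + log *a⁻*)

is a log ratio bounded in [−1, 1], positive when the taxon is
preferentially coated. Around this statistic the package provides:

- **IO and QC** — TSV count tables and sample manifests, newick trees,
  subject-level pairing of fractions (`pairFractions()`), the inclusive
  7,500-read depth rule (`filterByDepth()`), prevalence filtering,
  taxonomic aggregation, pseudocounted relative abundances.
- **Diversity** — Observed / Shannon / inverse Simpson alpha diversity with
  rank-sum group tests; unweighted UniFrac, PCoA, PERMANOVA.
- **IgA scoring** — per-taxon index matrices, within-group
  enrichment/depletion calls (one-sample Wilcoxon signed-rank vs 0,
  Benjamini–Hochberg FDR), between-group index comparisons, overlap counts
  of called taxa between groups.
- **Disease correlation** — Spearman correlation of the index (or relative
  abundance) with BASDAI, FDR-adjusted.
- **Discriminant cascade** — a three-step LEfSe-style procedure
  (Kruskal–Wallis class test → subclass Wilcoxon consistency →
  ridge-regularized LDA effect size at threshold 2) for taxa or
  predicted-function tables (KO / MetaCyc), plus overlap counts of
  significant features between fraction analyses.
- **Synthetic cohorts** — a Dirichlet-multinomial generator of paired
  sorted fractions with planted coating effects, group structure, depth
  variation, and a BASDAI coupling (`simulateCohort()`), plus a KO-like
  feature-table generator (`simulateFeatureTable()`); these drive all
  power/calibration checks.
- **Pipeline** — `runFullAnalysis()` executes QC → diversity → scoring →
  correlation → discriminant for one site from a single seeded config and
  writes every result as TSV; runs are bit-identical given the same seed.

## Worked example

Simulate a cohort with three taxa whose IgA coating is raised in patients
(1.5 logits), one of which also drives BASDAI; then score it:

```r
library(igaseqr)

beta <- rep(0, 50); beta[c(5, 15, 25)] <- 1.5
cfg <- simulationConfig(n_per_group = 20, beta = beta,
                        basdai_taxon = 15, seed = 7)
cohort <- simulateCohort(cfg)

paired <- pairFractions(cohort$counts, cohort$manifest, site = "fecal")
paired <- filterByDepth(paired, min_reads = 7500)
paired <- prevalenceFilter(paired, min_subjects = 3)
paired
#> PairedFractions: 50 taxa x 36 subjects
#>   groups:  axSpA=18, HC=18
#>   site:    fecal
#>   depth:   pos 8240-67664, neg 7704-65567 reads

idx <- igaIndexMatrix(paired, pseudocount = 1)
groups <- setNames(subjectData(paired)$group, colnames(paired))
calls <- callEnrichment(idx, groups, group = "axSpA", fdr_threshold = 0.05)
head(calls[order(calls$p_fdr), ], 5)
#>     taxon_id group  n median_index            p        p_fdr     call
#> 5  taxon_005 axSpA 18   0.24678386 7.629395e-06 0.0001271566 enriched
#> 15 taxon_015 axSpA 18   0.18898555 7.629395e-06 0.0001271566 enriched
#> 25 taxon_025 axSpA 18   0.10951261 7.629395e-06 0.0001271566 enriched
#> 8  taxon_008 axSpA 18  -0.05743873 1.449585e-04 0.0018119812 depleted
#> 20 taxon_020 axSpA 18  -0.04626766 6.713867e-04 0.0067138672 depleted
```

The three planted taxa are the top enriched calls (the exact signed-rank
floor at n = 18 gives p = 2/2¹⁸ ≈ 7.6e−6; the trailing "depleted" calls are
the compositional echo of planting true enrichments). The BASDAI-coupled
taxon dominates the disease-activity correlation:

```r
basdai <- setNames(subjectData(paired)$basdai, colnames(paired))
cors <- correlateWithBasdai(idx, basdai)
head(cors[order(-abs(cors$rho)), ], 3)
#>     taxon_id  n        rho            p        p_fdr
#> 15 taxon_015 36  0.8160113 1.324062e-09 6.620312e-08
#> 46 taxon_046 24 -0.5069565 1.146159e-02 1.146159e-01
#> 33 taxon_033 35 -0.4940122 2.560152e-03 6.400381e-02
```

`taxon_015` has rho = 0.82 at FDR 6.6e−8; the runners-up are chance-level.
See `vignettes/igaseq-methods.Rmd` for the models, default parameters and
their rationale, and known limitations.

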