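Package: igaseqr
Title: IgA-SEQ Analysis of IgA-Coated Microbiota Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of IgA-SEQ experiments, in which a microbial community is
    flow-sorted into IgA-coated (IgA+) and uncoated (IgA-) fractions and each
    fraction is profiled by 16S rRNA gene sequencing. Implements the per-taxon
    IgA index (a bounded log-ratio of fraction relative abundances),
    enrichment/depletion calling with Benjamini-Hochberg correction, alpha
    diversity and unweighted UniFrac/PCoA/PERMANOVA community comparisons,
    Spearman correlation of IgA coating with disease activity (BASDAI), and a
    three-step LEfSe-style discriminant cascade (Kruskal-Wallis, subclass
    Wilcoxon consistency, ridge-regularized LDA effect size) for taxa or
    predicted-function feature tables. Includes a Dirichlet-multinomial
    simulator of paired sorted fractions with planted coating effects for
    power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn,
    picante,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
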