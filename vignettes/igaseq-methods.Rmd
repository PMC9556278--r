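---
title: "IgA-SEQ analysis with igaseqr: models, statistics and design choices"
author: "igaseqr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IgA-SEQ analysis with igaseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igaseqr)
```

## The experiment and the statistic

IgA-SEQ sorts a microbial community (fecal or salivary) into an IgA-coated
(IgA+) and an uncoated (IgA-) fraction by anti-IgA staining, then profiles
each fraction by 16S rRNA gene sequencing. Secretory IgA preferentially
binds immunologically salient microbes, so a taxon over-represented in the
IgA+ fraction relative to the IgA- fraction of the *same subject* is a
candidate immune-reactive organism — even when its overall relative
abundance does not differ between patient groups.

The package's central statistic is the per-taxon, per-subject **IgA index**
on the two fractions' relative abundances $a^{+}, a^{-} \in (0,1)$:

$$\mathrm{index} \;=\; -\,\frac{\log a^{+} - \log a^{-}}
                              {\log a^{+} + \log a^{-}}.$$

Because both logarithms are negative for proportions, the index is bounded
in $[-1, 1]$, antisymmetric under swapping the fractions, invariant to the
logarithm base, and positive when the taxon is preferentially coated.
`igaIndex(0.1, 0.01)` equals exactly $1/3$; the test suite asserts these
identities on a dense grid.

### Zeros, missingness, and the pairing contract

The log-ratio is undefined at zero, so `igaIndexMatrix()` adds a
configurable pseudocount (default **1 read per cell**) before
normalization. A taxon undetected in *both* fractions of a subject is
reported `NA`, not a pseudocount-driven 0: double absence carries no
evidence about coating, and treating it as "equally coated" would dilute
every downstream test. Subjects enter the analysis only when both fractions
were sequenced (`pairFractions()`), and the depth rule retains a subject
only when **both** fractions have at least 7,500 reads (inclusive
boundary), applied by `filterByDepth()`.

## Statistical procedures

* **Enrichment calls** (`callEnrichment()`): per taxon and group, a
  two-sided one-sample Wilcoxon signed-rank test of the subjects' index
  values against 0 — the natural paired-design test, equivalent to a paired
  rank test on log fraction abundances — followed by Benjamini–Hochberg
  (BH) correction across the taxa tested in that group. A significant taxon
  is *enriched* or *depleted* by the sign of its median index. Taxa with
  fewer than `min_n = 5` usable subjects are reported *untested* rather
  than non-significant: below $n=5$ the exact signed-rank test cannot reach
  two-sided $p < 0.05$, so "ns" would be vacuous.
* **Group contrasts** (`compareIndexBetweenGroups()`, `compareAlpha()`):
  two-sided Wilcoxon rank-sum tests, BH-corrected within their family
  (taxa within a site; the three alpha metrics). `stats::wilcox.test()`
  supplies the exact null distribution for small tie-free samples and the
  tie-corrected normal approximation otherwise.
* **Alpha diversity** (`alphaDiversity()`): Observed richness, Shannon
  entropy (natural log — the base is a documented convention), inverse
  Simpson. No rarefaction is applied: the depth filter already imposes a
  floor, and subsampling would discard data without changing rank tests
  much; this is a deliberate, documented choice.
* **Beta diversity**: unweighted UniFrac (`unweightedUnifrac()`, computed
  with `picante` on the rooted tree) — the fraction of branch length
  leading exclusively to taxa present in only one of two samples — then
  principal coordinates (`pcoaOrdination()`, Gower double-centering and
  eigendecomposition; negative eigenvalues are reported, never corrected)
  and PERMANOVA (`permanovaTest()`, via `vegan::adonis2` with free label
  permutation and a mandatory seed). Taxa missing from the tree are an
  error unless pruning is requested explicitly, because silent pruning
  changes distances. Unrooted (trifurcating) trees are midpoint-rooted
  with a warning, since UniFrac needs a root. UniFrac at genus level
  requires a genus-level tree; the package computes UniFrac at whatever
  rank the supplied tree's leaves represent.
* **Disease-activity correlation** (`correlateWithBasdai()`): Spearman's
  rho between a per-subject taxon statistic (IgA index or relative
  abundance — both are first-class) and the BASDAI score (0–10), missing
  scores excluded, midranks for ties, exact permutation p for $n \le 9$
  tie-free and the t approximation otherwise, BH across taxa per site and
  statistic type. The default significance tier is FDR 0.05, with results
  near FDR 0.20 conventionally read as trends.
* **Discriminant cascade** (`runCascade()`): the three-step LEfSe-style
  procedure on any feature-by-sample table (taxa, KO, MetaCyc pathways):
  (1) Kruskal–Wallis across classes at `alpha_class` (0.05 strict preset;
  0.1 relaxed preset for exploratory runs); (2) a subclass consistency
  step — within every comparable stratum (e.g. within each sex), a
  rank-sum test between the classes must meet `alpha_sub` *and* agree in
  direction with the class-level difference; strata with fewer than two
  samples on a side are skipped, and absent subclass labels pass the step
  with a warning; (3) an LDA effect size with the LEfSe conventions
  (per-sample scaling to $10^6$, 30 bootstrap subsamples of 2/3, score
  $\log_{10}(1 + |\Delta|)$ where $\Delta$ averages the feature's share of
  the class separation along the discriminant axis with the raw class-mean
  difference), significant at $|\mathrm{score}| \ge 2$. The within-class
  scatter is ridge-regularized ($\lambda = 10^{-6}\,\mathrm{tr}(S_w)/p$)
  so the fit survives $p \gg n$ tables such as KO matrices.

Two cascade details deserve emphasis. The $10^6$ scaling is applied once
over the **full feature universe** and only enters the LDA stage;
normalizing within a survivor subset would redistribute the compositional
total over a handful of features and can flip apparent effect directions.
The rank tests see the table as supplied, so users analyzing relative
abundances test relative abundances (as is conventional), while simulated
absolute tables are tested on their own scale.

The subclass semantics pair **matched** subclass levels across the two
classes (males vs males, females vs females) and require every comparable
pairing to replicate the effect — a strict reading that is what controls
the cascade's family-wise null behaviour: with only ~40 features summing
to $10^6$, the LDA threshold of 2 (an absolute difference of ~100 on that
scale) cannot filter chance findings among abundant features, and without
the subclass step the any-significant rate under exchangeable classes
would be far above 10%.

## The synthetic cohort generator

No real sequencing data ships with the package; every downstream stage is
exercised against `simulateCohort()`, whose generative model is:

* community composition $\pi_s \sim \mathrm{Dirichlet}(\alpha)$ per
  subject, with $\alpha$ a geometric series from 10 to 0.1 over the taxa
  (an uneven, long-tailed community);
* coating probability $\theta_{s,t} = \mathrm{logistic}(\mu_t + \beta_t
  \cdot \mathbb{1}[\mathrm{axSpA}] + \varepsilon_{s,t})$ with subject noise
  $\varepsilon \sim N(0, \sigma^2)$;
* the sort is modelled **compositionally**: the IgA+ sample's expected
  composition is $\pi_s \theta_s$ renormalized and the IgA- sample's is
  $\pi_s (1-\theta_s)$ renormalized — 16S observes composition, not
  absolute load, which is exactly what IgA-SEQ measures. A carry-over
  parameter for sort impurity is exposed but defaults to 0, since no
  quantitative purity estimate is available;
* integer counts are multinomial at a negative-binomial depth (mean
  30,000, dispersion 0.3 — so the 7,500-read filter has realistic
  violations to reject);
* disease activity is linear in the coupled taxon's coating logit,
  $\mathrm{BASDAI}_s = \mathrm{clip}_{[0,10]}(b_0 + b_1
  \mathrm{logit}(\theta_{s,t^{*}}) + N(0, \sigma_b^2))$.

Defaults are fixed once as plausible study conditions: 15 subjects per
group (the size of a single-site sorted-fraction cohort), 50 taxa,
baseline coating probability 0.1 (gut communities are typically 5–10%
IgA-coated), subject coating noise 0.5 logits, and $b_0 = 6.8$, $b_1 =
1.5$, $\sigma_b = 1$, placing the mean simulated score near 3.5 — a
typical active-disease cohort mean — so that floor-clipping at 0 stays
rare. Without a coupled taxon, BASDAI is drawn as taxon-independent noise
around group-typical scores (3.5 for patients, 0.8 for controls).

`simulateFeatureTable()` generates KO-like function tables for the
cascade: heavy-tailed lognormal baselines (meanlog $\log 100$, sdlog 2 —
most features rare, a few dominant, with the feature index equal to the
abundance rank) and within-class lognormal noise of sdlog 0.25 (~25%
replicate CV, chosen after a small power analysis as a realistic
replicate-level spread for predicted functional profiles); planted effects
are fold changes on chosen abundance ranks.

### What the simulations do and do not show

The generator reproduces the *design* of a sorted-fraction study —
paired compositions, coating heterogeneity, depth variation, group
effects, an activity coupling — but not sequencing error, chimeras,
contamination, taxonomic misassignment, or ecological correlation between
taxa beyond the Dirichlet's. Passing recovery tests therefore demonstrates
that the statistical machinery detects the effects it models at realistic
sizes and depths, not that any particular real dataset will behave as
cleanly.

One calibration subtlety is documented rather than hidden: under the
*exchangeable* null ($\mu = 0$, no group effects) the per-subject index is
symmetric about 0 and the signed-rank test holds its nominal size (the
suite checks 0.05 within binomial tolerance over 500 cohorts). Under a
*skewed* coating baseline ($\mu = \mathrm{logit}(0.1)$) with subject-level
noise, the index distribution is median-zero but asymmetric, and the
signed-rank test becomes mildly anticonservative (measured near 0.066 at
$n=15$). That is a property of applying a symmetry test to a skewed
statistic — users comparing *groups* (rank-sum) are unaffected, and
within-group calls on strongly coated taxa dwarf this effect, but
borderline within-group calls at skewed baselines deserve caution.

## Numerical and procedural choices

* File dialect: TSV, UTF-8, `#` comments, first count-table header cell
  literally `taxon_id`; write–read round-trips are exact and tested.
* Genus-level tables are built by explicit aggregation
  (`aggregateTaxonomy()`) — summing ASV counts along the lineage, pooling
  taxa unclassified at the target rank into `unclassified_<parent>` —
  because whether published genus tables were summed or re-classified is
  generally ambiguous; aggregation conserves totals by construction.
* Prevalence filtering defaults to detection in ≥ 3 subjects: permissive,
  but enough to avoid single-subject artifacts.
* PERMANOVA p-values use the $(1 + \#\{F_{\pi} \ge F\})/(1 + n_{\pi})$
  convention; the seed is a required argument, not an ambient state.
* All simulator and bootstrap randomness flows through a single seed per
  call, and the RNG state of the caller is restored afterwards; the
  pipeline derives each stage's seed from the run seed, so a full
  `runFullAnalysis()` is bit-identical across repeated invocations (no
  timestamps are written into outputs).
* Enrichment testing is per group (separate patient and control panels),
  matching the convention of reporting each group's coated taxa; pooled
  testing is a one-line variant the user can run on the index matrix.

Problem sizes used by the shipped checks — 500 null cohorts of 30 taxa and
15 subjects per group for calibration, 20 replicate cohorts of 50 taxa and
20 subjects per group for recovery, 100 null feature tables for the
cascade — were chosen as the smallest sizes at which the binomial
tolerances of the checks are meaningful.

## Known limitations

* The IgA index inherits compositional closure: planting true enrichments
  makes unrelated taxa drift slightly negative. Recovery is therefore
  assessed on *enriched* calls; symmetric "depletion" calls near zero
  median should be interpreted with the closure in mind.
* The signed-rank anticonservatism at skewed coating baselines, above.
* The subclass step's strictness trades sensitivity for specificity: a
  true effect that fails to replicate at $p<0.05$ within a small stratum
  (7–8 subjects) is dropped.
* UniFrac, PCoA and PERMANOVA operate at the rank of the supplied tree's
  leaves; no genus-level tree is constructed internally.
* `basdai` is the only clinical coupling modelled; no covariate
  adjustment (age, sex, medication) is implemented for the correlations.
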