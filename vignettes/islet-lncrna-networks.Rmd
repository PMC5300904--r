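---
title: "Models and design choices in isletlncnet"
author: "isletlncnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in isletlncnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isletlncnet` chains the analyses needed to argue that β-cell lncRNAs and
transcription factors co-regulate islet gene programs: knockdown
differential expression with a combinatorial specificity null, phenotype
correlation, expression-matched gene-set enrichment, co-expression module
detection, a cis-regulatory scan, and disease-cohort count DE. This
vignette records the statistical models behind each stage, the parameters
that matter, what the synthetic-data generators do and do not emulate,
and the design decisions taken where the methodology was genuinely open.

## Knockdown differential expression

Each knockdown target (a lncRNA or TF) is silenced by one or two
independent artificial microRNAs (amiRNAs), transduced in replicate, and
profiled on log2-scale arrays alongside five non-targeting control
amiRNAs. `anova_de()` pools all replicates of a target and all control
replicates and tests each gene with a two-group one-way ANOVA — the
pooled-variance t statistic squared, with p from F(1, nA + nB − 2). The
equal-variance form was chosen deliberately: with 6-vs-15 samples the
pooled test has exact small-sample behaviour under the Gaussian noise
model, and its null calibration is verified by simulation in the test
suite (fraction of null genes at p < 10⁻³ within three binomial standard
deviations of 10⁻³ over 2 × 10⁶ gene-tests). Genes with zero variance
everywhere are reported with F = 0, p = 1; perfect separation with zero
within-group variance gives p = 0. The DE gate defaults to
`alpha = 1e-3` with no multiple-testing correction, matching the screen
convention this models; `bh_adjust()` is available when an FDR is wanted
instead.

## The control-split specificity null

RNAi can deregulate genes nonspecifically, so a knockdown phenotype is
only convincing if two *independent* amiRNAs against the same target
deregulate more genes than two *unrelated* control amiRNAs do.
`enumerate_control_partitions()` forms all C(5,2) = 10 two-vs-three
splits of the five control groups; `specificity_null()` counts DE genes
in each, then counts DE genes for the fixed target amiRNA pair against
every control triple, and compares the two count samples with
`mann_whitney_one_sided()`. For pooled sizes up to 20 the Mann-Whitney p
is computed by full enumeration of rank assignments with mid-rank ties —
at 10 + 10 counts this is the exact conditional permutation p — and by
the tie-corrected normal approximation (with continuity correction)
above that.

One property of this design deserves emphasis. The ten target
comparisons reuse one fixed amiRNA pair, and the ten control splits
reuse the same five groups, so the twenty counts are *not* independent:
if the pseudo-target pair happens to deviate by chance, all ten of its
counts deviate together. Under a global-null simulation the Mann-Whitney
p is therefore mildly anti-conservative in its tail (the test suite
measures roughly twice the nominal rate at the 5% level over 200
replicates, with a super-uniform centre). This is a property of the
screen design itself, which the package reproduces faithfully rather
than repairs; it is immaterial for the strong phenotypes the screen is
built to detect, where the p-value sits at its enumeration floor
(1/C(20,10) ≈ 5.4 × 10⁻⁶), but borderline calls near p ≈ 0.05 should
not be over-read.

## Phenotype similarity

`build_foldchange_matrix()` keeps the union of genes significant in at
least one knockdown and tabulates their log2 fold changes per contrast
(the union across *all* contrasts; a pairwise-union variant can be had by
passing two tables). `pairwise_phenotype_correlation()` uses Pearson r
with the t transform on n − 2 degrees of freedom;
`cluster_contrasts()` clusters contrasts by average linkage on 1 − r, the
common convention for expression phenotypes. "Most regulated" genes in
`top_regulated_union()` are ranked by |log2fc| — magnitude, because the
quantity plotted in such comparisons is the fold change — with ties
broken by smaller p and then gene id so the selection is deterministic.

## Enrichment with expression-matched controls

`gsea_enrichment_score()` implements the weighted Kolmogorov-Smirnov
running sum: walking the ranking from the highest score down, set members
add |score|^w (normalised by the total hit weight, default w = 1) and
non-members subtract 1/(N − N_hits); the enrichment score is the signed
maximum deviation. For any proper subset the walk starts and ends at
zero; if the set covers the whole ranking there are no miss steps and the
walk ends at its maximum, a degenerate case the functions permit but flag
in documentation. The null in `gsea_permutation_p()` is *gene-set*
permutation — random sets of the same size — rather than phenotype
permutation, because knockdown designs have too few samples to permute
labels meaningfully; this is a documented deviation of convenience from
sample-permuting implementations. When no permuted score shares the
observed sign, there are no comparable null deviations and the function
reports p = 1 rather than manufacturing significance.

Control gene sets "expressed at similar levels" as a target set are built
by `expression_matched_control_sets()`: genes are binned into deciles of
mean expression (`n_bins = 10`), each control set reproduces the target's
per-bin counts exactly, and *within* a bin each target gene is matched by
one of its `k_nearest = 10` expression-nearest unused non-target genes.
Plain uniform sampling within deciles was found to leave set means up to
~0.2 log2 units off in wide tail bins; nearest-neighbour matching keeps
the mean difference well inside 0.1 log2 units while preserving the
per-bin profile and the sets' randomness. Exhausted bins borrow from the
nearest neighbouring bins with a message.

Islet-enriched genes are defined by `islet_enriched_genes()` as strictly
exceeding the tissue-panel mean by two sample standard deviations;
module-annotation enrichment uses the hypergeometric upper tail
(`stats::phyper`, cross-checked against exhaustive enumeration in the
tests) at a default gate of p < 10⁻².

## Co-expression modules

The network stage follows the weighted co-expression recipe: Pearson
correlation across samples, unsigned soft-threshold adjacency
a = |r|^β (signed available), topological overlap, average-linkage
clustering on 1 − TOM, and a static cut.

Numerical choices here matter and were made as follows.

* **Soft power.** `pick_soft_threshold()` scans candidate powers and
  fits log10 p(k) against log10 k over equal-width connectivity bins,
  returning the smallest power whose signed R² reaches `r2_target = 0.8`
  (otherwise the best-fitting power, with a message). Equal-width bins
  are essential: quantile bins flatten p(k) by construction on the
  near-homogeneous degree distributions that factor-model data produce,
  and the fit never becomes informative.
* **Static cut.** With the selected powers (typically β = 9–12 on the
  bundled synthetic cohort) all TOM entries are small and every merge
  height crowds into a narrow band just below 1, so any cut at a fixed
  fraction of the maximum height lands inside the within-module merge
  continuum and shatters the modules. `detect_modules()` instead places
  its default cut at the midpoint of the widest gap between consecutive
  merge heights in the *upper half* of the dendrogram: a modular network
  produces a two-scale tree whose few between-module merges sit above a
  clear gap, and restricting to the upper half keeps tight outlier pairs
  at the bottom of the tree from attracting the cut. `cut_height`
  remains a user parameter for non-modular data. Clusters below
  `min_module_size` (default 30) are labelled "unassigned"; modules are
  renamed M1, M2, … by decreasing size, and "major" modules are those
  with more than 100 genes.
* **Eigengenes.** `module_eigengene()` returns the first right singular
  vector of the per-gene z-scored module submatrix, oriented so its mean
  correlation with member genes is non-negative. The orientation follows
  the members: flipping the sign of every input flips the oriented
  eigengene, which is the deterministic behaviour the rule implies.

## cis-regulatory scan and disease-count DE

`nearest_coding_gene()` pairs each lncRNA with the coding gene minimising
the interval distance (gene-body distance on 0-based half-open
coordinates; 0 when overlapping) within 1 Mb — the window operationalises
"adjacent", which the methodology leaves unstated — with ties broken
toward the lncRNA's 5′ side and then lexicographically. A TSS-distance
mode was considered and left out of scope; gene-body distance is the more
conservative notion for multi-isoform lncRNA loci.
`cis_pair_scan()` flags pairs whose expression correlation across the
cohort reaches p < 10⁻⁷ as candidate cis-regulatory lncRNAs.

For disease cohorts, `size_factors()` is the median-of-ratios estimator
over genes expressed in all samples, and `nb_wald_de()` fits per-gene,
per-condition negative-binomial means on normalised counts with a
method-of-moments dispersion (pooled over conditions via
Var(K/s) = μ/s + αμ², floored at 10⁻⁸) and a Wald test on the log2 fold
change, BH-adjusted at padj < 0.05. This is intentionally a simplified
core: dispersion shrinkage across genes, outlier (Cook's distance)
filtering, and GLM offsets of full-featured count-DE packages are *not*
reproduced, because the claims exercised here are the thresholding logic
and effect directions, not those refinements. Consequences visible in
the tests: the null BH-significant fraction stays below the FDR target,
planted |log2fc| = 2 effects at 50-vs-15 samples are recovered with high
power, and in the vanishing-dispersion limit the median agreement with a
Poisson Wald oracle is within 10% while individual genes can deviate
more through moment-estimator noise.

## lncRNA candidate filtering and assay arithmetic

`filter_candidates()` applies the three retention rules for de-novo
lncRNA annotation — β-cell expression, no exocrine enrichment (an acinar
contamination guard), and promoter-like H3K4me3 near the 5′ end — in that
order, recording the first failing rule per rejected candidate. The
numeric defaults (`min_beta_expr = 0.5` abundance units,
`max_exocrine_ratio = 1.0`, `max_h3k4me3_distance = 2000` bp) are
explicit placeholders for thresholds that live in supplementary detail of
annotation pipelines, not derived values; they are parameters the user is
expected to set. The filter is a pure function: retained plus rejected
equals the input in order, and loosening any single threshold can only
grow the retained set.

The assay helpers implement exactly specified arithmetic: qPCR relative
expression as 2^−(Ct_target − Ct_reference) folded over a control group
or a time-zero baseline (amplification efficiency fixed at 2; a
two-reference variant averages the reference Cts, as used for protein
quantification against two loading controls); amiRNA efficiency as
100 × (1 − fold remaining) with a strict > 50% gate; insulin secretion
normalised per cell and folded over basal-glucose controls, with the
secreted/content secretion index as the content-corrected measure (the
correction formula itself is not stated by assay conventions, and the
ratio is the natural choice); and 3C contacts as region/control-region
signal expressed relative to the control sample.

## The synthetic-data generators

Three generators produce every input with ground truth.

* `simulate_knockdown_experiment()`: log2 intensities as per-gene
  baseline N(8, 1.5²) plus planted regulon effects plus N(0, σ) noise,
  with σ = 0.25 log2 units by default — a free parameter chosen as a
  plausible replicate variability for array data, since no value is
  prescribed; the target's own transcript is knocked down by ≥ 50% to
  exercise the efficiency gate. Default planted effects alternate in
  sign, because real knockdowns both up- and downregulate genes — and
  because a constant-sign regulon makes fold-change profiles over the
  union of significant genes trivially (anti)correlated, which would
  caricature the phenotype-correlation analysis. Shared regulons
  between two targets copy genes *with their effects* from donor to
  recipient, so co-regulated genes move the same way in both knockdowns.
* `simulate_islet_cohort()`: a latent-factor model x = λ f_m + ε per
  module over (by default) 64 donor samples, giving within-module
  correlation λ²/(λ² + σ²); biotype labels (lncRNA/TF/coding) and a
  synthetic single-chromosome annotation. Declared cis pairs share a
  pair-specific factor with x = √w·u + √(1 − w)·ε, so the *expected pair
  correlation equals the declared weight* — a parameterisation chosen so
  that w is interpretable on the correlation scale that the cis gate
  (p < 10⁻⁷ at n = 64, i.e. |r| ≳ 0.6) is defined on — and the pair
  members are placed as mutual nearest neighbours with a reduced
  inter-gene gap.
* `simulate_count_cohort()`: NB counts with log-normal baseline means
  and dispersions, per-sample depth factors, and planted log2 effects in
  a case group (default 50 controls vs 15 cases, the cohort geometry of
  the impaired-glucose-tolerance comparison).

What the generators do *not* emulate — and hence what passing tests do
not show about real data: probe-level array artefacts and normalisation,
correlated (batch) noise, heavy-tailed expression distributions,
mean-variance trends on the log2 scale, overlapping gene models and
multi-chromosome genomes, library-composition biases beyond global depth,
and biological correlation between modules. Recovery statistics on this
synthetic (module ARI, cis recall, regulon sensitivity) are therefore
upper bounds on real-data performance, useful for verifying the
implementation, not for benchmarking the methods.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run at desk scale, chosen to
exercise each statistical claim with adequate Monte-Carlo resolution:
2 × 10⁶ null gene-tests for the DE calibration, 200 global-null
replicates for the specificity null, a 2,000-gene × 64-sample cohort over
five seeds for module recovery, 20 planted cis pairs, and 5,000-gene
count cohorts for FDR calibration. Every stochastic function takes an
explicit seed, seeded helpers restore the caller's RNG state, and
`run_pipeline()` derives all stage seeds from one master seed, so any
report is reproducible from its configuration.

## Known limitations

* The NB Wald core deliberately omits dispersion shrinkage and outlier
  handling (above); very small cohorts or genes with extreme dispersion
  will be tested less efficiently than by full-featured count-DE tools.
* The static-cut module detection targets clearly modular data; on
  networks without a two-scale merge structure the widest-gap default can
  land arbitrarily and `cut_height` should be set explicitly.
* The specificity null inherits the tail anti-conservativeness of its
  reuse-heavy design (measured and discussed above).
* `read_bed_annotation()` parses only the minimal BED6+biotype fields;
  GTF/GFF gene models are out of scope.
* All coordinates are 0-based half-open throughout; mixing conventions
  with external annotations is the caller's responsibility.
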