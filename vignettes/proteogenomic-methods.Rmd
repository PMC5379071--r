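---
title: "Proteogenomic integration for xenograft cohorts: models and design choices"
author: "ProteoPDX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic integration for xenograft cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoPDX)
```

# The problem

Genomic profiling nominates druggable alterations in only a fraction of
breast tumours, and a mutation or amplification does not guarantee that
the corresponding protein is overexpressed or its pathway active.
Patient-derived xenograft (PDX) panels profiled at the copy-number,
mRNA, protein (isobaric-label log-ratios) and phosphosite levels allow
the two views to be reconciled per tumour: expression outliers and
phosphorylation-driven pathway activity complement the mutation table
when nominating targets. ProteoPDX implements that integration as a
reusable, tested pipeline: normalization, mRNA–protein concordance,
proteomic subtyping, differential expression, druggable-outlier
detection across all four levels, phosphoproteomic pathway activation,
and tumour/xenograft variant-allele-fraction (VAF) fidelity — plus a
synthetic multi-omic cohort generator that provides planted ground
truth for every stage.

All expression inputs are feature-by-sample matrices on a log scale:
CNV as log-R ratios referenced to the per-gene cohort mean, mRNA as
log2 abundances, protein and phosphosites as log2 ratios to a common
reference channel. Missing cells are `NA` and every statistic below is
missing-aware.

# Normalization and gene collapsing

**Mixture re-centering.** Isobaric-label columns are contaminated by
per-sample loading and instrument effects that shift the whole
log-ratio distribution. `mixtureCenter()` fits, per sample column, a
two-component Gaussian mixture by EM and subtracts the dominant
(higher-weight) component's mean, so the unregulated bulk of the
proteome sits at zero while regulated tails keep their sign and
magnitude. Numerical choices:

* EM means are initialised at the column's 25th/75th percentiles with
  equal weights and pooled-s.d. starts; tolerance `1e-6` on the
  log-likelihood, at most 500 iterations; fits are per-column and
  deterministic.
* A two-component EM on a column that is in truth a single Gaussian is
  degenerate: symmetric splits (means at roughly ±0.5 s.d., weights
  near one half) have essentially the likelihood of the true model, so
  "the dominant mean" becomes an arbitrary ±0.5 s.d. offset. We
  therefore compare the converged two-component fit against the
  single-Gaussian fit by BIC (5 vs 2 parameters) and use the single
  component's mean when it wins — the same model-order choice mclust
  makes. The `basis` column of the fit table records which path was
  taken (`mixture`, `single`, or `median` for non-convergent columns,
  which fall back to the column median).
* Only the location is corrected. No variance rescaling is applied.

Normalization is per sample, not global: the artefact being corrected
is differential protein loading per channel.

**Isoform collapsing.** `collapseToGene()` keeps one row per gene:
single rows pass through; of two rows the higher (missing-aware) mean
wins; with three or more rows the row with the highest *connectivity* —
its summed pairwise Pearson correlation with the gene's other rows on
pairwise-complete samples — wins, exact ties reverting to the higher
mean. Connectivity needs at least 3 pairwise-complete samples per row
pair; genes failing that fall back to the higher mean and are flagged.
This mirrors the max-mean / max-connectivity collapse rule popularised
by WGCNA's `collapseRows`.

**Observation filter.** Downstream statistics use features quantified
in at least `minObs` samples (default 10 of 24). The mRNA–protein
correlation uses its own, laxer 30%-coverage rule (below).

# mRNA–protein correlation and pathway enrichment

`geneCorrelation()` computes, per gene observed in ≥ 30% of samples in
*both* layers (the required count is the ceiling, so 8 of 24),
a Spearman correlation over pairwise-complete samples. Spearman is the
default — the two layers are measured on different scales and only
monotone agreement is claimed — but the Pearson coefficient is always
reported alongside, since cohort medians are conventionally quoted as
Pearson values; the two differ slightly (for a bivariate normal,
Spearman ≈ (6/π)·asin(ρ/2) < ρ).

`ksPathwayEnrichment()` asks whether a pathway's member genes sit
unusually high or low in the correlation ranking: a two-sample,
two-sided Kolmogorov–Smirnov test of in-set versus all out-of-set
correlations (the complement, not the full list, so the null is
exchangeability of membership), Benjamini–Hochberg adjusted across all
pathways tested in the run. Sets with fewer than 5 scored genes are
skipped. Exact p-values are used when both sides have ≤ 10
observations, the asymptotic distribution otherwise.

# Subtyping

`selectVariableMarkers()` keeps features with cohort s.d. above a
threshold (conventional values: 2 for an isobaric proteome, 2.5 for a
phosphoproteome, on the log2-ratio scale) and ≥ `minObs` observations.
`clusterSamples()` then runs complete-linkage agglomeration on
euclidean distances computed over pairwise-complete markers, the
squared sum rescaled by `n_markers / n_observed` (the convention
`stats::dist` implements); `1 − Pearson` distance is available by
flag. Marker rows are median-centered by default; full row
standardisation is optional, since with a common log-ratio scale the
s.d. itself is informative. The tree is cut at an explicit `k`
(default 2, the basal/luminal split).

For joint PDX/human clustering, `coClusteringMarkers()` removes genes
that differ systematically between the cohorts (xenograft stroma is
mouse, human tumour stroma is not): keep genes with BH-adjusted
two-sample t-test q > 0.3 (i.e. *non*-differential), merged-cohort
s.d. > 2 and observation in > 10 merged samples.

# Differential expression and gene-set enrichment

`differentialTest()` is a per-feature two-sample t-test (Welch by
default — "Student's t-test" in common usage rarely implies pooled
variance, and Welch is the safer default; pooled available by flag),
computed when both groups have ≥ 3 non-missing values, BH-adjusted
over tested features. `rankedGeneSetEnrichment()` then tests each gene
set's t-statistics against the complement with a two-sided Wilcoxon
rank-sum test (average ranks for ties; exact null when both sides ≤
10, normal approximation with continuity correction otherwise), BH
over sets. Any GMT collection can be supplied (KEGG, Reactome, custom).

# Druggable expression outliers

For one feature across the cohort the outlier score of sample value
\(x\) is
\[ O(x) = \frac{x - Q_3}{\mathrm{IQR}} \]
with quartiles over the feature's non-missing values. \(O > 1.5\) is
exactly the classic boxplot rule "more than 1.5 IQRs above the third
quartile"; the score form additionally orders outliers so they can be
ranked within a sample. Conventions:

* Quartiles interpolate linearly between order statistics
  (`h = (n−1)p`, `quantile` type 7); the test-suite oracle implements
  the same convention independently.
* IQR = 0: values above Q3 get `Inf` (outliers by the definition),
  everything else 0 — preserving the equivalence `O > 1.5 ⇔
  x > Q3 + 1.5·IQR` in the degenerate case.
* Only high-side outliers are called: the use case is
  overexpression/hyperactivation, and log-ratio compression makes
  low-side calls uninterpretable as drug targets.

`callOutliers()` restricts to a druggable-gene list (phosphosites
inherit druggability from their `GENE:site` gene symbol), applies the
≥ 10-observation filter, ranks calls within each (sample, level) and
flags CNV calls as cross-validated only when the same gene scores
> 1 at the mRNA or protein level in the same sample — a copy-number
outlier with no expression echo is treated as a technical or passenger
event. `humanValidation()` checks PDX outlier events against a human
cohort: validated if any human sample shows the feature with score > 1
or within that sample's top 2 scores at the same level (computed
within-level); features absent from the human data are excluded from
the rate denominator. `druggableMutationCensus()` is the genomic
complement: distinct samples carrying ≥ 1 somatic mutation in a
druggable gene (the caller chooses the denominator for a percentage —
for example, whether lymphoproliferative models count in the cohort
size).

# Phosphoproteomic pathway activation

`collapsePhosphoToGene()` averages each gene's observed site values
per sample. `modifiedZscore()` robust-standardises each gene across
the cohort (Hoaglin's modified z):
\[ M = 0.6745\,(x - \tilde{x}) / \mathrm{MAD}, \]
falling back to \(0.7979\,(x-\tilde{x})/\mathrm{meanAD}\) when the MAD
is zero, and to 0 when both scales vanish; the basis used is recorded.
Standardisation is per gene across samples — the only axis that makes
a *per-sample* rank test meaningful, since each sample's member
z-scores then measure that sample's deviation from the cohort.
`pathwayActivation()` tests, within each sample, member-gene z-scores
against all non-member z-scores (two-sided rank-sum), pools all
(sample, pathway) p-values of the run into one BH family (per-sample
adjustment by flag) and flags activation at q ≤ 0.01 with a positive
median member z — the two-sided p is kept so coordinated
*de*phosphorylation remains visible without being mislabelled
"activated".

# VAF fidelity

`pairMutations()` matches tumour and xenograft calls on
(gene, protein change) — the resolution at which such events are
reported — flags private calls, and summarises per-pair retention.
`vafConcordance()` is the pooled Pearson correlation of raw
(tumour, PDX) VAF fractions over shared calls (≥ 3 pairs and
non-degenerate variance required). Pooling across pairs, rather than
averaging per-pair correlations, weights every mutation equally and is
stable for pairs with few calls.

# The synthetic cohort generator

`simulateCohort()` draws a full multi-omic bundle from an explicit
generative model so that every downstream stage has known truth:

* **Coupling.** Per gene \(g\) and sample \(s\), mRNA and protein
  share a latent term with gene-specific weight \(w_g\):
  \(x_{gs} = \mu_g + m_{gs} + \sigma(\sqrt{w_g}Z_{gs} +
  \sqrt{1-w_g}E_{gs})\), so the mRNA–protein Pearson correlation of
  gene \(g\) is \(w_g\) by construction. Baseline weights are drawn
  around a target median of 0.536 (the regime reported for isobaric
  PDX proteomes); per-pathway targets override member genes, which
  yields the pathway-structured enrichment pattern.
* **Layers.** Defaults: mRNA noise s.d. 1.0, protein 0.5, CNV 0.3 on
  the log scale; per-gene baselines; a per-sample loading offset
  (s.d. 0.2) on protein and phosphosite columns for the mixture
  centering to remove; 1–5 phosphosites per gene tracking the gene's
  protein value plus site noise (s.d. 0.3).
* **Cohort.** 24 PDX samples (10 basal-like, 14 luminal-like) by
  default, optionally joined by a human cohort sharing the subtype
  structure plus a sparse per-gene batch shift (half the genes,
  s.d. 0.8) for the co-clustering filter to remove. 200 subtype marker
  genes carry a between-subtype mean difference of 1.5 log2 units
  (3× the protein noise s.d.).
* **Missingness** is missing-completely-at-random per cell with
  per-feature rates drawn from 20–60% for protein and phosphosite
  layers — the simplest mechanism consistent with count-based
  observation filters. Real isobaric data are missing not at random
  (abundance-dependent), so passing tests here say nothing about
  informative missingness.
* **Planted truth.** Single-sample expression outliers (shift in
  layer-s.d. units, added on top of the cell's own noise; planted
  cells are never masked), per-sample pathway activations (shift in
  gene-level z units applied to member-gene sites), subtype markers,
  pathway coupling targets and paired tumour/PDX VAFs (PDX VAF =
  tumour VAF + 0.03 + N(0, 0.18²), clipped — noise chosen to put the
  pooled concordance near the R ≈ 0.66 regime reported for such
  pairs). Everything is recorded in a truth manifest, and the bundle
  is a deterministic, byte-stable function of (design, params, seed).

What the generator does *not* emulate: informative missingness,
isobaric ratio compression, shared-peptide protein inference,
mouse/human peptide ambiguity, CNV segment structure (genes are
independent), and correlated noise between samples of a multiplex.
Recovery tests on this cohort therefore validate the statistics, not
the upstream measurement process.

A note on detection power: an outlier planted as an *additive* +4 s.d.
shift keeps its own unit noise, so even against the exact Gaussian
fence (Q3 + 1.5 IQR = 2.70 s.d.) its detection probability cannot
exceed Φ(4 − 2.70) ≈ 0.90, and finite-cohort quartile noise at n = 24
with 20–60% missingness brings it to ≈ 0.85; +5 s.d. plants are
detected at ≈ 0.97. The false-call rate of the rule on null Gaussian
features is likewise n-dependent (≈ 1% per cell at n = 24, above the
asymptotic 0.35%), so the test suite checks it against a Monte-Carlo
oracle at the realized observation counts rather than a fixed
constant.

# Problem sizes and runtime choices

The shipped tests exercise the pipeline at 150–2 000 genes × 24–64
samples with fixed seeds — large enough for stable medians, planted
signals and calibration checks, small enough for routine runs; the
generator's 10 000-gene default reflects the realistic cohort scale.
Exact enumeration oracles (rank-sum, KS, BH) run on micro examples
where the full permutation set is tractable, and the
quartile/fence/Monte-Carlo oracles in the suite are implemented
independently of the package's own code paths.

# Limitations

* Subtype labels, gene-set collections and the druggable-gene list are
  inputs; no PAM50 classification, pathway curation or drug–gene
  mapping is performed.
* CNV enters pre-transformed as log-R ratios; segmentation and calling
  are upstream.
* The KS and rank-sum enrichment tests treat sets as flat gene lists;
  no topology, no gene–gene correlation correction — p-values are
  calibrated under gene exchangeability, which real co-regulated
  pathways violate.
* Human-cohort validation assumes the human matrices share the
  feature space and reference scale of the PDX data (parallel
  processing); no cross-study harmonisation is attempted.

# A minimal run

```{r example, eval = FALSE}
d <- cohortDesign(10, 14, nHuman = 30)
b <- simulateCohort(d, cohortParams(nGenes = 2000, seed = 7))
paths <- writeCohort(b, "cohort")

cfg <- pipelineConfig(
  out_dir = "run",
  inputs = as.list(paths[c("cnv", "mrna", "protein", "phosphosite",
    "mutations", "pathways", "druggable", "design", "pairing")]),
  params = list(sd_protein = 0.7, sd_phospho = 0.7))
res <- runPipeline(cfg)
res$manifest$stages$outliers
```
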