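---
title: "Methods: inferring miRNA-mRNA-pathway risk networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring miRNA-mRNA-pathway risk networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpathnet)
```

# The analysis in one paragraph

`mirpathnet` infers, from case/control expression profiles, which pathways
are dysregulated in a disease, which genes drive that dysregulation, and
which miRNAs plausibly regulate those genes. The chain is: per-study
differential expression combined across mRNA studies by Fisher's method;
gene set enrichment analysis (GSEA) per study with a consensus rule to pick
*risk pathways*; *core genes* as the leading edges of those pathways;
*risk genes* as the intersection of core genes and DEGs; an upper-tail
hypergeometric test (BH-adjusted) linking each DE miRNA to each risk
pathway through its validated targets; a tripartite miRNA-gene-pathway
network with a protein-protein interaction (PPI) overlay and topology
metrics; cross-validated single-feature ROC AUC as a biomarker score; and
a lexical cross-species DE-miRNA comparison. Every stage returns a tibble,
so results chain with the pipe.

# Statistical models and their assumptions

## Differential expression

Expression values are assumed to be normalized log2 intensities; no
raw-array processing is performed. The per-study test is a two-sided Welch
t (default), chosen over the pooled-variance t because the designs this
package targets are unbalanced (e.g. 33 cases vs 58 controls), where
unequal group variances otherwise distort the type-I error. An
empirical-Bayes moderated t is available for small studies: pooled
variances are shrunk toward a prior estimated by moment matching of the
log sample variances (the prior df solves
`var(log s^2) - trigamma(d/2) = trigamma(d0/2)` by Newton inversion of the
trigamma function; with no excess dispersion the prior collapses to the
mean sample variance and shrinkage is complete). The scheme is the standard
limma one, and the test suite cross-checks it against limma on simulated
data.

Across mRNA studies, per-feature p values are combined by Fisher's method
(`X^2 = -2 * sum(log p)` on `2k` df). Fisher is the fixed default because
it is the classic closed-form combination and is exact for independent
studies; the consensus fold change is the inverse-variance weighted mean,
with a `discordant` flag when study signs disagree. DE calling uses the raw
p value at a strict `p < .05` (adjusted p is reported alongside but does
not gate the call); the rodent rule is inclusive, `p <= .05` with linear
fold change `>= 2`. These inequalities are deliberately pinned and
boundary-tested, since consensus lists are sensitive to them.

## GSEA and risk pathways

The ranking metric is signal-to-noise,
`(mu_case - mu_ctrl) / (sd_case + sd_ctrl)`, with each group sd floored at
`max(0.2 |mu|, 0.2)` — the conventional guard against near-zero variances
dominating the ranking. Ties are broken lexicographically by feature id so
rankings are strict and reproducible. The enrichment score is the weighted
Kolmogorov-Smirnov running sum with hit-weight exponent 1 (configurable;
weight 0 recovers the classical two-sample KS walk, which the tests verify
against a brute-force oracle). The leading edge — the *core genes* — is the
set members at or before the walk extremum (after it, for negative scores).
A magnitude tie between the positive and negative extremum resolves to the
positive one; this convention is applied identically in the fast
permutation path and the full-walk path so the two can never disagree.

Significance is a phenotype-permutation p:
`p = (1 + #{|ES_perm| >= |ES_obs|}) / (1 + n_perm)`, with labels permuted
`n_perm = 1000` times by default and permutations shared across pathways.
We compare |ES| over *all* permutations rather than within the same-signed
subset: |ES| is exchangeable between the observed labeling and its
permutations under the null, so this p is exactly uniform on its support
for a null pathway and attains `1/(n_perm + 1)` for a strongly enriched
one. The same-sign variant halves the effective denominator (the permuted
ES sign is close to a fair coin even for strongly shifted pathways, because
the sign follows the permuted group overlap), which makes its attainable
minimum ~`2/n_perm` and its small-sample behavior erratic; we therefore do
not use it.

A pathway is a *risk pathway* when its nominal p is below 0.1 in strictly
more than half of the datasets. With two datasets this means both — the
strict reading of a ">50%" consensus rule; the fraction is a parameter for
users who prefer a weaker rule. Nominal p (not an FDR q) drives this rule;
NES/FDR machinery is deliberately out of scope.

## miRNA-pathway association

For DE miRNA `i` and pathway `A`, with background of `N` genes, `K` targets
of `i` in the background, `M` pathway genes in the background, and overlap
`x`, the association p is the upper-tail hypergeometric probability
`P(X >= x)`, computed in log space and verified against combinatorial
enumeration to 1e-12. Benjamini-Hochberg adjustment is applied across the
full (miRNA x pathway) table and pairs are flagged at adjusted `p < .05`;
a flag restores raw-p thresholding. The default background is the
intersection of the genes measured on the mRNA platform with the union of
the target-map and pathway universes: the test is only meaningful over
genes that could have appeared in both a target set and a pathway.

## Network and topology

Triples (miRNA, gene, pathway) require all of: the gene is a risk gene, the
(miRNA, gene) pair is in the target map, the gene belongs to the pathway,
and the pathway is a risk pathway. PPI edges are overlaid only between risk
genes that appear in at least one triple. Topology treats the heterogeneous
network as one undirected simple graph (metrics spanning all three node
types, as topology tables in this literature do); shortest-path metrics are
also reported for the risk genes within the full PPI network, where hubs
are better calibrated. Conventions are the Cytoscape NetworkAnalyzer ones:
unnormalized betweenness with each unordered pair counted once,
component-wise closeness `(n_reachable - 1) / sum d`, local clustering
`2T/(k(k-1))`, and the topological coefficient
`TC_v = mean_u (shared(v, u) + [u ~ v]) / deg(v)` over partners `u` sharing
at least one neighbor (0 for degree < 2). All six metrics are checked
against a brute-force Floyd-Warshall/path-counting oracle on random graphs.
Hubs are the top 3 by degree, ties broken by betweenness then id.

## Biomarker AUC

Single-feature discrimination is scored by stratified 5-fold
cross-validation: a univariate logistic score is fit per training split and
held-out samples are pooled before computing the ROC and its Mann-Whitney
AUC (ties counted half). Pooling, rather than averaging per-fold AUCs,
avoids the small-fold variance of per-fold estimates; a raw-expression mode
(no fitting) is provided, and for a single feature the two agree up to the
logistic sign. The logistic choice is the simplest classifier that makes
cross-validation meaningful for one feature; nothing in the pipeline
depends on it beyond the AUC ranking.

## Cross-species matching

Matching is purely lexical: strip a lowercase three-letter species prefix
(`hsa-`, `rno-`, ...) when the remainder still looks like a miRNA name,
lowercase, and keep `-5p`/`-3p` arm suffixes verbatim. Arm-resolved ids
only match the same arm (a collapse flag exists); no ortholog database is
consulted. This mirrors how shared DE-miRNA lists are constructed in
practice and keeps the operation deterministic and offline.

# The synthetic bundle and what it does (not) show

`simulate_bundle()` generates the full input set with planted truth. The
defaults are the study conditions the pipeline is designed for: two mRNA
studies of 9 vs 9 samples, one miRNA study of 33 vs 58, a 2400-gene and
150-miRNA universe, 10 pathways of 15-30 genes, 10% DE features with a
log2 effect of 1.0 on Gaussian noise of sd 0.5, ~25 validated targets per
miRNA, a preferential-attachment PPI network (attachment 2), and a small
companion rat miRNA study (4 vs 4, log2 effect 1.5 so the fold-change rule
is attainable) sharing 3 DE miRNAs with the human study. The original
cohorts publish no effect sizes or variances, so these values were chosen
once for testability — an effect of 2 within-group sds gives per-feature
power near 1 at n = 9 vs 9, which is what an end-to-end recovery check
needs — and are not revisited.

Identifiability choices make the planted structure the unique recoverable
signal: planted pathways draw members from disjoint pools and are the only
pathways containing shifted genes; extra DE genes live outside all
pathways; background miRNAs never target planted-pathway genes, while each
planted miRNA places 60% of its targets inside its pathway (>= 5x the
background target density). Null pathways overlap one another freely, as
KEGG sets do. The miRNA feature space is disjoint from the gene space;
the only linkage is the target map.

What passing tests on this bundle do *not* show: robustness to batch
effects, probe-level artifacts, correlated noise within pathways,
mis-annotated targets, or identifier drift — none of which the generator
emulates. The bundle validates the statistical machinery and the plumbing,
not the biology of any particular dataset.

# Numerical and design details

- Probe collapsing at load time averages rows sharing a feature id;
  features with missing cells are dropped by default (threshold
  configurable), and the remaining missing cells (if a nonzero threshold is
  chosen) are mean-imputed. Averaging before/after log transform is not
  distinguished because inputs are assumed already log-scale.
- Zero-variance degenerate DE records: equal means give `t = 0, p = 1`;
  unequal means get the smallest representable p and a `degenerate` flag,
  so they survive Fisher combination without producing `-Inf` logs.
- `hypergeom_upper_tail()` sums in log space with a max-shift; `bh_adjust()`
  is the textbook step-up with a cumulative minimum.
- Every stochastic step takes an explicit seed; `run_pipeline()` fans a
  single global seed out to per-stage seeds deterministically, so a run is
  reproducible end to end from one integer.
- Problem sizes in the test suite (e.g. 200 permutation-calibration
  repeats at `n_perm = 100` on 1000 features; 100 random graphs up to 50
  nodes for the topology oracle) were chosen as the smallest sizes at which
  the distributional checks have useful resolution.

# Known limitations

- The GSEA implementation omits NES normalization and gene-set permutation
  mode; the consensus rule operates on nominal p values.
- The moderated t supports only the two-group design — no covariates,
  contrasts, or paired structures.
- miRNA-pathway association treats target sets as fixed and validated;
  prediction uncertainty in the target map is not modeled.
- Cross-species matching is lexical; paralogs with different numbering will
  not match.
- `fraction_de_genes` interacts with the planted pathways: the planted
  pathway members are always DE, so the effective DE fraction cannot drop
  below their share of the universe.
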