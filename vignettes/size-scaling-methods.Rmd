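---
title: "Methods: correlating gene expression and metabolites with cell size"
author: "sizeScaling authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlating gene expression and metabolites with cell size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizeScaling)
```

## The scientific setting

When hepatocytes are prevented from dividing (a liver-specific *Cdk1*
knockout) and the liver is then forced to regenerate by partial
hepatectomy, the remaining cells grow by hypertrophy instead of
proliferating. Together with the unperturbed control genotype, before and
after surgery, this produces four nearly isogenic sample groups whose
cells span roughly a 1x to 2.5x range of relative nuclear radius — a
continuous cell-size gradient in vivo, with nuclear radius serving as the
size proxy. Correlating every transcript and metabolite against that
gradient asks a simple question: which parts of the molecular economy
scale up with cell volume, and which fall behind?

This package implements that analysis as a reusable pipeline:

1. per-feature Pearson correlation with the size gradient, with
   confidence intervals, p-values and multiplicity adjustment;
2. gene-set scaling profiles (binned correlation distributions against a
   size-normalised whole-cell background) compared by a two-sample
   Kolmogorov–Smirnov test;
3. connectivity of size-correlated genes on a protein-interaction
   network, tested against random same-size gene sets;
4. lipid-class summaries of the metabolite correlations;
5. an overlap analysis separating genotype effects from size effects;
6. the geometric surface-area-to-volume expectation used to interpret
   membrane-lipid scaling.

Because the underlying liver data are not publicly deposited, the package
ships a synthetic-data generator that emulates the study design with
planted, known signal; every downstream stage is tested against that
ground truth and against independent brute-force oracles.

## Per-feature statistics

For feature $i$ with abundances $y_{ij}$ over samples $j$ with relative
radii $r_j$, the package computes the Pearson correlation
$\rho_i = \mathrm{cor}(y_{i\cdot}, r_\cdot)$ over **all** samples, pooling
the four groups. The p-value uses the exact-null $t$ statistic
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom; the
confidence interval uses the Fisher $z$ transform,
$\tanh\!\big(\operatorname{atanh}\rho \pm z_{1-\alpha/2}/\sqrt{n-3}\big)$,
at a 90% level by default, matching the interval bands customarily drawn
on per-gene scatter plots. The CI construction behind such bands is not
uniquely determined by convention; Fisher $z$ was chosen because it is
the standard closed form and its coverage is verified empirically in the
test suite (0.90 ± 0.03 at $n = 12$ over 2000 bivariate-normal
simulations).

Choices worth making explicit:

* **Linear versus log abundance.** Correlations are computed on the
  abundance scale as provided, because expression-versus-radius trends in
  this setting are close to linear on the measurement scale. An opt-in
  `log2_transform` flag exists; in the noiseless limit of the generator
  the log scale recovers planted slopes with $|\rho| = 1$ exactly, which
  the tests exploit.
* **Degenerate features.** A feature with zero variance has no defined
  correlation; it is reported as missing and excluded from the BH
  adjustment rather than silently assigned 0.
* **Perfect correlations.** $|\rho| = 1$ would give $p = 0$; the package
  reports the smallest positive double instead so that log-scale
  summaries stay finite.
* **Multiple testing.** The adjustment procedure behind "adjusted p"
  thresholds is taken as Benjamini–Hochberg step-up, the field default;
  it is validated against a literal step-up oracle.
* **Fold change.** The largest-versus-smallest-cell fold change is
  $\log_2\!\big((\bar y_\mathrm{largest} + c)/(\bar y_\mathrm{smallest} + c)\big)$
  over group means, with pseudocount $c = 1$ for gene matrices and
  $c = 0$ for metabolite intensities (strictly positive by
  construction). A tie for the extreme group radii is an error rather
  than an arbitrary pick.
* **Binning convention.** All histograms over $[-1, 1]$ use
  left-closed/right-open bins with a closed terminal bin, so $\rho = 1$
  is counted exactly once.

## Gene-set scaling profiles

A set's scaling profile is the binned distribution of its members'
correlations. For comparability, the whole-background histogram is
rescaled so that its counts sum to the set's measured size; the
conservation property (rescaled background counts sum to the set size) is
asserted for every profile. The default background is the union of all
annotated features, because comparing a set against "annotated genes"
avoids the compositional bias of unannotated features; `all_features` is
available as an alternative. The tested set stays inside its background
(the whole-cell profile is the same for every set); an exclusion flag
exists for sensitivity analysis.

Set versus background is compared with a two-sample, two-sided
Kolmogorov–Smirnov test: asymptotic p by default, exact when both samples
have at most 25 untied values. KS p-values are reported both raw and
BH-adjusted across the sets of a collection, since whether such analyses
adjust across components varies in practice.

The same machinery runs in `log2fc` mode, where the per-feature statistic
is a log2 fold change rather than a correlation — the form needed for
two-condition designs (e.g. an RNAi perturbation that enlarges cultured
cells), in which case bins tile the observed fold-change range instead of
$[-1, 1]$.

Transcription-factor family summaries and lipid-class summaries reuse
this operation; lipid classes are reported only when they have at least
five measured members ("more than four"), and are ranked by median
correlation, with the mean size fold change carried alongside.

## Network connectivity null

For the significantly size-correlated genes (adjusted p < 0.05, one
sign), the package counts the interaction-network edges with both
endpoints in the set and divides by the set size ("edges per gene").
The phrase *connections per gene* is ambiguous between induced edges per
gene and mean degree (a factor of 2); the induced-edges reading is used
and recorded in the result's `statistic` field so ratios remain
comparable.

The null model draws random gene sets of the same size uniformly without
replacement — the literal reading of "similarly sized random networks" —
from a configurable universe (default: network nodes, typically
intersected with the measured features). The enrichment ratio is
observed over null-mean edges per gene; the empirical p uses the add-one
rule $(1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$, so it is never 0.
Genes absent from the network stay in the denominator, which is
conservative. For universes small enough to enumerate, an exhaustive
mode computes the exact null; the sampled null is tested to converge to
it, and the empirical p is calibrated (fraction below 0.05 within
0.05 ± 0.02) on unstructured random networks. Degree-preserving rewiring
nulls are deliberately out of scope.

## Genotype effects versus size effects

Because the enlarged cells are all of one genotype, a genotype effect
and a size effect are partially confounded. The package defines
"genotype-affected" features by a Welch two-sample test of
log2 abundance between genotypes at a fixed timepoint — pre-hepatectomy
by default, which isolates the deletion from the regeneration response —
with BH adjustment and a fold-change threshold (default
$\log_2 1.5$). Welch was preferred over a pooled-variance t because
group variances are not assumed equal; with 2–3 replicates per group
this is a screening statistic, not an inferential claim. The overlap of
that set with the positively and negatively size-correlated sets is then
reported as "$x\%$ ($a$ of $b$)", the percentage referring to the
size-correlated set.

## The synthetic study and what it does (not) show

`simulateStudy()` generates the full artifact suite under one global
seed, which drives independent named substreams so each artifact can be
regenerated on its own. Its defaults are the package's statement of the
study conditions:

* **Design:** 4 groups × 3 replicates. Per-sample radii are lognormal
  around group means (1.0, 1.05, 1.3, 2.5) with CV 0.05, renormalised so
  the control/pre mean is exactly 1. Control cells are essentially
  unchanged by hepatectomy; knockout cells after regeneration sit inside
  the published 2–3x radius range; the modestly enlarged knockout/pre
  value is a free choice. The replicate count is not published for the
  molecular data; 3 is a typical in-vivo omics depth and is
  configurable.
* **Features:** log2 abundance is linear in relative radius plus
  Gaussian noise (sd 0.25), the simplest generative model consistent
  with near-linear observed trends; slopes are ±U(0.5, 1.5) per unit
  radius for the 30% positive / 12% negative classes (echoing the
  published asymmetry of 302 positive versus 118 negative strong
  correlators without claiming its exact values) and 0 for the 58% null
  class; baselines are lognormal (log2 mean 6, sd 2) so abundance strata
  exist.
* **Genotype-only effects:** 50 null-class genes get a ±2 log2 shift
  along the knockout indicator *residualised against radius*. Genotype
  and size are confounded in this design, so a raw indicator shift would
  itself be a size effect; the residualised contrast is the generative
  meaning of "affected by the deletion, not by size", and makes the
  planted genotype set disjoint from the size-coupled classes by
  construction.
* **Annotations:** a mitochondria-like set (drawn 90% from the negative
  class), a cytoskeleton-like set (90% positive), and null-class decoys;
  sets never share members. Lipid classes include a
  triacylglyceride-analog class (90% positive-slope metabolites, the
  storage-lipid accumulation signature), a sterol-like negative class,
  neutral phospholipid/fatty-acid classes, and a 4-member class that
  exercises the size filter.
* **Network:** Erdős–Rényi with edge probability 0.3 inside the planted
  module (the negative class, emulating a dense mitochondrial cluster)
  and 0.02 elsewhere.

What the generator does **not** emulate: read-count sampling noise and
library-size artifacts, batch effects, correlated noise between features,
mass-spectrometry peak-shape or annotation ambiguity, hierarchical GO
structure, and degree heterogeneity of real interaction networks.
Passing tests therefore demonstrate that the statistics recover planted
linear size-coupling under Gaussian noise on this design — they do not
certify performance on raw sequencing data, nor that a real network null
is exchangeable with an Erdős–Rényi one.

## Numerical and design choices

* All randomness flows through explicit seeds; identical (config, seed)
  pairs give byte-identical outputs, which the tests assert end to end.
* Ties in abundance-stratified summaries are broken by table order
  (stable), making strata deterministic.
* The Fisher-z interval is clamped so the point estimate always lies
  inside its own CI, including at $|\rho| = 1$ where the transform
  diverges.
* Result tables serialise floats at 6 significant digits; the config
  echo uses 15 digits so a re-run from the echo reproduces the run
  exactly.
* Problem sizes used by the test suite: oracle equivalence on 100 random
  small instances per statistic; CI coverage on 2000 simulations at
  n = 12; calibration on 1000 replicates each; planted-signal recovery
  on 100 seeded studies of 1000 genes, 300 metabolites, 12 samples.

## Known limitations

* Pooling all samples into one correlation treats animals as independent
  points and ignores within-group structure; a mixed-effects model over
  animals is out of scope.
* With n = 12 samples the per-feature p-values are coarse, and the
  significant sets are sensitive to the BH threshold; the set-level and
  network-level summaries are the robust outputs.
* The random-gene-set null does not preserve degree structure; on
  networks with heavy-tailed degrees the enrichment ratio can be driven
  by hub membership.
* The genotype screen at 2–3 replicates per group has limited power and
  is intended to bound the genotype/size overlap, not to produce a
  definitive differential-expression catalogue.

## A worked example

```{r example, eval = FALSE}
library(sizeScaling)
study <- simulateStudy(seed = 1)
ct <- correlateFeatures(study$genes)
profileSummary(setScalingProfiles(ct, study$gene_sets))
neg <- selectSignificant(ct, "negative")
connectivityTest(study$network, neg,
                 universe = intersect(networkNodes(study$network),
                                      ct$feature_id),
                 seed = 1)
```

The README shows the printed output of this analysis and
`scripts/acceptance.R` recomputes the same quantities from scratch.
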