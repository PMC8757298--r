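---
title: "Methods and numerical conventions in moqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical conventions in moqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`moqtl` maps expression QTL in eight-founder multiparent populations such
as Diversity Outbred (DO) mice. This vignette is the package's account of
the statistical model, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical conventions taken
where a published description leaves the implementation open.

## The mapping model

The genotype of individual *i* at marker *m* is the probability vector
`p_im·` over the eight founder haplotypes (letter order A–H = A/J,
C57BL/6J, 129S1/SvImJ, NOD/ShiLtJ, NZO/HlLtJ, CAST/EiJ, PWK/PhJ,
WSB/EiJ). Relatedness is the average allele-probability inner product,
`K_ij = (1/M) Σ_m Σ_f p_imf p_jmf`; for a scan of chromosome *c* the
kinship is rebuilt leaving out all of *c*'s markers (LOCO), so the tested
locus does not contaminate the polygenic control.

For each phenotype and chromosome the null model
`y = Xβ + g + ε, g ~ N(0, σ²_g K_LOCO)` is fit by REML: one symmetric
eigendecomposition of the kinship and a bounded one-dimensional
optimization of the profiled REML criterion over the variance ratio
(parametrized as the logit of `h = σ²_g/(σ²_g+σ²_e)`, tolerance 1e-8, with
an explicit check of the `h = 0` boundary). Eigenvalues are rescaled so
the kinship has unit mean diagonal; this puts `h` directly on the
heritability scale and makes the generator's target h² and the
estimator's ratio commensurable. The fitted variance components are held
fixed across that chromosome's markers — the standard convention in
multiparent scan software, trading a small amount of exactness for an
enormous amount of tractability — and each marker is tested by
generalized least squares in the whitened space:

`LOD = (n/2) log10(RSS₀/RSS₁)`

with the full model = covariates + the 8 founder dosages (cell-means
coding: the dosage block spans the intercept, which is therefore dropped
from the marker block), and the null = covariates only. The interactive
model adds dosage×covariate products to the full model while keeping the
same covariates-only null, which is why interactive-model LOD scores and
their permutation thresholds run systematically higher than additive
ones. Diet-subset models are additive scans of the subsetted cohort with
no diet covariate. With the kinship zeroed the whole construction
collapses exactly to Haley–Knott regression, a property the test suite
asserts at 1e-8 against an independent least-squares oracle.

**Marker-block rank.** The dosage block is doubly degenerate (its columns
sum to the intercept, and founders can be locally absent), and pivoted QR
proved not rank-revealing on these blocks — it occasionally kept a
direction that existed only as rounding noise of the residualization,
inflating LOD by ~0.01. Orthonormal bases of the residualized marker
blocks are therefore taken from the SVD, keeping singular values above
1e-8 of the leading one.

## Permutation thresholds

Significance is per phenotype: the rows of the phenotype are shuffled
against genotype + covariates + kinship, the genome-wide maximum LOD is
recorded, and the 95th quantile (linear interpolation between order
statistics, R type 7) of the null draws is the phenotype's threshold.
The two-stage screen runs 50 permutations for every phenotype, forms the
conservative screen threshold `Q90 − SE(Q90)` (Maritz–Jarrett kernel
estimator by default; a bootstrap option is provided since the published
procedure names no formula), and runs the full null only for phenotypes
whose observed maximum exceeds it.

Two conventions matter here:

* Permutation streams are hashed per phenotype from the master seed, so
  the 50 screening draws are the *first 50 draws of the full stream*.
  Adding or removing phenotypes never changes another phenotype's null,
  and the two-stage result can be compared exactly against exhaustive
  permutation — the test suite reproduces, in miniature, the validation
  that both procedures select the same significant set.
* The null variance components for a phenotype are estimated once from
  the observed data and held fixed across its permutations (the
  per-chromosome convention above, extended across shuffles). Refitting
  REML per permutation changes thresholds by far less than their Monte
  Carlo error and costs two orders of magnitude more.

## Peaks and characterization

At most one peak per chromosome is called — the maximum-LOD marker, if
strictly above the threshold, ties broken toward the smaller position; a
phenotype significant on several chromosomes yields a multiple-mapping
record. Support intervals walk outward from the peak (inclusive) to the
first marker whose LOD is at or below `peak − 1.8`; if none occurs the
bound is censored at the chromosome end. The inclusive walk makes a zero
drop collapse the interval onto the peak marker, and the "first marker at
or below" convention (rather than "last marker above") is the
documented choice where the rule is ambiguous.

A peak is **cis** when it lies on the feature's chromosome within 4 Mb
(inclusive) of its TSS; 1 Mb is available as a sensitivity switch, and
shrinking the window can only convert cis calls to trans. Variance
explained is deliberately *unmixed*: the difference of plain least-squares
R² between (covariates + dosages) and (covariates only) at the peak
marker, even though the scan itself is a mixed model — the convention of
the analysis this package operationalizes. BLUP founder effects treat the
8 dosages as a random effect with variance estimated by a second 1-D REML
(Woodbury identities through the 8×8 core), on top of the polygenic
whitening; they are shrunken relative to least squares, and under a null
trait the marker-variance REML sits at its zero boundary about half the
time — so null BLUPs are usually, but not always, near zero.
Heritability is the REML ratio with the full (non-LOCO) kinship.

## Architecture statistics

* **Founder enrichment**: each peak's 8 BLUPs are mean-centered and
  scaled to unit SD; absolute scaled effects are compared across founders
  by Kruskal–Wallis, with Dunn's post hoc z-tests on the pooled ranks
  (tie-corrected) and BH adjustment. Dunn's test is implemented in the
  package — no suitable dependency was available — and is verified
  against a manual computation in the tests.
* **Colocalization**: all same-chromosome eQTL–mirQTL pairs with
  overlapping closed support intervals, with the peak-to-peak distance in
  Mb (zero = same marker).
* **Correlation structure**: every miRNA×mRNA Spearman correlation, with
  t-approximation p-values and BH across the full cross-product;
  multi-mapping mRNAs are removed before category comparisons, and
  categories (cis / trans / no-eQTL) are compared by pairwise Wilcoxon on
  |rho| among significant pairs. Spearman's rho is invariant to the
  monotone transforms between the native and analysis scales, so either
  panel scale gives identical results.
* **Differential expression**: features must reach the expression floor
  (mRNA ≥ 4 log-intensity, miRNA ≥ 50 RPMMM) in at least 25% of samples
  — both bounds inclusive, so a feature exactly at the floor in exactly a
  quarter of samples passes — then Wilcoxon rank-sum by diet with BH at
  0.05. `wilcox.test`'s exact/normal switching handles small groups.
* **Allele×diet ranking**: at each interactive-model eQTL, a plain
  least-squares F-test of the dosage×diet block (rank-aware, since both
  blocks are degenerate); BH-significant phenotypes are kept only when
  both diet-subset models contain a concordant peak (same chromosome,
  overlapping intervals, same cis/trans class). The per-founder percent
  difference of HFCA vs HP BLUPs uses HP as reference with a floor of
  `0.05 × SD` of that phenotype's 16 effect values — near-zero reference
  effects otherwise make the score explode — and the divergence score
  (the summed absolute percent differences) is invariant to a common
  positive rescaling of both effect vectors.

## The synthetic generator

`simulate_do_dataset()` emulates exactly the features the statistics
need: founder mosaics from a marker-to-marker Markov switch process
(Poisson events at `recomb_rate`/Mb, new founder uniform over the other
seven, so the expected event count is rate × length; no interference, no
founder linkage disequilibrium), allele probabilities softened by
spreading 2% of the mass uniformly (emulating probabilistic genotype
reconstruction), an unbalanced two-diet assignment (default 134:109),
polygenic backgrounds drawn with covariance proportional to the realized
kinship and scaled to a target h², diet main effects, and planted
cis/trans QTL with mean-centered founder effect vectors (cis at the
marker nearest the feature TSS). miRNA panels are emitted on a
nonnegative RPMMM-like scale (`200·2^y`) and mRNA on a log-intensity-like
scale (`y + 7`); the default miRNA panel has 246 features. Generator
sub-streams (mosaics, diet, effects, noise) are hashed separately from
the master seed, so adding phenotypes never perturbs genotypes.

What it does **not** emulate — and hence what passing tests do not show
about real data: realistic recombination maps and LD, X-chromosome
dosage, the empirical distribution of founder effect sizes (exposed as
free parameters rather than claimed), array/sequencing noise models, and
genome-scale marker density. One desk-scale artifact deserves emphasis:
with two chromosomes, LOCO kinship can absorb at most half of the
polygenic background, and the remainder manifests as spurious trans
peaks; a 20-chromosome genome dilutes this twentyfold. Test problem
sizes (typically 80–400 individuals, 2–4 chromosomes of 20–40 markers,
40–200 phenotypes, 50–200 permutations) were chosen as the smallest
panels at which each property is statistically decidable.

## Degenerate inputs and edge conventions

Constant phenotypes scan to LOD 0 with a warning rather than an error; a
single-chromosome tensor makes LOCO fall back to a zero kinship with a
warning; zero kinship short-circuits to plain least squares (no REML);
markers at which fewer than two founders are represented are rejected for
BLUPs; Fisher tables with a zero denominator report an infinite sample
odds ratio (flagged) with the exact p-value still computed; support
intervals at chromosome ends are censored, not extrapolated.

## Known limitations

Dominance and multi-QTL joint models are out of scope, as are Bayesian
credible intervals, X-chromosome covariates, and gene-set enrichment.
The interaction ANOVA and variance-explained computations are unmixed by
design (see above). Permutation p-values inherit the granularity of the
null size (1/1000 by default). The two-stage screen is conservative but
not guaranteed to equal exhaustive permutation when an observed maximum
falls in the narrow band between the screen threshold and the full
95th-quantile threshold; in practice (and in the test suite) the sets
coincide.
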