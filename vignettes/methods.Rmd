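---
title: "Methods: from growth records to candidate functional variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from growth records to candidate functional variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedomics)
```

feedomics reconstructs, as reusable and testable code, a common
multi-omics strategy for explaining GWAS signals of a quantitative
production trait — here a feed-conversion-ratio (FCR)-like trait in pigs:
find genome-wide-significant SNPs with a mixed-model scan, keep those
falling inside differential open-chromatin regions (ATAC-seq), assign
candidate genes within the same topologically associated domain (TAD),
attach expression evidence (RNA-seq), and sanity-check each variant by
comparing trait values across genotype classes. This vignette documents
the statistical models, the defaults and why they are set where they are,
and the choices made where the design was genuinely open.

## Phenotype quality control

Growth is modelled per animal as a straight line, weight (kg) = a + b ×
age (days), fit by ordinary least squares. Animals whose records are
unreliable show up as large residual scatter around their own line, so the
screen works on the per-animal residual SD: an animal is excluded when its
residual SD exceeds `median + k × MAD` over all animals (MAD with the
1.4826 consistency constant; default `k = 3`). The rule is robust — a
handful of grossly non-linear growers cannot drag the cutoff — and
scale-free, so it transfers across units and cohorts. `k` is exposed
because the appropriate stringency depends on how noisy the weighing
protocol is.

Descriptive statistics use the sample (n−1) SD throughout. Normality of
the trait is assessed with the D'Agostino–Pearson omnibus K² test
(skewness and kurtosis Z scores, χ² with 2 df), implemented in the
package and verified against an independent reference implementation; it
has no upper sample-size limit, which matters for cohort-scale traits.
Shapiro–Wilk is available as an option for small samples. The test needs
n ≥ 8; below that the summary is returned with the test fields `NA`.

Extreme groups (default `k = 3` per tail, matching typical RNA-seq
replicate numbers; ATAC layers often use 2) are the `k` largest and `k`
smallest trait values, with ties broken by animal id so the selection is
reproducible and invariant to row order.

## Genotype quality control

A variant is kept iff its call rate is ≥ 0.90 **and** its minor allele
frequency (computed on non-missing dosages as `min(f, 1−f)`) is ≥ 0.05 —
"below" is strict, so boundary values survive. Variants with no calls are
dropped with reason `no_calls` rather than tripping a division. Imputation
itself is out of scope; the concordance metric compares any two call sets
over their shared samples and variants (matched on chromosome, position,
ref and alt; swapped-allele pairs are counted and reported, never silently
flipped) as the fraction of identical dosages among entries non-missing in
both.

## The mixed-model association scan

The trait model is the standard mixed linear model

y = X b + g β + u + e,  u ~ N(0, σ²_g K),  e ~ N(0, σ²_e I),

with X an intercept, the top GRM principal components (default 5) and
one-hot-coded categorical covariates (first level dropped); g is the
tested dosage vector. K is the VanRaden method-1 genomic relationship
matrix: dosages column-standardized by `sqrt(2f(1−f))` after mean
imputation of missing entries, `K = W W' / m`; monomorphic variants are
skipped and counted. For a variant on chromosome c the GRM excludes
chromosome c entirely (leave one chromosome out), so the polygenic term
cannot absorb the tested signal (proximal contamination).

Variance components are estimated once per LOCO GRM by REML on the null
model. One eigendecomposition `K = U D U'` rotates the model so the
covariance is diagonal, leaving a one-dimensional profile restricted
likelihood in `h² = σ²_g/(σ²_g+σ²_e)`, maximized by Brent search on
`[1e−6, 1−1e−6]` with tolerance 1e−8. An identity-like GRM makes only
σ²_g + σ²_e identifiable; the fit detects this as a flat likelihood
(range over an h² grid below 1e−6 relative) and reports it, falling back
to h² = 0 in the scan. A perfect fixed-effect fit (zero residual) is
reported with a `zero_residual` note instead of a degenerate likelihood.

Each variant is then tested by a generalized-least-squares Wald statistic
in the whitened space (`1/sqrt(h² d_i + 1 − h²)` scaling of the rotated
data), with the variance components held fixed — the classic two-stage
device that costs one eigendecomposition per chromosome instead of one
REML per variant. One refinement: the residual *scale* is re-estimated per
variant from the whitened residuals, making the statistic a t ratio. Two
consequences: (i) with σ²_g = 0 the statistic is *numerically identical*
to the per-variant OLS t statistic, so the OLS oracle check is an exact
equality rather than an approximation; (ii) under the mixed model the
correction is O(1/n) and the two-sided standard-normal p remains
appropriate at cohort sizes. Variants with zero variance after whitening
(monomorphic after imputation) get `p = 1` with reason `zero_variance`.

The genome-wide threshold defaults to Bonferroni, α divided by the
realized number of tests; fixed thresholds used in the GWAS literature
(e.g. 5e−8, or a chip-specific 4.55e−8) can be supplied instead via
`gwas_threshold`.

## Differential testing of count layers

RNA genes and ATAC peaks share one negative-binomial pipeline, differing
only in the classification preset: a feature is `up`/`down` when p < 0.05
(strict) and |log2FC| ≥ 1 (RNA) or ≥ 0.58 (ATAC, i.e. a 1.5-fold change);
both thresholds are config-overridable. Raw p is used for status;
Benjamini–Hochberg adjusted p is computed and reported alongside.

Size factors are median-of-ratios: for each sample the median, over
features positive in all samples, of the count divided by the feature's
geometric mean — the linear-scale median, reported unnormalized.
Dispersion α (variance μ + αμ²) is estimated per feature by method of
moments from within-group variances of normalized counts (shot-noise term
`μ × mean(1/sf)` subtracted, df-weighted across groups, floored at 0),
then shrunk with weight `w = 0.5` toward a mean–dispersion trend
`α ~ a0 + a1/μ` fitted across features. The GLM (log link, intercept +
group, size factors as offsets) is fit by IRLS with α fixed; the Wald
statistic on the group coefficient is referred to a **t distribution with
`df_within/(1−w)²` degrees of freedom** rather than the normal. The
rationale is Satterthwaite-style: the plug-in dispersion carries only
`Σ(n_g − 1)` df of information (4 at n = 3+3), inflated by `1/(1−w)²`
through the trend shrinkage; a normal reference is measurably
anti-conservative at these depths (empirical type-I ≈ 0.07 at nominal
0.05), while the effective-df t restores calibration (≈ 0.05) without
costing power against planted two-fold changes. As w → 1 or as replicate
numbers grow the reference converges back to the normal.

Groups of size 2 are allowed — accessibility experiments often have only
two replicates — with a warning, because a 2-sample variance estimate is
genuinely unstable. No outlier filtering, independent filtering or
fold-change shrinkage is applied: status depends on raw p and raw log2FC
only, and exact equality with any specific external tool is a non-goal
(one test cross-checks direction and magnitude against an independent NB
implementation on strong planted signal).

## Integration

Coordinates follow two conventions on purpose: variant positions are
1-based (VCF), intervals are 0-based half-open (BED). A single shared
utility owns the conversion; a variant at position p overlaps
`[start, end)` iff `start < p ≤ end`. Overlap queries run on indexed
interval containers but are contract-identical to the double loop, which
the tests assert on random instances.

The linking pipeline: keep variants below the GWAS threshold; keep those
inside peaks whose differential status is not `ns` (each peak carries its
tissue label); assign each surviving variant to its TAD (TADs are
validated non-overlapping per chromosome; positions in inter-TAD gaps
yield no links); emit one candidate link per gene *fully contained* in
that TAD (boundary-straddling genes are not assigned), annotated with the
gene's DE status and log2FC in every tissue; attach the genotype-class
comparison — per dosage class (0/1/2) n, mean and SD, plus a two-sided
Welch test of the homozygous-alternate class against the rest
(Kruskal–Wallis across the three classes as an option). Degenerate inputs
are reported deterministically: identical trait values give p = 1 with a
`zero_variance` flag; a single genotype class gives summaries with p = NA
and a reason.

Ranking is lexicographic: GWAS p ascending, then gene DE evidence (DE in
the peak's own tissue, then DE elsewhere, then none), then genotype-class
p, with a final (chromosome, position, gene) tie-break for a
deterministic total order. All genes in the TAD are emitted with evidence
attached; no external gene-function filter is applied — that judgement is
left to the reader of the report, which flags tissue-specific links via
the per-tissue columns.

## The synthetic cohort

Every stage is tested against data with planted truth. The generator
produces: genotypes as two independent allele draws per individual at a
variant frequency drawn uniformly from `maf_range` (default 0.05–0.5),
assigned contiguously to 5 chromosomes of 2 Mb — a deliberately small
genome so LOCO runs in seconds while exercising every code path; a trait
`y = Xb + Σ g_j β_j + u + e` with polygenic `u` built from standardized
non-causal dosages (VanRaden scaling, so its covariance is exactly h² ×
GRM and REML recovery is a fair test) and Gaussian `e` filling the
variance remainder; growth records with per-animal lines plus optional
corrupted animals at inflated noise; a regulatory landscape where
non-overlapping TADs partition each chromosome with gaps, peaks and genes
fall inside TADs, and each planted link constructs a peak over its causal
variant and a DE gene in the same TAD; NB counts with planted log2 fold
changes at the small group sizes the study designs actually use (3+3 for
RNA, 2+2 for ATAC).

Defaults describing the study-scale cohort: 500 animals, 5,000 variants,
h² = 0.3, one causal variant explaining 5% of trait variance (the effect
size is derived from the realized allele frequency), planted log2FC = 2
for the linked peak and gene, NB dispersion 0.05, pen and birth-month as
categorical covariates. Heritability and effect sizes are simulation
choices pitched at realistic values for production traits, not estimates
taken from any particular cohort. Missing dosages use `NA` in memory,
`./.` in VCF and the literal `NA` in the dosage TSV dialect.

What the generator does **not** emulate: linkage disequilibrium (variants
are independent), family/pedigree structure, genotyping batch effects,
GC-content or length biases in counts, and peak-calling artefacts.
Passing tests therefore demonstrate correctness of the statistical
machinery under a clean generative model, not robustness to every
real-data pathology.

## What the planted-recovery rate can and cannot show

With the default cohort, detection of the planted variant at the realized
Bonferroni threshold (≈ 1e−5) is the binding step of end-to-end recovery.
The GLS noncentrality for a variant explaining a fraction q of trait
variance is `sqrt(q·n / σ²_eff)`, and for a variant sharing the cohort's
covariance structure σ²_eff stays close to the *total* genetic + residual
variance: a mixed model describes the polygenic covariance, it does not
delete it from the denominator (at n = 500 vs ~4,000 background variants,
the GRM-BLUP could explain only ~1% of the polygenic term). That gives
noncentrality ≈ 5.0 against a threshold z of 4.42, i.e. per-seed
detection ≈ 0.7; the differential-peak and DE-gene steps are essentially
always recovered, and whenever the pair enters the report it ranks first.
The package reports the measured rates as they come; pushing the planted
effect or the threshold until recovery looks certain would only
misrepresent the power a study of this size actually has.

## Problem sizes in the test-suite

Unit tests run reduced instances (hundreds of samples/variants, hundreds
of features); the study-scale properties — null calibration of the scan
at 500 × 5,000 over 20 permutation seeds, REML recovery at n = 1,000 over
20 seeds, differential calibration at 2,000 features, end-to-end recovery
over 20 seeds — live in a dedicated acceptance test file and in
`scripts/acceptance.R`, which recomputes them from scratch and writes the
numbers as JSON. These sizes were chosen so the whole suite completes on
a laptop-class single core in a few minutes while keeping Monte-Carlo
noise well inside the asserted tolerances.

## Known limitations

* The scan's two-stage test holds variance components fixed per
  chromosome; exact per-variant REML would be slower and differs at
  O(1/n). Confidence intervals for h² are not reported.
* The dispersion trend is a two-parameter `a0 + a1/μ` curve; count layers
  with strongly non-monotone mean–dispersion relations would deserve a
  smoother.
* TADs are consumed as given (BED); acquiring a biologically appropriate
  TAD map is the user's responsibility, and only synthetic TADs ship with
  the package.
* With two tissues the report carries per-tissue evidence columns; more
  complex designs (paired tissues, covariate-adjusted counts) are out of
  scope.
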