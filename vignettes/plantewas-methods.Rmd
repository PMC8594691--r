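---
title: "Methods: association models, imputation and study simulation in plantewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association models, imputation and study simulation in plantewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantewas)
```

This vignette documents the statistical model, the numerical choices,
and the design decisions behind `plantewas`, together with what the
simulation-based tests do and do not demonstrate about real data.

## The association models

All three scans are ordinary least squares on a per-position response
vector, with two-sided *t* tests on a single coefficient:

* **Emodel**: `M_i ~ E + cvrt`; tested coefficient: `E`.
* **Gmodel**: `M_i ~ G_j + cvrt` for cis pairs; tested coefficient:
  `G_j`, with the 1/2/3 genotype code used as an additive numeric
  dosage.
* **GxE**: `M_i ~ G_j + E + G_j:E + cvrt`; tested coefficient: the
  interaction `G_j:E`.

Covariates are encoded as in `lm()`: an intercept, numeric covariates
as-is, categorical covariates one-hot with the first level dropped. The
design must be full rank and leave at least one residual degree of
freedom for the tested term; `design_matrix()` enforces both.

Rather than refitting a dense model per position, each scan residualizes
both the response and the tested predictor against the nuisance design
and regresses residuals on residuals (the Frisch–Waugh–Lovell
decomposition). The coefficient, its standard error computed with the
residual degrees of freedom of the *full* model, and hence the *t*
statistic and p-value are algebraically identical to the per-row full
fit; the test suite verifies agreement with naive `lm()` refits to
1e-8 relative on random instances with numeric and categorical
covariates.

An important implementation detail: residualization is performed one
position at a time against a prefactored QR decomposition. Multi-column
LAPACK kernels may choose shape-dependent code paths, which would make a
position's 15th decimal depend on which other positions share the
matrix. Column-at-a-time computation makes every per-position number
bitwise independent of the surrounding matrix, which is what makes
chunked scans exactly reproducible (below).

**Treating genotype as a dosage.** The genotype enters the regression as
a numeric 1/2/3 dosage rather than a two-degree-of-freedom factor. The
additive coding is the standard association-study choice and keeps one
interpretable coefficient per pair; the genotype-as-groups view (AA/AB/BB)
is preserved in the genotype interaction plot, which fits one trend line
per class. A categorical G (or a stratified fit per class) would be the
natural alternative; it costs residual degrees of freedom and was not
adopted.

### Multiple testing and chunked execution

Each scan applies the Benjamini–Hochberg step-up over all rows it
retained, per model and context, after dropping rows with non-finite
*t* statistics (zero residual variance — e.g. a response exactly
collinear with the predictor — produces an infinite statistic; such
rows carry no usable evidence). FDR is corrected globally, not per
chromosome: correcting within subsets changes every q-value whenever
the subset composition changes.

`chunked_scan()` splits the position set into contiguous blocks, runs
the scan per block without FDR, and merges with `merge_chunked()`,
which concatenates, re-sorts into the canonical (chromosome, position,
SNP) order, drops non-finite rows and recomputes BH globally. The
output is bitwise identical to a 1-chunk run for any partition — the
test suite asserts `identical()` on whole tables.

### The cis window

Gmodel and GxE test (position, variant) pairs on the same chromosome
with |variant start − position start| ≤ `distance` (default 2000 bp,
with VCF positions converted to 0-based starts). A cis window keeps the
pair count linear in the genome size and reflects the expectation that
methylation-disrupting variants act locally; an `all_pairs` switch
exists for small data sets. Variants that are constant across samples,
or whose extended design is rank deficient (e.g. a single genotype
class, or an interaction column collinear with the main effects), are
skipped and counted.

## Missing data

Uniting independently sequenced samples creates missing cells wherever
coverage drops. Two tools address this:

* `filter_missing(max_na_fraction)` — keep positions whose missing
  fraction is at most the threshold. The default 0 (zero tolerance)
  analyses only complete positions; the CLI exposes any fraction, and
  sweeping 0 to 1 in 0.1 steps is a useful sensitivity analysis.
* `impute_methylation(seed)` — replace each missing cell with a draw
  from a beta distribution fitted to the observed values at the same
  position by the method of moments (`fit_beta_moments`): with sample
  mean m and variance v, c = m(1−m)/v − 1, α = mc, β = (1−m)c. The
  method-of-moments fit is closed-form and well-behaved at the small
  per-position sample sizes involved; maximum likelihood is not
  offered. When v ≈ 0 (below 1e-12) or c ≤ 0 (empirical variance
  exceeding what any beta law allows, e.g. observed values {0, 1}),
  the fit is degenerate and the row mean is used instead.

The beta draw mimics the marginal distribution of the observed samples,
so imputed cells carry no systematic association with any predictor:
significant hits must be driven by the samples with real data.

**Locality of the imputation stream.** Each cell's draw is seeded by a
hash of (chromosome, start, sample id, master seed). Consequently the
imputed value at a position is identical whether the matrix holds that
position alone or a million others — the per-position p-values cannot
drift with chunking, subsetting, or per-chromosome splits. A global
sequential RNG stream would silently violate this. The hash is a
polynomial rolling hash over the key string, reduced modulo 2³¹−1 and
fed to R's Mersenne–Twister via `set.seed`; the Monte-Carlo tests
confirm the resulting draws reproduce the fitted beta's mean and
variance within three standard errors over 10,000 draws.

Genotype imputation (`impute_genotypes`) is intentionally simple:
variants above a missingness threshold are dropped, remaining missing
codes take the variant's modal code (ties resolve toward the variant
mean, then to the smaller code). Haplotype-aware imputation is a
different problem and out of scope; for the default VCF filters
(complete genotyping) the imputer is a no-op.

## Matrix assembly and input types

`union_positions` reproduces union-bedGraph semantics (the tests verify
against `bedtools unionbedg` on identical inputs). Coordinates are
0-based half-open everywhere internally; VCF positions are converted on
ingest. The four input types map to:

1. **MPs** — the union matrix as-is.
2. **DMPs** — `restrict_to_dmps`: keep positions inside the union of
   the per-comparison DMP sets.
3. **DMRs (positions)** — `restrict_to_regions`: keep positions inside
   any region; nested or abutting regions never duplicate a row.
4. **DMRs (averaged)** — `build_union_dmrs` then `average_over_regions`.

Union-DMRs are computed by splitting all intervals at every boundary
(elementary intervals, via interval disjoint-union) and keeping those
covered by at least a fraction X of the pairwise comparisons; a
comparison with two overlapping DMRs over an interval counts once. With
one comparison the regions pass through unchanged; X → 0 recovers the
full union and X = 1 the intersection. Adjacent kept intervals are
merged by default (`merge = TRUE`); keeping them separate is available
because both conventions are defensible. The brute-force per-base
counter in the test suite checks 100 random instances.

Region averaging uses the mean over *non-missing* positions, with a
cell missing only when the sample is missing at every covered position.
The alternative (propagating any missing position into a missing
region) would discard most regions before the NA filter; averaging over
what was observed maximizes retained data and lets `filter_missing`
make the retention decision explicitly.

The per-position variation filter (`filter_by_variation`) uses the
sample standard deviation (n−1 denominator) and/or the range
(max − min), both on the fraction scale; 0.10 corresponds to a 10%
range of variation, and SD thresholds like 0.028 (CpG) reproduce
published RRBS filter settings. Contexts never mix within a matrix; the
pipeline runs each context independently.

## The simulator

`simulate_ewas_data` emulates a targeted-bisulfite clonal common-garden
study:

| quantity | default | rationale |
|---|---|---|
| samples | 28 | a realistic clonal design across sites |
| covariate | 3 planting sites, logit offsets SD 0.3 | site is the canonical grouping covariate |
| environment | Normal(0, 1) | standardized climate variable |
| baseline methylation | Beta(2, 2), clamped to [0.02, 0.98] | broad, avoids infinite logits |
| biological noise | logit SD 0.5 | between-tree epigenetic variability |
| coverage | NB(mean 15, size 5) | targeted bisulfite depth of ~8–26× |
| counts | Binomial(coverage, p) | bisulfite read sampling |
| dropout | 10% per call | union-induced missingness |
| variants | MAF uniform in [0.1, 0.5], Hardy–Weinberg | filtered SNP panel |

Effects are planted on the logit scale so fractions stay bounded;
a G or GxE effect's driver is the nearest variant within the cis
window. Planted-effect rows may pin the driver's minor-allele
frequency and the baseline methylation: an effect recovery experiment
should measure detection of a *well-identified* effect — an interaction
whose driver is nearly monomorphic, or a logit effect at baseline 0.95,
is unidentifiable on the bounded fraction scale regardless of method —
rather than averaging over identifiability.

What the simulator does **not** model: linkage disequilibrium between
variants (variants are independent), spatial correlation of methylation
along the genome, bisulfite non-conversion, context-specific maintenance
dynamics, or population structure beyond the site covariate. Passing
tests therefore demonstrate correctness of the statistical machinery
under a clean generative model, not robustness to confounding in field
data — for real studies the covariate set carries that burden.

Problem sizes used by the test and acceptance runs: calibration pools
~5,000 positions per model at n = 50 over four replicate studies;
recovery uses 100 replicates of a 100-position, 10-variant study at
n = 50; oracle-equivalence checks use 200 positions × 50 samples × 3
covariates.

## Numerical and formatting choices

* Residual sums of squares are clamped at zero before the square root;
  an exact fit yields an infinite statistic, which the non-finite
  filter removes.
* Tables are written with 9-significant-digit formatting; write/read
  round-trips agree to better than 1e-6 relative for all magnitudes,
  and repeated runs are byte-identical (the golden-tree test relies on
  this).
* Ties for the major allele at a site resolve to REF; multiallelic and
  non-SNP records are skipped.
* Sample-sheet covariate types are inferred per column (numeric iff
  every entry parses); the sheet has no header row.
* The internal methylation scale is the fraction; bedGraph I/O converts
  from/to percentages.

## Known limitations

* **GxE power at moderate effect sizes.** A 1.0-logit interaction at
  n = 50 under the default count-noise model is detected at q < 0.1 in
  roughly half of replicates, not ≥ 90% as one might extrapolate from
  the Emodel (≈ 99%). The attenuation is intrinsic: the model fits a
  *linear* interaction on the bounded fraction scale, while the planted
  effect acts on the logit scale — samples pushed into the saturated
  tails contribute little or even oppositely-signed slope, and the BH
  correction across all cis pairs demands p ≈ 1e-3. Sensitivity probes
  (no missingness, halved noise, doubled coverage) raise the rate only
  to ≈ 0.88. Interaction scans at this sample size should be read as
  low-sensitivity screens.
* With very few samples the GxE model may be infeasible outright (it
  needs n ≥ rank(design) + 4); the worked example (n = 4) honestly
  yields empty GxE tables.
* Beta-distribution imputation preserves marginals but not
  correlations; at high missingness it dilutes true effects (imputed
  cells carry no signal), which is the conservative direction.
* The q-values are valid under independence-ish assumptions of BH;
  methylation autocorrelation along the genome is not modelled.
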