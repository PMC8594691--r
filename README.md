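# plantewas

Epigenome-wide association scans (EWAS) for plant bisulfite methylation
data, with genotype interaction models and beta-distribution imputation
of missing methylation values.

## The problem

Base-resolution bisulfite sequencing (WGBS/RRBS/targeted capture) yields
per-cytosine methylation fractions in the three plant contexts (CpG, CHG,
CHH). A common question in plant ecology and epigenetics is which
cytosines' methylation tracks an environmental gradient (precipitation,
temperature), which track genotype (methQTL), and which respond to their
interaction. `plantewas` answers this with mass-univariate linear models
over a methylation matrix **M** (positions × samples):

- **Emodel** — `lm(M_i ~ E + cvrt)`: methylation at position *i* on the
  environment value *E*, adjusting for covariates (e.g. planting site).
- **Gmodel** — `lm(M_i ~ G_j + cvrt)`: methylation on the genotype code
  of a cis SNP *j* (within a configurable window, default 2000 bp),
  treated as an additive dosage. Genotypes are encoded 1/2/3 for major
  homozygote (AA), heterozygote (AB) and minor homozygote (BB).
- **GxE** — `lm(M_i ~ G_j + E + G_j·E + cvrt)`: the reported effect is
  the interaction coefficient.

Each scan reports, per position (or per position–SNP pair), the tested
coefficient `beta`, its *t* statistic with the residual degrees of
freedom of the full model, the two-sided p-value, and a global
Benjamini–Hochberg q-value (`FDR`). Rows with non-finite statistics are
dropped before the correction. Scans may be run in chunks and merged:
the merged q-values are bitwise identical to an unchunked run, because
computing FDR within subsets biases the q-values.

Missing cells (positions not covered in every sample) are either
filtered (`filter_missing`, threshold 0 = zero tolerance) or imputed by
drawing from a beta distribution fitted by the method of moments to the
observed values at the same position. Each draw is seeded by
(chromosome, position, sample, seed), so an imputed value never depends
on which other positions are present in the matrix.

Four input types are supported: all methylated positions (MPs), MPs
restricted to differentially methylated positions (DMPs), MPs within
DMRs, and methylation averaged over union-DMRs (uDMRs) — non-overlapping
intervals supported by at least a user-chosen fraction X of the pairwise
DMR comparisons.

## Worked example

The package ships a tiny hand-checkable study (4 samples, 10 CpG
positions, 3 SNPs, 2 DMR comparisons):

```r
library(plantewas)
bundle <- tempfile(); make_worked_example(bundle)
res <- run_ewas(samples  = file.path(bundle, "samples.tsv"),
                methylation_dir = file.path(bundle, "methylation"),
                outdir   = file.path(bundle, "out"),
                snps     = file.path(bundle, "snps.vcf"),
                plots    = FALSE)
head(res$CpG$Emodel, 3)
```

```
                id beta stats     pvalue       fdr
1 contig01:100-101 0.11    11 0.05771588 0.3011149
2 contig01:150-151 0.03     3 0.20483276 0.3413879
3 contig01:200-201 -0.05   -5 0.12566592 0.3141648
```

The first position was constructed to track the environment: its
methylation rises by 0.11 per environment unit after adjusting for the
site covariate — the same slope you get by centering within sites by
hand ((0.025 + 0.025 + 0.03 + 0.03)/1 = 0.11). With only one residual
degree of freedom nothing survives the BH correction at q < 0.1, which
is the honest answer at n = 4.

The output directory follows the standard layout:
`input/` (env.txt, cov.txt, snps.txt, gxe.txt,
`bed/{unfiltered,filtered,imputed}`) and `positions/` or `regions/`
(averaged uDMR input) with one directory per model containing
`<context>_<model>.txt`, its `filtered_<fdr>` companion and diagnostic
plots (p-value Q–Q plots and histograms, Manhattan plots for the Emodel,
significance dot matrices for the Gmodel, genotype interaction plots for
GxE).

A command-line wrapper is included:

```sh
Rscript inst/scripts/ewas.R simulate --out data --n-samples 28 --seed 1
Rscript inst/scripts/ewas.R run --samples data/samples.tsv \
    --methylation-dir data/methylation --snps data/snps.vcf \
    --out results --coverage 5 --distance 2000 --filter-NA 0 --fdr 0.1
```

## Simulating studies

`sim_config()` / `simulate_dataset()` generate complete input bundles
(per-sample 6-column bedGraphs, a biallelic VCF in Hardy–Weinberg
proportions, a sample sheet, and a truth table) with E, G and GxE
effects planted on the logit-methylation scale and beta-binomial count
noise. The defaults emulate a 28-sample clonal common-garden design;
every module of the package is tested against such simulations.

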