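Package: plantewas
Title: Epigenome-Wide Association Scans for Plant Bisulfite Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds methylation matrices from per-sample bisulfite
    methylation calls (bedGraph, CpG/CHG/CHH contexts), imputes missing
    values from per-position beta distributions, encodes genotypes from
    VCF as major/heterozygote/minor codes, and runs mass-univariate
    linear-model scans of methylation on environment (Emodel), genotype
    (Gmodel, cis-window methQTL) and their interaction (GxE) with
    covariates and global Benjamini-Hochberg FDR. Supports methylated
    positions, differentially methylated positions and regions, and
    averaged union-DMR input types, with post-hoc separation of
    environmental from genetic associations, diagnostic plots, a
    synthetic-data generator with planted effects, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
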