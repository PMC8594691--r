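#' @importFrom stats pt sd var rbeta rnorm rbinom rnbinom runif plogis qlogis p.adjust
#' @importFrom utils write.table read.table head modifyList
NULL

# Methylation contexts recognised throughout the package (H = A/T/C).
METH_CONTEXTS <- c("CpG", "CHG", "CHH")

#' Construct a sample frame
#'
#' A sample frame holds the ordered samples of a study: one unique id per
#' sample, one numeric environment/phenotype value, and zero or more named
#' covariates (numeric or categorical). Every matrix in the package keeps its
#' sample columns in sample-frame order.
#'
#' @param sample_id character vector of unique, non-empty sample ids.
#' @param env numeric vector of environment values, one per sample.
#' @param covariates optional data.frame of covariates (columns numeric or
#'   character/factor), one row per sample.
#' @return A `SampleFrame`: a data.frame with columns `sample_id`, `env`, and
#'   the covariate columns.
#' @export
sample_frame <- function(sample_id, env, covariates = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (any(!nzchar(sample_id)) || anyNA(sample_id)) {
    stop("sample ids must be non-empty")
  }
  env <- as.numeric(env)
  if (length(env) != length(sample_id) || anyNA(env)) {
    stop("every sample needs a numeric environment value")
  }
  out <- data.frame(sample_id = sample_id, env = env,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != length(sample_id)) {
      stop("covariates must have one row per sample")
    }
    out <- cbind(out, covariates)
  }
  class(out) <- c("SampleFrame", "data.frame")
  out
}

#' @export
print.SampleFrame <- function(x, ...) {
  cat(sprintf("SampleFrame: %d samples, %d covariate(s)\n",
              nrow(x), ncol(x) - 2L))
  print.data.frame(head(x, 6L))
  invisible(x)
}

covariate_names <- function(samples) {
  setdiff(colnames(samples), c("sample_id", "env"))
}

#' Construct a methylation matrix
#'
#' Positions x samples grid of methylation fractions in \[0, 1\], with `NA`
#' marking missing cells. Positions are 0-based half-open single-context
#' intervals, kept unique and sorted by (chrom, start); columns follow the
#' sample-frame order.
#'
#' @param positions data.frame with columns `chrom`, `start`, `end`,
#'   `context`.
#' @param samples character vector of sample ids (column order).
#' @param values numeric matrix, `nrow(positions)` x `length(samples)`.
#' @return A `MethylationMatrix` (list with `positions`, `samples`, `values`).
#' @export
methylation_matrix <- function(positions, samples, values) {
  positions <- as.data.frame(positions, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "context") %in% colnames(positions)))
  values <- as.matrix(values)
  if (nrow(values) != nrow(positions) || ncol(values) != length(samples)) {
    stop("values must be positions x samples")
  }
  bad <- !is.na(values) & (values < 0 | values > 1)
  if (any(bad)) stop("methylation values must lie in [0, 1]")
  ids <- position_id(positions)
  if (anyDuplicated(ids)) stop("duplicate positions")
  ord <- order(positions$chrom, positions$start, method = "radix")
  positions <- positions[ord, , drop = FALSE]
  values <- values[ord, , drop = FALSE]
  rownames(positions) <- NULL
  dimnames(values) <- list(position_id(positions), samples)
  structure(list(positions = positions, samples = as.character(samples),
                 values = values),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d positions x %d samples (%s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$positions$context), collapse = ","),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$values)

# "chrom:start-end" ids, matching the MA_160146:1616-1617 style of output
# tables; start/end are the 0-based half-open interval bounds.
position_id <- function(positions) {
  sprintf("%s:%d-%d", positions$chrom, as.integer(positions$start),
          as.integer(positions$end))
}

parse_position_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("unparseable position id(s): ",
                     paste(head(id[bad]), collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' Variants x samples grid of genotype codes: 1 = major homozygote (AA),
#' 2 = heterozygote (AB), 3 = minor homozygote (BB), `NA` = missing. Only
#' biallelic SNPs are represented; columns follow the sample-frame order.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `ref`, `alt`, `qual`.
#' @param samples character vector of sample ids.
#' @param codes integer matrix over \{1, 2, 3, NA\}.
#' @return A `GenotypeMatrix` (list with `variants`, `samples`, `codes`).
#' @export
genotype_matrix <- function(variants, samples, codes) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% colnames(variants)))
  if (!"qual" %in% colnames(variants)) variants$qual <- NA_real_
  if (any(variants$pos < 1L)) stop("VCF positions are 1-based (pos >= 1)")
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != nrow(variants) || ncol(codes) != length(samples)) {
    stop("codes must be variants x samples")
  }
  if (!all(codes %in% c(1L, 2L, 3L, NA))) {
    stop("genotype codes must be 1, 2, 3 or NA")
  }
  dimnames(codes) <- list(variant_id(variants), samples)
  structure(list(variants = variants, samples = as.character(samples),
                 codes = codes),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d variants x %d samples, %.1f%% missing\n",
              nrow(x$codes), ncol(x$codes), 100 * mean(is.na(x$codes))))
  invisible(x)
}

variant_id <- function(variants) {
  sprintf("%s:%d", variants$chrom, as.integer(variants$pos))
}

parse_variant_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)$", id))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             pos = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Construct a region set
#'
#' Genomic intervals (DMPs, DMRs or union-DMRs), 0-based half-open, each
#' tagged with the pairwise-comparison label it came from.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param label comparison label per interval.
#' @param merged_flag whether overlapping intervals within a comparison have
#'   been merged.
#' @return A `RegionSet`: data.frame with columns `chrom`, `start`, `end`,
#'   `label` and attribute `merged_flag`.
#' @export
region_set <- function(chrom, start, end, label, merged_flag = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("regions must satisfy start < end")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = as.character(label), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "merged_flag") <- merged_flag
  class(out) <- c("RegionSet", "data.frame")
  out
}

# 0-based half-open -> IRanges 1-based closed
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

positions_to_granges <- function(positions) {
  GenomicRanges::GRanges(positions$chrom,
                         IRanges::IRanges(positions$start + 1L, positions$end))
}

new_association_table <- function(id, beta, stat, pvalue, fdr = NA_real_,
                                  snp = NULL) {
  out <- data.frame(id = id, stringsAsFactors = FALSE)
  if (!is.null(snp)) out$snp <- snp
  out$beta <- beta; out$stat <- stat; out$pvalue <- pvalue; out$fdr <- fdr
  class(out) <- c("AssociationTable", "data.frame")
  out
}

empty_association_table <- function(with_snp = FALSE) {
  new_association_table(id = character(0), beta = numeric(0),
                        stat = numeric(0), pvalue = numeric(0),
                        fdr = numeric(0),
                        snp = if (with_snp) character(0))
}
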