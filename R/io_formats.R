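#' Read a tab-separated sample sheet
#'
#' The sheet has no header line: sample identifiers in the first column,
#' environment values in the second, and any further columns become
#' covariates named `cov1`, `cov2`, ... A covariate column is treated as
#' numeric iff every value parses as a number; otherwise it is categorical.
#'
#' @param path path to a tab-separated file.
#' @return A [sample_frame()].
#' @export
read_sample_sheet <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty sample sheet: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L) stop("ragged rows in sample sheet: ", path)
  if (ncol < 2L) stop("sample sheet needs at least 2 columns (id, env)")
  mat <- do.call(rbind, fields)
  env <- suppressWarnings(as.numeric(mat[, 2L]))
  if (anyNA(env)) {
    stop("non-numeric environment value(s) in column 2: ",
         paste(head(mat[is.na(env), 2L]), collapse = ", "))
  }
  covs <- NULL
  if (ncol > 2L) {
    covs <- as.data.frame(mat[, 3:ncol, drop = FALSE],
                          stringsAsFactors = FALSE)
    colnames(covs) <- paste0("cov", seq_len(ncol - 2L))
    for (j in seq_along(covs)) {
      num <- suppressWarnings(as.numeric(covs[[j]]))
      if (!anyNA(num)) covs[[j]] <- num
    }
  }
  sample_frame(mat[, 1L], env, covs)
}

#' Read per-sample methylation calls from bedGraph
#'
#' Expects the 6-column bisulfite-call dialect: chrom, start, end (0-based
#' half-open, single cytosines), methylation percentage in \[0, 100\], count
#' methylated, count unmethylated. A 4-column bedGraph (no counts) is also
#' accepted; its coverage is then unknown and the coverage filter does not
#' apply.
#'
#' @param path bedGraph file.
#' @param min_coverage records with total read count below this are dropped
#'   (they become missing data downstream). Ignored for 4-column input.
#' @param context methylation context of the file (CpG, CHG or CHH).
#' @return data.frame of methylation records with columns `chrom`, `start`,
#'   `end`, `context`, `value` (fraction in \[0, 1\]) and `coverage`
#'   (`NA` for 4-column input).
#' @export
read_bedgraph <- function(path, min_coverage = 5L, context = "CpG") {
  context <- match.arg(context, METH_CONTEXTS)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = TRUE, showProgress = FALSE)
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      value = numeric(0), coverage = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (!ncol(dt) %in% c(4L, 6L)) {
    stop("bedGraph must have 4 or 6 columns, got ", ncol(dt), ": ", path)
  }
  chrom <- as.character(dt[[1L]])
  start <- as.integer(dt[[2L]]); end <- as.integer(dt[[3L]])
  pct <- as.numeric(dt[[4L]])
  if (any(start >= end)) stop("malformed interval (start >= end) in ", path)
  if (any(pct < 0 | pct > 100)) {
    stop("methylation percentage outside [0, 100] in ", path)
  }
  if (ncol(dt) == 6L) {
    cm <- as.integer(dt[[5L]]); cu <- as.integer(dt[[6L]])
    if (any(cm < 0) || any(cu < 0)) stop("negative counts in ", path)
    coverage <- cm + cu
    keep <- coverage >= min_coverage
  } else {
    coverage <- rep(NA_integer_, nrow(dt))
    keep <- rep(TRUE, nrow(dt))
  }
  data.frame(chrom = chrom[keep], start = start[keep], end = end[keep],
             context = context, value = pct[keep] / 100,
             coverage = coverage[keep], stringsAsFactors = FALSE)
}

#' Read DMP/DMR interval files (BED3+)
#'
#' One file per pairwise comparison, each tagged with its comparison label.
#' Overlapping intervals within one comparison are merged with a warning.
#'
#' @param paths character vector of BED files.
#' @param labels comparison labels, same length as `paths`.
#' @return A [region_set()].
#' @export
read_regions <- function(paths, labels = NULL) {
  if (is.null(labels)) {
    labels <- tools::file_path_sans_ext(basename(paths))
  }
  stopifnot(length(paths) == length(labels))
  parts <- lapply(seq_along(paths), function(i) {
    dt <- tryCatch(
      suppressWarnings(data.table::fread(paths[i], header = FALSE,
                                         sep = "\t",
                                         showProgress = FALSE)),
      error = function(e) NULL)
    if (is.null(dt) || nrow(dt) == 0L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), label = character(0)))
    }
    if (ncol(dt) < 3L) stop("BED file needs >= 3 columns: ", paths[i])
    df <- data.frame(chrom = as.character(dt[[1L]]),
                     start = as.integer(dt[[2L]]),
                     end = as.integer(dt[[3L]]),
                     label = labels[i], stringsAsFactors = FALSE)
    gr <- regions_to_granges(df)
    red <- GenomicRanges::reduce(gr)
    if (length(red) < length(gr)) {
      warning("merged overlapping intervals within comparison '",
              labels[i], "'", call. = FALSE)
    }
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red) - 1L,
               end = GenomicRanges::end(red),
               label = labels[i], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  if (nrow(df) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "merged_flag") <- TRUE
    attr(out, "comparisons") <- labels
    class(out) <- c("RegionSet", "data.frame")
    return(out)
  }
  out <- region_set(df$chrom, df$start, df$end, df$label, merged_flag = TRUE)
  attr(out, "comparisons") <- labels
  out
}

#' Encode biallelic genotype calls as 1/2/3 codes
#'
#' 1 = major homozygote (AA), 2 = heterozygote (AB), 3 = minor homozygote
#' (BB). The major allele is the more frequent allele among the non-missing
#' calls at the site; ties resolve to REF. Missing calls pass through as
#' `NA`.
#'
#' @param gt_calls character vector of VCF GT strings ("0/0", "0/1", "1/1",
#'   "./."; "|" separators accepted).
#' @return integer vector over \{1, 2, 3, NA\}.
#' @export
encode_genotype <- function(gt_calls) {
  gt <- gsub("|", "/", as.character(gt_calls), fixed = TRUE)
  alt_n <- ifelse(gt %in% c("0/0"), 0L,
           ifelse(gt %in% c("0/1", "1/0"), 1L,
           ifelse(gt %in% c("1/1"), 2L, NA_integer_)))
  obs <- !is.na(alt_n)
  if (!any(obs)) return(rep(NA_integer_, length(gt)))
  alt_count <- sum(alt_n[obs])
  total <- 2L * sum(obs)
  # ties -> REF stays major
  alt_major <- alt_count > total - alt_count
  code <- alt_n + 1L                 # REF major: 0/1/2 alt -> 1/2/3
  if (alt_major) code <- 3L - alt_n  # ALT major: reverse homozygotes
  as.integer(code)
}

#' Read and filter genotypes from a VCF
#'
#' Keeps biallelic SNPs passing a site quality threshold, a per-site
#' missingness threshold and a minor-allele-count threshold, then encodes
#' genotypes with [encode_genotype()]. Samples are restricted and reordered
#' to the sample-frame order. The defaults mirror a conservative population
#' filter: QUAL >= 30, complete genotyping, minor allele count >= 3.
#'
#' @param path VCF or vcf.gz file with a GT field.
#' @param samples a [sample_frame()]; every sample must be present in the
#'   VCF.
#' @param min_qual minimum site QUAL (sites with missing QUAL pass).
#' @param max_missing_fraction maximum fraction of samples with a missing
#'   call at a site (0 = genotyped in 100% of individuals).
#' @param min_minor_allele_count minimum count of the minor allele among
#'   non-missing calls.
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path, samples, min_qual = 30,
                               max_missing_fraction = 0,
                               min_minor_allele_count = 3L) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_all <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_all))) {
    gt_all <- matrix(gt_all, nrow = 1, dimnames = list(NULL, names(gt_all)))
  }
  missing_samples <- setdiff(samples$sample_id, colnames(gt_all))
  if (length(missing_samples) > 0L) {
    stop("sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  }
  gt_all <- gt_all[, samples$sample_id, drop = FALSE]

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  qual_ok <- is.na(qual) | qual >= min_qual

  n <- nrow(samples)
  keep <- logical(nrow(fix))
  codes_list <- vector("list", nrow(fix))
  for (i in which(snp & qual_ok)) {
    gt <- gsub("|", "/", gt_all[i, ], fixed = TRUE)
    alt_n <- ifelse(gt %in% "0/0", 0L,
             ifelse(gt %in% c("0/1", "1/0"), 1L,
             ifelse(gt %in% "1/1", 2L, NA_integer_)))
    n_miss <- sum(is.na(alt_n))
    if (n_miss / n > max_missing_fraction) next
    obs <- !is.na(alt_n)
    if (!any(obs)) next
    ac <- sum(alt_n[obs]); total <- 2L * sum(obs)
    mac <- min(ac, total - ac)
    if (mac < min_minor_allele_count) next
    keep[i] <- TRUE
    codes_list[[i]] <- encode_genotype(gt)
  }
  if (!any(keep)) {
    warning("no variant survives the VCF filters", call. = FALSE)
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           qual = numeric(0), stringsAsFactors = FALSE)
    return(genotype_matrix(variants, samples$sample_id,
                           matrix(integer(0), 0, n)))
  }
  variants <- data.frame(chrom = fix[keep, "CHROM"],
                         pos = as.integer(fix[keep, "POS"]),
                         ref = ref[keep], alt = alt[keep],
                         qual = qual[keep], stringsAsFactors = FALSE)
  codes <- do.call(rbind, codes_list[keep])
  ord <- order(variants$chrom, variants$pos, method = "radix")
  genotype_matrix(variants[ord, , drop = FALSE], samples$sample_id,
                  codes[ord, , drop = FALSE])
}

# fixed significant-digit formatting so that written tables are byte-stable
format_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write an association table
#'
#' Tab-separated with header `ID[<TAB>snp]<TAB>beta<TAB>stats<TAB>pvalue<TAB>FDR`;
#' ids are `chrom:start-end` (and `chrom:pos` for the snp column). Numbers
#' are written at 9 significant digits, so a write/read cycle round-trips
#' well within 1e-6 relative.
#'
#' @param table an association table (from one of the scans).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  has_snp <- "snp" %in% colnames(table)
  header <- c("ID", if (has_snp) "snp", "beta", "stats", "pvalue", "FDR")
  lines <- paste(header, collapse = "\t")
  if (nrow(table) > 0L) {
    cols <- cbind(table$id, if (has_snp) table$snp,
                  format_num(table$beta), format_num(table$stat),
                  format_num(table$pvalue), format_num(table$fdr))
    lines <- c(lines, apply(cols, 1L, paste, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an association table written by [write_association_table()]
#'
#' @param path tab-separated association file.
#' @return An association table data.frame.
#' @export
read_association_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          showProgress = FALSE)
  has_snp <- "snp" %in% colnames(dt)
  new_association_table(id = as.character(dt[["ID"]]),
                        beta = as.numeric(dt[["beta"]]),
                        stat = as.numeric(dt[["stats"]]),
                        pvalue = as.numeric(dt[["pvalue"]]),
                        fdr = as.numeric(dt[["FDR"]]),
                        snp = if (has_snp) as.character(dt[["snp"]]))
}

#' Write a methylation matrix as a multi-sample union bedGraph
#'
#' Tab-separated: chrom, start, end followed by one value column per sample
#' (fractions; `NA` for missing), with a `track`-less header line naming the
#' samples, matching `bedtools unionbedg -header` output shape.
#'
#' @param matrix a [methylation_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_union_bedgraph <- function(matrix, path) {
  header <- paste(c("chrom", "start", "end", matrix$samples),
                  collapse = "\t")
  if (nrow(matrix$values) > 0L) {
    vals <- apply(matrix$values, 2L, format_num)
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    body <- cbind(matrix$positions$chrom,
                  as.character(matrix$positions$start),
                  as.character(matrix$positions$end), vals)
    lines <- c(header, apply(body, 1L, paste, collapse = "\t"))
  } else lines <- header
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-sample union bedGraph written by [write_union_bedgraph()]
#'
#' @param path union bedGraph file with a header line.
#' @param context methylation context to tag positions with.
#' @return A [methylation_matrix()].
#' @export
read_union_bedgraph <- function(path, context = "CpG") {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", na.strings = "NA",
                          showProgress = FALSE)
  samples <- colnames(dt)[-(1:3)]
  positions <- data.frame(chrom = as.character(dt[[1L]]),
                          start = as.integer(dt[[2L]]),
                          end = as.integer(dt[[3L]]),
                          context = context, stringsAsFactors = FALSE)
  values <- as.matrix(dt[, -(1:3), with = FALSE])
  methylation_matrix(positions, samples, values)
}
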