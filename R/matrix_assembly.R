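#' Unite per-sample methylation calls into one matrix
#'
#' Implements union-bedGraph semantics: the row set is the union of all
#' positions seen in any sample; a cell holds the sample's methylation
#' fraction, or `NA` where that sample has no (retained) call — positions
#' not covered by all sample methylomes generate missing data.
#'
#' @param per_sample named list of record data.frames (from
#'   [read_bedgraph()]), names matching sample ids; all records must share
#'   one context.
#' @param samples a [sample_frame()] fixing the column order.
#' @return A [methylation_matrix()].
#' @export
union_positions <- function(per_sample, samples) {
  if (nrow(samples) == 0L) stop("no samples")
  missing <- setdiff(samples$sample_id, names(per_sample))
  if (length(missing) > 0L) {
    stop("no methylation records for sample(s): ",
         paste(missing, collapse = ", "))
  }
  per_sample <- per_sample[samples$sample_id]
  ctx <- unique(unlist(lapply(per_sample, function(d) unique(d$context))))
  if (length(ctx) > 1L) stop("records mix methylation contexts: ",
                             paste(ctx, collapse = ", "))
  if (length(ctx) == 0L) ctx <- "CpG"
  long <- data.table::rbindlist(lapply(samples$sample_id, function(s) {
    d <- per_sample[[s]]
    data.table::data.table(chrom = d$chrom, start = d$start, end = d$end,
                           sample = s, value = d$value)
  }))
  if (nrow(long) == 0L) {
    positions <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), context = character(0),
                            stringsAsFactors = FALSE)
    return(methylation_matrix(positions, samples$sample_id,
                              matrix(numeric(0), 0, nrow(samples))))
  }
  wide <- data.table::dcast(long, chrom + start + end ~ sample,
                            value.var = "value")
  data.table::setorder(wide, chrom, start)
  positions <- data.frame(chrom = wide$chrom, start = wide$start,
                          end = wide$end, context = ctx,
                          stringsAsFactors = FALSE)
  values <- as.matrix(wide[, samples$sample_id, with = FALSE])
  methylation_matrix(positions, samples$sample_id, values)
}

subset_matrix_rows <- function(matrix, idx) {
  methylation_matrix(matrix$positions[idx, , drop = FALSE], matrix$samples,
                     matrix$values[idx, , drop = FALSE])
}

#' Restrict a methylation matrix to differentially methylated positions
#'
#' Keeps the matrix rows contained in the union (across pairwise
#' comparisons) of the 1-bp DMP intervals; values are unchanged.
#'
#' @param matrix a [methylation_matrix()].
#' @param dmps a [region_set()] of 1-bp intervals.
#' @return The row-restricted matrix.
#' @export
restrict_to_dmps <- function(matrix, dmps) {
  restrict_to_regions(matrix, dmps)
}

#' Restrict a methylation matrix to positions inside regions
#'
#' Keeps rows overlapping any interval of the region set (union across
#' comparisons; a position inside several regions is kept once). Rows keep
#' their per-position identity.
#'
#' @param matrix a [methylation_matrix()].
#' @param regions a [region_set()].
#' @return The row-restricted matrix.
#' @export
restrict_to_regions <- function(matrix, regions) {
  if (nrow(regions) == 0L || nrow(matrix$values) == 0L) {
    if (nrow(matrix$values) > 0L) {
      warning("no matrix position falls inside the region set",
              call. = FALSE)
    }
    return(subset_matrix_rows(matrix, integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(positions_to_granges(matrix$positions),
                                      regions_to_granges(regions))
  idx <- sort(unique(S4Vectors::queryHits(hits)))
  if (length(idx) == 0L) {
    warning("no matrix position falls inside the region set", call. = FALSE)
  }
  subset_matrix_rows(matrix, idx)
}

#' Build union-DMRs from pairwise DMR comparisons
#'
#' Splits the genome at every region boundary into elementary intervals and
#' keeps those supported by at least `min_fraction` of the pairwise
#' comparisons (a comparison counts once per elementary interval, however
#' many of its regions cover it). With a single comparison the regions are
#' returned as is. Kept adjacent intervals are coalesced when `merge` is
#' set.
#'
#' @param dmrs a [region_set()] with comparison labels.
#' @param min_fraction minimum supporting fraction X in (0, 1\]; e.g. 0.5
#'   keeps intervals supported by at least half the comparisons.
#' @param merge coalesce adjacent kept intervals (default `TRUE`).
#' @return A [region_set()] of distinct, non-overlapping intervals labelled
#'   `"uDMR"`.
#' @export
build_union_dmrs <- function(dmrs, min_fraction = 0.5, merge = TRUE) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must lie in (0, 1]")
  }
  comparisons <- attr(dmrs, "comparisons")
  if (is.null(comparisons)) comparisons <- unique(dmrs$label)
  n_comp <- length(comparisons)
  if (nrow(dmrs) == 0L) return(dmrs)
  if (n_comp == 1L) return(dmrs)  # single comparison: taken as is
  gr <- regions_to_granges(dmrs)
  elem <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(elem, gr)
  support <- integer(length(elem))
  if (length(hits) > 0L) {
    lab <- dmrs$label[S4Vectors::subjectHits(hits)]
    key <- paste(S4Vectors::queryHits(hits), lab)
    first <- !duplicated(key)  # distinct comparisons only
    support <- tabulate(S4Vectors::queryHits(hits)[first], length(elem))
  }
  kept <- elem[support / n_comp >= min_fraction]
  if (length(kept) == 0L) {
    out <- dmrs[integer(0), , drop = FALSE]
    attr(out, "merged_flag") <- merge
    attr(out, "comparisons") <- comparisons
    return(out)
  }
  if (merge) kept <- GenomicRanges::reduce(kept)
  out <- region_set(as.character(GenomicRanges::seqnames(kept)),
                    GenomicRanges::start(kept) - 1L,
                    GenomicRanges::end(kept),
                    "uDMR", merged_flag = merge)
  attr(out, "comparisons") <- comparisons
  out
}

#' Average methylation over regions
#'
#' Collapses a position-level matrix to one row per region: each cell is the
#' arithmetic mean of the sample's non-missing values over the positions the
#' region covers, and missing only if the sample is missing at all of them.
#' Regions covering no matrix position are dropped (with a message). Row
#' ids become `chrom:start-end` of the region.
#'
#' @param matrix a position-level [methylation_matrix()].
#' @param regions a non-overlapping [region_set()] (e.g. union-DMRs).
#' @return A region-level [methylation_matrix()].
#' @export
average_over_regions <- function(matrix, regions) {
  if (nrow(regions) == 0L) {
    return(subset_matrix_rows(matrix, integer(0)))
  }
  gr_reg <- regions_to_granges(regions)
  ov <- GenomicRanges::findOverlaps(gr_reg, gr_reg)
  if (length(ov) > length(gr_reg)) stop("regions must be non-overlapping")
  hits <- GenomicRanges::findOverlaps(positions_to_granges(matrix$positions),
                                      gr_reg)
  pos_i <- S4Vectors::queryHits(hits)
  reg_i <- S4Vectors::subjectHits(hits)
  covered <- sort(unique(reg_i))
  n_drop <- nrow(regions) - length(covered)
  if (n_drop > 0L) {
    message(n_drop, " region(s) cover no methylated position and were dropped")
  }
  vals <- matrix$values[pos_i, , drop = FALSE]
  grp <- match(reg_i, covered)
  obs <- !is.na(vals)
  v0 <- vals; v0[!obs] <- 0
  sums <- rowsum(v0, grp)
  cnts <- rowsum(obs + 0, grp)
  means <- sums / cnts
  means[cnts == 0] <- NA_real_
  ctx <- unique(matrix$positions$context)
  if (length(ctx) == 0L) ctx <- "CpG"
  positions <- data.frame(chrom = regions$chrom[covered],
                          start = regions$start[covered],
                          end = regions$end[covered],
                          context = ctx[1L], stringsAsFactors = FALSE)
  methylation_matrix(positions, matrix$samples, means)
}

#' Filter positions by methylation variation across samples
#'
#' Keeps rows whose non-missing values have at least the given sample
#' standard deviation (n-1 denominator) and/or at least the given range
#' (max - min). Thresholds are on the fraction scale: 0.10 corresponds to a
#' 10% range of variation. Rows with fewer than two non-missing values are
#' dropped whenever a threshold is set.
#'
#' @param matrix a [methylation_matrix()].
#' @param min_sd minimum per-position SD, or `NULL` to skip.
#' @param min_range minimum per-position range, or `NULL` to skip.
#' @return The row-filtered matrix.
#' @export
filter_by_variation <- function(matrix, min_sd = NULL, min_range = NULL) {
  if (is.null(min_sd) && is.null(min_range)) return(matrix)
  n_obs <- rowSums(!is.na(matrix$values))
  keep <- n_obs >= 2L
  if (!is.null(min_sd)) {
    sds <- apply(matrix$values, 1L, sd, na.rm = TRUE)
    keep <- keep & !is.na(sds) & sds >= min_sd
  }
  if (!is.null(min_range)) {
    rng <- apply(matrix$values, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NA_real_)
      max(v) - min(v)
    })
    keep <- keep & !is.na(rng) & rng >= min_range
  }
  subset_matrix_rows(matrix, which(keep))
}
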