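#' Ids significant at an FDR cutoff
#'
#' @param table an association table with an `fdr` column.
#' @param fdr_cutoff q-value threshold; rows with `fdr < fdr_cutoff` count.
#' @return character set (unique, sorted) of significant position ids.
#' @export
significant_ids <- function(table, fdr_cutoff = 0.1) {
  if (nrow(table) == 0L) return(character(0))
  sort(unique(table$id[!is.na(table$fdr) & table$fdr < fdr_cutoff]))
}

#' Exact membership counts over a family of id sets (upset semantics)
#'
#' For every non-empty combination of set labels, counts the ids belonging
#' to exactly that combination (members of every listed set and of no
#' other). Counts over all combinations sum to the size of the union.
#'
#' @param sets named list (>= 2 entries) of character id vectors.
#' @return data.frame with columns `combination` (labels joined by `&`),
#'   `degree` (number of sets in the combination) and `count`.
#' @export
membership_counts <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  labels <- names(sets)
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, labels))
  sig <- apply(member, 1L, function(r) paste(labels[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(labels), function(k) {
    apply(utils::combn(labels, k), 2L, paste, collapse = "&")
  }))
  counts <- vapply(combos, function(cmb) sum(sig == cmb), 0L)
  data.frame(combination = combos,
             degree = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove genetically driven positions from an Emodel table
#'
#' An Emodel hit that is also significant in the Gmodel or GxE scan, or
#' that sits exactly on a SNP coordinate (a C/T-type genetic confound), is
#' more plausibly genetic than environmental; such rows are dropped so the
#' remaining associations reflect environmental factors. Counts removed by
#' each rule are attached as attribute `removed` and reported via message.
#'
#' @param emodel Emodel association table.
#' @param gmodel,gxe Gmodel/GxE association tables (pair-level); may be
#'   empty.
#' @param snp_positions data.frame with columns `chrom`, `start` (0-based
#'   cytosine-style starts, i.e. VCF pos - 1), or `NULL`.
#' @param fdr_cutoff q-value threshold defining "significant".
#' @param drop_snp_overlap also apply the positional SNP-coordinate rule
#'   (default `TRUE`).
#' @return The filtered Emodel table with attribute `removed`
#'   (named counts: `genetic_model`, `snp_position`).
#' @export
exclude_genetic <- function(emodel, gmodel, gxe, snp_positions = NULL,
                            fdr_cutoff = 0.1, drop_snp_overlap = TRUE) {
  genetic_ids <- union(significant_ids(gmodel, fdr_cutoff),
                       significant_ids(gxe, fdr_cutoff))
  drop_model <- emodel$id %in% genetic_ids
  drop_pos <- rep(FALSE, nrow(emodel))
  if (drop_snp_overlap && !is.null(snp_positions) &&
      nrow(snp_positions) > 0L && nrow(emodel) > 0L) {
    pos <- parse_position_id(emodel$id)
    key <- paste(pos$chrom, pos$start)
    snp_key <- paste(snp_positions$chrom, snp_positions$start)
    drop_pos <- key %in% snp_key
  }
  removed <- c(genetic_model = sum(drop_model),
               snp_position = sum(drop_pos & !drop_model))
  out <- emodel[!(drop_model | drop_pos), , drop = FALSE]
  rownames(out) <- NULL
  message("exclude_genetic: removed ", removed[["genetic_model"]],
          " shared with G/GxE, ", removed[["snp_position"]],
          " at SNP coordinates")
  attr(out, "removed") <- removed
  out
}
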