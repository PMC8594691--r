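#' Build a design matrix of intercept plus covariates
#'
#' Categorical covariates are one-hot encoded with the first level dropped
#' (the `lm()` factor convention); numeric covariates enter as-is. The
#' result must be full column rank and leave at least one residual degree
#' of freedom for the tested term.
#'
#' @param samples a [sample_frame()].
#' @param covariates character vector of covariate column names to use
#'   (default: all).
#' @return list with `X` (n x k numeric matrix, first column the
#'   intercept), `rank` and `n`.
#' @export
design_matrix <- function(samples, covariates = covariate_names(samples)) {
  n <- nrow(samples)
  if (length(covariates) == 0L) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    cov_df <- as.data.frame(samples)[, covariates, drop = FALSE]
    for (j in seq_along(cov_df)) {
      if (!is.numeric(cov_df[[j]])) cov_df[[j]] <- factor(cov_df[[j]])
    }
    X <- stats::model.matrix(~ ., data = cov_df)
    attr(X, "assign") <- NULL
    attr(X, "contrasts") <- NULL
  }
  r <- qr(X)$rank
  if (r < ncol(X)) stop("design matrix is rank deficient after encoding")
  if (n <= r + 1L) {
    stop("too few samples: need n > rank + 1 for at least one residual ",
         "degree of freedom")
  }
  list(X = X, rank = r, n = n)
}

#' Residualize a vector against a design matrix
#'
#' Returns `y` minus its least-squares projection onto the design columns;
#' the result is orthogonal to every design column.
#'
#' @param y numeric vector (or matrix, column-wise) over samples.
#' @param design a [design_matrix()].
#' @return residual vector/matrix of the same shape.
#' @export
residualize <- function(y, design) {
  qr.resid(qr(design$X), y)
}

#' Scan configuration
#'
#' @param distance cis-window half-width in bp for Gmodel/GxE pairing
#'   (default 2000): a (position, variant) pair is tested when both lie on
#'   the same chromosome within this distance.
#' @param fdr_cutoff q-value threshold used when writing filtered outputs
#'   (default 0.1).
#' @param drop_nonfinite drop rows with non-finite t statistics before FDR
#'   (default `TRUE`).
#' @param all_pairs test every (position, variant) pair regardless of
#'   distance (for small data sets).
#' @return list of settings.
#' @export
scan_config <- function(distance = 2000L, fdr_cutoff = 0.1,
                        drop_nonfinite = TRUE, all_pairs = FALSE) {
  stopifnot(distance >= 0, fdr_cutoff > 0, fdr_cutoff <= 1)
  list(distance = as.integer(distance), fdr_cutoff = fdr_cutoff,
       drop_nonfinite = drop_nonfinite, all_pairs = all_pairs)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: sort p ascending, set
#' q_(i) = min over j >= i of p_(j) * m / j, cap at 1, map back to input
#' order.
#'
#' @param pvalues numeric vector of finite p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Column-wise residualization against a prefactored design. Done one
# column at a time so each position's numbers are bitwise independent of
# which other positions share the matrix — the property that makes
# chunked runs reproduce the unchunked run exactly.
resid_cols <- function(qrX, Y) {
  n <- nrow(Y)
  vapply(seq_len(ncol(Y)), function(j) qr.resid(qrX, Y[, j]),
         numeric(n))
}

# Shared core: given residualized predictor x_r (orthogonal to the design)
# and the residualized methylation rows R (samples x positions), compute
# the OLS slope of each M column on the predictor given the design, its t
# statistic (Frisch-Waugh: identical to the coefficient test in the full
# fit) and two-sided p-value. df = residual df of the full model.
marginal_test <- function(R, x_r, df) {
  sxx <- sum(x_r^2)
  sxy <- colSums(R * x_r)
  beta <- sxy / sxx
  rss <- pmax(colSums(R^2) - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  stat <- beta / se
  pvalue <- 2 * pt(-abs(stat), df)
  list(beta = unname(beta), stat = unname(stat), pvalue = unname(pvalue))
}

finalize_scan <- function(tab, config, add_fdr = TRUE) {
  if (config$drop_nonfinite) {
    tab <- tab[is.finite(tab$stat), , drop = FALSE]
  }
  rownames(tab) <- NULL
  if (add_fdr && nrow(tab) > 0L) tab$fdr <- bh_fdr(tab$pvalue)
  tab
}

#' Environment scan (Emodel)
#'
#' For every position fits the linear model M ~ E + covariates and reports
#' the environment coefficient, its t statistic (residual df of the full
#' model), the two-sided p-value and the global BH q-value. Implemented by
#' residualizing both M and E against the covariate design and regressing
#' residuals on residuals, which is algebraically identical to the per-row
#' full fit. Rows with non-finite statistics (e.g. zero residual variance)
#' are dropped before FDR when configured.
#'
#' @param m a complete [methylation_matrix()] (impute first).
#' @param samples a [sample_frame()]; `env` must be non-constant.
#' @param design a [design_matrix()] (covariates only; E is added by the
#'   scan).
#' @param config a [scan_config()].
#' @return An association table with columns `id`, `beta`, `stat`,
#'   `pvalue`, `fdr`.
#' @export
emodel_scan <- function(m, samples, design = design_matrix(samples),
                        config = scan_config()) {
  scan <- emodel_scan_raw(m, samples, design, config)
  finalize_scan(scan, config)
}

emodel_scan_raw <- function(m, samples, design, config) {
  E <- samples$env
  if (sd(E) == 0) stop("environment is constant across samples")
  if (anyNA(m$values)) stop("methylation matrix has missing values; impute first")
  qrX <- qr(design$X)
  e_r <- qr.resid(qrX, E)
  R <- resid_cols(qrX, t(m$values))
  df <- design$n - design$rank - 1L
  res <- marginal_test(R, e_r, df)
  new_association_table(id = rownames(m$values), beta = res$beta,
                        stat = res$stat, pvalue = res$pvalue)
}

# cis pairs: indices of (position, variant) with same chrom and
# |variant_start - position_start| <= distance (0-based starts)
cis_pairs <- function(positions, variants, config) {
  if (config$all_pairs) {
    out <- expand.grid(pos_i = seq_len(nrow(positions)),
                       var_j = seq_len(nrow(variants)))
    return(out[order(out$pos_i, out$var_j), , drop = FALSE])
  }
  pos_gr <- GenomicRanges::GRanges(
    positions$chrom, IRanges::IRanges(positions$start + 1L,
                                      positions$start + 1L))
  var_start <- variants$pos - 1L  # VCF pos p -> bed start p-1
  win <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(pmax(var_start - config$distance, 0L) + 1L,
                     var_start + config$distance + 1L))
  hits <- GenomicRanges::findOverlaps(pos_gr, win)
  out <- data.frame(pos_i = S4Vectors::queryHits(hits),
                    var_j = S4Vectors::subjectHits(hits))
  out[order(out$pos_i, out$var_j), , drop = FALSE]
}

#' Genotype scan (Gmodel, cis methQTL)
#'
#' For every cis (position, variant) pair — same chromosome, within the
#' configured distance — fits M ~ G + covariates with the genotype code
#' (1/2/3) as an additive numeric dosage, and reports the genotype
#' coefficient, t statistic, p-value and a global BH q-value over all
#' pairs. Variants that are constant across samples are skipped.
#'
#' @param m a complete [methylation_matrix()].
#' @param g a complete [genotype_matrix()] over the same samples in the
#'   same order.
#' @param design a [design_matrix()].
#' @param config a [scan_config()].
#' @return An association table with columns `id`, `snp`, `beta`, `stat`,
#'   `pvalue`, `fdr`.
#' @export
gmodel_scan <- function(m, g, design, config = scan_config()) {
  finalize_scan(gmodel_scan_raw(m, g, design, config), config)
}

gmodel_scan_raw <- function(m, g, design, config) {
  check_paired_inputs(m, g)
  pairs <- cis_pairs(m$positions, g$variants, config)
  if (nrow(pairs) == 0L) {
    warning("no (position, variant) pair within the cis window",
            call. = FALSE)
    return(empty_association_table(with_snp = TRUE))
  }
  qrX <- qr(design$X)
  R <- resid_cols(qrX, t(m$values))
  df <- design$n - design$rank - 1L
  pos_ids <- rownames(m$values)
  var_ids <- rownames(g$codes)
  parts <- list(); skipped <- 0L
  for (j in sort(unique(pairs$var_j))) {
    gv <- as.numeric(g$codes[j, ])
    if (sd(gv) == 0) { skipped <- skipped + 1L; next }
    g_r <- qr.resid(qrX, gv)
    pos_i <- pairs$pos_i[pairs$var_j == j]
    res <- marginal_test(R[, pos_i, drop = FALSE], g_r, df)
    parts[[length(parts) + 1L]] <- new_association_table(
      id = pos_ids[pos_i], snp = rep(var_ids[j], length(pos_i)),
      beta = res$beta, stat = res$stat, pvalue = res$pvalue)
  }
  if (skipped > 0L) {
    message(skipped, " constant variant(s) skipped")
  }
  if (length(parts) == 0L) return(empty_association_table(with_snp = TRUE))
  tab <- do.call(rbind, parts)
  sort_pair_table(tab)
}

#' Genotype-by-environment interaction scan (GxE)
#'
#' For every cis (position, variant) pair fits
#' M ~ G + E + G:E + covariates and reports the interaction coefficient
#' G:E, its t statistic, p-value and a global BH q-value over all pairs.
#' Pairs where only one genotype class is present (or where the extended
#' design is rank deficient) are skipped.
#'
#' @inheritParams gmodel_scan
#' @param samples a [sample_frame()]; `env` must be non-constant.
#' @return An association table with columns `id`, `snp`, `beta`, `stat`,
#'   `pvalue`, `fdr`.
#' @export
gxe_scan <- function(m, g, samples, design = design_matrix(samples),
                     config = scan_config()) {
  finalize_scan(gxe_scan_raw(m, g, samples, design, config), config)
}

gxe_scan_raw <- function(m, g, samples, design, config) {
  check_paired_inputs(m, g)
  E <- samples$env
  if (sd(E) == 0) stop("environment is constant across samples")
  pairs <- cis_pairs(m$positions, g$variants, config)
  if (nrow(pairs) == 0L) {
    warning("no (position, variant) pair within the cis window",
            call. = FALSE)
    return(empty_association_table(with_snp = TRUE))
  }
  pos_ids <- rownames(m$values)
  var_ids <- rownames(g$codes)
  M_t <- t(m$values)
  parts <- list(); skipped <- 0L
  for (j in sort(unique(pairs$var_j))) {
    gv <- as.numeric(g$codes[j, ])
    if (sd(gv) == 0) { skipped <- skipped + 1L; next }
    X2 <- cbind(design$X, G = gv, E = E)
    qrX2 <- qr(X2)
    if (qrX2$rank < ncol(X2)) { skipped <- skipped + 1L; next }
    w_r <- qr.resid(qrX2, gv * E)
    if (sum(w_r^2) < 1e-12 * sum((gv * E)^2)) {
      skipped <- skipped + 1L; next  # interaction collinear with main terms
    }
    df <- design$n - qrX2$rank - 1L
    if (df < 1L) { skipped <- skipped + 1L; next }
    pos_i <- pairs$pos_i[pairs$var_j == j]
    R2 <- resid_cols(qrX2, M_t[, pos_i, drop = FALSE])
    res <- marginal_test(R2, w_r, df)
    parts[[length(parts) + 1L]] <- new_association_table(
      id = pos_ids[pos_i], snp = rep(var_ids[j], length(pos_i)),
      beta = res$beta, stat = res$stat, pvalue = res$pvalue)
  }
  if (skipped > 0L) {
    message(skipped, " variant(s) skipped (constant or collinear)")
  }
  if (length(parts) == 0L) return(empty_association_table(with_snp = TRUE))
  sort_pair_table(do.call(rbind, parts))
}

check_paired_inputs <- function(m, g) {
  if (!identical(m$samples, g$samples)) {
    stop("methylation and genotype matrices must share the same samples ",
         "in the same order")
  }
  if (anyNA(m$values)) stop("methylation matrix has missing values; impute first")
  if (anyNA(g$codes)) stop("genotype matrix has missing codes; impute first")
}

# canonical (chrom, start, snp chrom, snp pos) row order so that chunked
# and unchunked runs produce bitwise-identical tables
sort_pair_table <- function(tab) {
  pos <- parse_position_id(tab$id)
  if ("snp" %in% colnames(tab)) {
    snp <- parse_variant_id(tab$snp)
    ord <- order(pos$chrom, pos$start, snp$chrom, snp$pos, method = "radix")
  } else {
    ord <- order(pos$chrom, pos$start, method = "radix")
  }
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Merge chunked scan outputs and apply a global FDR
#'
#' Scans run on disjoint subsets of positions (e.g. per chromosome, or 10
#' separate runs) are concatenated, rows with non-finite statistics are
#' dropped, and the BH correction is recomputed over the merged table. The
#' result is identical to running the scan unchunked: computing FDR within
#' subsets would bias the q-values.
#'
#' @param chunks list of association tables without (or with stale) `fdr`,
#'   disjoint in their (id, snp) keys.
#' @param config a [scan_config()].
#' @return A single association table with a global `fdr`.
#' @export
merge_chunked <- function(chunks, config = scan_config()) {
  chunks <- chunks[vapply(chunks, nrow, 0L) > 0L]
  if (length(chunks) == 0L) return(empty_association_table())
  tab <- do.call(rbind, chunks)
  keys <- if ("snp" %in% colnames(tab)) paste(tab$id, tab$snp) else tab$id
  if (anyDuplicated(keys)) stop("duplicate (id, snp) keys across chunks")
  tab <- tab[is.finite(tab$stat), , drop = FALSE]
  tab <- sort_pair_table(tab)
  tab$fdr <- if (nrow(tab) > 0L) bh_fdr(tab$pvalue) else numeric(0)
  tab
}

#' Run a scan in row chunks and merge (chunk-safe)
#'
#' Splits the methylation matrix into `n_chunks` contiguous row blocks,
#' runs the requested scan on each without FDR, then merges with a single
#' global BH correction. Output is identical to a 1-chunk run.
#'
#' @param model one of "emodel", "gmodel", "gxe".
#' @param m,g,samples,design,config as for the individual scans (`g` is
#'   ignored by the Emodel).
#' @param n_chunks number of row blocks.
#' @return An association table with a global `fdr`.
#' @export
chunked_scan <- function(model = c("emodel", "gmodel", "gxe"), m,
                         g = NULL, samples, design = design_matrix(samples),
                         config = scan_config(), n_chunks = 1L) {
  model <- match.arg(model)
  n <- nrow(m$values)
  n_chunks <- max(1L, min(n_chunks, n))
  blocks <- split(seq_len(n), ceiling(seq_len(n) / ceiling(n / n_chunks)))
  raw_cfg <- config; raw_cfg$drop_nonfinite <- FALSE
  chunks <- lapply(blocks, function(idx) {
    mi <- subset_matrix_rows(m, idx)
    switch(model,
           emodel = emodel_scan_raw(mi, samples, design, raw_cfg),
           gmodel = gmodel_scan_raw(mi, g, design, raw_cfg),
           gxe = gxe_scan_raw(mi, g, samples, design, raw_cfg))
  })
  merge_chunked(chunks, config)
}
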