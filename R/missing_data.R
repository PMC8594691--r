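#' Filter positions by fraction of missing samples
#'
#' Keeps rows whose fraction of missing cells is at most `max_na_fraction`.
#' A threshold of 0 is the zero-tolerance setting: only positions observed
#' in every sample survive. A threshold of 1 keeps everything.
#'
#' @param matrix a [methylation_matrix()].
#' @param max_na_fraction maximum tolerated missing fraction in \[0, 1\].
#' @return The row-filtered matrix.
#' @export
filter_missing <- function(matrix, max_na_fraction = 0) {
  stopifnot(max_na_fraction >= 0, max_na_fraction <= 1)
  na_frac <- rowMeans(is.na(matrix$values))
  subset_matrix_rows(matrix, which(na_frac <= max_na_fraction))
}

#' Fit a beta distribution by the method of moments
#'
#' With sample mean m and sample variance v (n-1 denominator), sets
#' c = m(1-m)/v - 1, alpha = m*c, beta = (1-m)*c. When the variance is
#' (numerically) zero or the moments are incompatible with a beta law
#' (c <= 0), the fit is flagged degenerate and only the mean is kept.
#'
#' @param values numeric vector of >= 2 methylation fractions in \[0, 1\].
#' @return list with `alpha`, `beta`, `degenerate`, `mean`.
#' @export
fit_beta_moments <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 non-missing values")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  m <- mean(values)
  v <- var(values)
  if (v < 1e-12) {
    return(list(alpha = NA_real_, beta = NA_real_, degenerate = TRUE,
                mean = m))
  }
  cc <- m * (1 - m) / v - 1
  if (cc <= 0) {
    return(list(alpha = NA_real_, beta = NA_real_, degenerate = TRUE,
                mean = m))
  }
  list(alpha = m * cc, beta = (1 - m) * cc, degenerate = FALSE, mean = m)
}

# Deterministic per-cell seed: polynomial rolling hash of the cell key.
# Keeping the draw keyed by (chrom, start, sample, seed) makes an imputed
# value independent of which other rows are in the matrix, so p-values do
# not drift with chunking or row subsetting.
cell_seed <- function(chrom, start, sample_id, seed) {
  key <- sprintf("%s:%d:%s:%d", chrom, as.integer(start), sample_id,
                 as.integer(seed))
  bytes <- utf8ToInt(key)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Impute missing methylation values from per-position beta distributions
#'
#' Each missing cell is replaced by a draw from a beta distribution fitted
#' (method of moments) to the observed values of the same position, so the
#' estimated data perturb the model as little as possible. Degenerate rows
#' (zero variance or moments incompatible with a beta law) use the row mean.
#' The draw for a cell is seeded by (chrom, start, sample id, seed), so the
#' imputed value at a position does not depend on which other positions are
#' present.
#'
#' @param matrix a [methylation_matrix()] whose rows all have >= 2
#'   non-missing values (apply [filter_missing()] first).
#' @param seed integer master seed.
#' @return A complete [methylation_matrix()].
#' @export
impute_methylation <- function(matrix, seed = 1L) {
  vals <- matrix$values
  miss_rows <- which(rowSums(is.na(vals)) > 0L)
  if (length(miss_rows) == 0L) return(matrix)
  if (any(rowSums(!is.na(vals[miss_rows, , drop = FALSE])) < 2L)) {
    stop("every row must have >= 2 non-missing values before imputation")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  for (i in miss_rows) {
    fit <- fit_beta_moments(vals[i, ])
    cols <- which(is.na(vals[i, ]))
    for (j in cols) {
      set.seed(cell_seed(matrix$positions$chrom[i],
                         matrix$positions$start[i],
                         matrix$samples[j], seed))
      vals[i, j] <- if (fit$degenerate) fit$mean else {
        rbeta(1L, fit$alpha, fit$beta)
      }
    }
  }
  methylation_matrix(matrix$positions, matrix$samples, vals)
}

#' Impute missing genotype codes
#'
#' Variants with a missing fraction above the threshold are dropped; the
#' remaining missing codes are replaced by the variant's modal code (ties
#' resolve to the code closest to the variant mean, then to the smaller
#' code). This is a simple frequency-based imputer; haplotype-aware
#' imputation is out of scope.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing_fraction maximum tolerated per-variant missing
#'   fraction.
#' @return A complete [genotype_matrix()].
#' @export
impute_genotypes <- function(g, max_missing_fraction = 0.5) {
  codes <- g$codes
  na_frac <- rowMeans(is.na(codes))
  keep <- which(na_frac <= max_missing_fraction)
  codes <- codes[keep, , drop = FALSE]
  variants <- g$variants[keep, , drop = FALSE]
  for (i in which(rowSums(is.na(codes)) > 0L)) {
    v <- codes[i, ]
    obs <- v[!is.na(v)]
    tab <- table(obs)
    modes <- as.integer(names(tab)[tab == max(tab)])
    if (length(modes) > 1L) {
      d <- abs(modes - mean(obs))
      modes <- modes[d == min(d)]
    }
    codes[i, is.na(v)] <- min(modes)
  }
  genotype_matrix(variants, g$samples, codes)
}
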