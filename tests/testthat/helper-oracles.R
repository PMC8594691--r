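# Independent oracles and small in-code fixtures shared across test files.

# Naive per-row OLS refit via lm(); the reference the matrix scans must
# reproduce. `extra` is a named list of predictor vectors appended to the
# covariates; `term` names the tested coefficient in the lm output.
lm_oracle <- function(y, samples, extra, term) {
  df <- data.frame(y = y)
  for (cv in setdiff(colnames(samples), c("sample_id", "env"))) {
    v <- samples[[cv]]
    df[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  rhs <- paste(c(setdiff(colnames(df), "y")), collapse = " + ")
  # interaction term spelled explicitly when requested
  if (term == "G:E") rhs <- paste(rhs, "+ G:E")
  fit <- summary(lm(stats::as.formula(paste("y ~", rhs)), df))
  co <- fit$coefficients[term, ]
  list(beta = co[[1]], stat = co[[3]], pvalue = co[[4]])
}

# Hand-written BH step-up, independent of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Per-base brute-force union-DMR oracle: count distinct comparisons
# covering every single base, keep bases with coverage fraction >= X,
# then stitch runs of kept bases into intervals.
udmr_oracle <- function(dmrs, min_fraction, merge = TRUE) {
  n_comp <- length(unique(attr(dmrs, "comparisons") %||% dmrs$label))
  out <- list()
  for (ch in unique(dmrs$chrom)) {
    d <- dmrs[dmrs$chrom == ch, , drop = FALSE]
    lo <- min(d$start); hi <- max(d$end)
    bases <- lo:(hi - 1L)
    cover <- vapply(bases, function(b) {
      length(unique(d$label[d$start <= b & b < d$end]))
    }, 0L)
    keep <- cover / n_comp >= min_fraction
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = bases[starts[k]], end = bases[ends[k]] + 1L)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  if (!merge) {
    # split merged runs back at every boundary of the input intervals
    pieces <- list()
    bounds <- sort(unique(c(dmrs$start, dmrs$end)))
    for (i in seq_len(nrow(res))) {
      cuts <- sort(unique(c(res$start[i], res$end[i],
                            bounds[bounds > res$start[i] &
                                     bounds < res$end[i]])))
      for (k in seq_len(length(cuts) - 1L)) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = res$chrom[i], start = cuts[k], end = cuts[k + 1L])
      }
    }
    res <- do.call(rbind, pieces)
  }
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small deterministic methylation matrix builder.
toy_matrix <- function(values, starts = NULL, chrom = "c1",
                       samples = NULL, context = "CpG") {
  values <- as.matrix(values)
  if (is.null(starts)) starts <- seq(100L, by = 100L,
                                     length.out = nrow(values))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  methylation_matrix(
    data.frame(chrom = chrom, start = starts, end = starts + 1L,
               context = context, stringsAsFactors = FALSE),
    samples, values)
}

toy_samples <- function(n, env = NULL, covariates = NULL) {
  sample_frame(paste0("S", seq_len(n)),
               env %||% seq_len(n), covariates)
}

# Random scan instance used by the oracle-equivalence tests.
random_instance <- function(seed, n = 50L, npos = 10L, nvar = 3L) {
  set.seed(seed)
  samples <- sample_frame(
    sprintf("S%02d", seq_len(n)), rnorm(n),
    data.frame(cov1 = rnorm(n),
               cov2 = sample(c("a", "b", "c"), n, TRUE),
               cov3 = runif(n), stringsAsFactors = FALSE))
  m <- toy_matrix(matrix(runif(npos * n), npos, n),
                  starts = seq(100L, by = 200L, length.out = npos),
                  samples = samples$sample_id)
  codes <- matrix(0L, nvar, n)
  for (v in seq_len(nvar)) {
    repeat {
      codes[v, ] <- sample(1:3, n, TRUE, prob = c(0.45, 0.4, 0.15))
      if (length(unique(codes[v, ])) > 1L) break
    }
  }
  g <- genotype_matrix(
    data.frame(chrom = "c1",
               pos = seq(150L, by = 200L, length.out = nvar),
               ref = "C", alt = "T", qual = 60,
               stringsAsFactors = FALSE),
    samples$sample_id, codes)
  list(samples = samples, m = m, g = g)
}

write_toy_vcf <- function(path, chrom, pos, gt_rows, sample_ids,
                          qual = 60, ref = "C", alt = "T") {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", sample_ids),
                    collapse = "\t"))
  qual <- rep_len(qual, length(pos))
  ref <- rep_len(ref, length(pos)); alt <- rep_len(alt, length(pos))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom, pos[i], ".", ref[i], alt[i], qual[i], "PASS", ".",
            "GT", gt_rows[[i]]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}
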