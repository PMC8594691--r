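#' @import ggplot2
NULL

save_plot <- function(p, path, width = 7, height = 5) {
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 96)
  invisible(path)
}

#' Data layer for a p-value Q-Q plot
#'
#' Pairs the i-th smallest observed -log10 p-value with the expected
#' uniform quantile -log10((i - 0.5) / m), largest first.
#'
#' @param pvalues numeric p-values in \[0, 1\].
#' @return data.frame with `expected` and `observed` -log10 quantiles.
#' @export
qq_plot_data <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0L) stop("no p-values to plot")
  m <- length(pvalues)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = sort(-log10(pvalues), decreasing = TRUE))
}

#' P-value Q-Q plot
#'
#' Observed vs expected -log10 p-value quantiles with the identity line;
#' uniform p-values track the diagonal, enrichment of small p-values lifts
#' the upper tail.
#'
#' @param pvalues numeric p-values.
#' @param path output image file (png).
#' @return `path`, invisibly.
#' @export
qq_plot <- function(pvalues, path) {
  d <- qq_plot_data(pvalues)
  p <- ggplot(d, aes(x = .data$expected, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    geom_point(size = 0.8) +
    labs(x = expression(Expected ~ -log[10](p)),
         y = expression(Observed ~ -log[10](p))) +
    theme_bw()
  save_plot(p, path, width = 5, height = 5)
}

#' Data layer for a Manhattan plot
#'
#' Parses the table's `chrom:start-end` ids, lays chromosomes end to end
#' and returns per-row plotting coordinates plus the p-value threshold
#' corresponding to the FDR cutoff (the largest p among rows with
#' `fdr <= cutoff`; `NA` when nothing is significant).
#'
#' @param table an association table with `fdr`.
#' @param fdr_cutoff q-value cutoff for the threshold line.
#' @return list with `data` (chrom, start, xpos, neglogp, chrom_index) and
#'   `p_threshold`.
#' @export
manhattan_plot_data <- function(table, fdr_cutoff = 0.1) {
  if (nrow(table) == 0L) stop("empty association table")
  pos <- parse_position_id(table$id)
  chroms <- unique(pos$chrom[order(pos$chrom, method = "radix")])
  offsets <- c(0, cumsum(vapply(chroms, function(ch) {
    max(pos$start[pos$chrom == ch]) + 1
  }, 0)))
  names(offsets) <- c(chroms, "_end")
  idx <- match(pos$chrom, chroms)
  d <- data.frame(chrom = pos$chrom, start = pos$start,
                  xpos = pos$start + offsets[idx],
                  neglogp = -log10(table$pvalue),
                  chrom_index = idx, stringsAsFactors = FALSE)
  sig <- !is.na(table$fdr) & table$fdr <= fdr_cutoff
  p_threshold <- if (any(sig)) max(table$pvalue[sig]) else NA_real_
  list(data = d, p_threshold = p_threshold)
}

#' Manhattan plot for a position-level scan
#'
#' -log10(p) by genome order with chromosomes alternately coloured and a
#' line at the p-value threshold implied by the FDR cutoff.
#'
#' @param table an association table with `fdr`.
#' @param fdr_cutoff q-value cutoff for the threshold line.
#' @param path output image file (png).
#' @return `path`, invisibly.
#' @export
manhattan_plot <- function(table, fdr_cutoff = 0.1, path) {
  md <- manhattan_plot_data(table, fdr_cutoff)
  d <- md$data
  d$col <- factor(d$chrom_index %% 2L)
  p <- ggplot(d, aes(x = .data$xpos, y = .data$neglogp,
                     colour = .data$col)) +
    geom_point(size = 0.8, show.legend = FALSE) +
    scale_colour_manual(values = c("grey30", "steelblue")) +
    labs(x = "Genomic position", y = expression(-log[10](p))) +
    theme_bw()
  if (!is.na(md$p_threshold)) {
    p <- p + geom_hline(yintercept = -log10(md$p_threshold),
                        linetype = "dashed", colour = "red")
  }
  save_plot(p, path)
}

#' Data layer for a genotype interaction plot
#'
#' @param m_row methylation fractions over samples.
#' @param g_row genotype codes (1/2/3) over samples.
#' @param env environment values over samples.
#' @return data.frame with `env`, `meth` and `genotype` (factor AA/AB/BB).
#' @export
genotype_interaction_data <- function(m_row, g_row, env) {
  if (length(unique(g_row)) < 2L) {
    stop("all samples share one genotype class")
  }
  data.frame(env = env, meth = m_row,
             genotype = factor(c("AA", "AB", "BB")[g_row],
                               levels = c("AA", "AB", "BB")))
}

#' Genotype interaction plot for a GxE hit
#'
#' Methylation vs environment with one linear trend per genotype class
#' (AA = major homozygote, AB = heterozygote, BB = minor homozygote): the
#' environment effect split into genotype groups.
#'
#' @inheritParams genotype_interaction_data
#' @param path output image file (png).
#' @return `path`, invisibly.
#' @export
genotype_interaction_plot <- function(m_row, g_row, env, path) {
  d <- genotype_interaction_data(m_row, g_row, env)
  p <- ggplot(d, aes(x = .data$env, y = .data$meth,
                     colour = .data$genotype)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    labs(x = "Environment", y = "Methylation fraction",
         colour = "Genotype") +
    theme_bw()
  save_plot(p, path)
}

#' Data layer for a p-value histogram (20 bins on \[0, 1\])
#'
#' @param pvalues numeric p-values.
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
pvalue_histogram_data <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0L) stop("no p-values to plot")
  breaks <- seq(0, 1, length.out = 21L)
  bin <- pmin(pmax(ceiling(pvalues * 20), 1L), 20L)  # p = 0 goes to bin 1
  data.frame(bin_start = head(breaks, -1L), bin_end = breaks[-1L],
             count = tabulate(bin, 20L))
}

#' P-value histogram
#'
#' 20 equal bins on \[0, 1\]; uniform p-values give a flat profile, true
#' signal a spike near zero.
#'
#' @param pvalues numeric p-values.
#' @param path output image file (png).
#' @return `path`, invisibly.
#' @export
pvalue_histogram <- function(pvalues, path) {
  d <- pvalue_histogram_data(pvalues)
  p <- ggplot(d, aes(x = (.data$bin_start + .data$bin_end) / 2,
                     y = .data$count)) +
    geom_col(width = 0.05, fill = "steelblue") +
    labs(x = "p-value", y = "Count") +
    theme_bw()
  save_plot(p, path)
}

#' Data layer for a Gmodel significance dot matrix
#'
#' Cytosine coordinate x SNP coordinate with point size -log10(q), a
#' compact view of where methQTL pairs concentrate.
#'
#' @param table a pair-level association table with `snp` and `fdr`.
#' @return data.frame with `pos_start`, `snp_pos`, `neglogq`.
#' @export
dot_matrix_data <- function(table) {
  if (nrow(table) == 0L) stop("empty association table")
  pos <- parse_position_id(table$id)
  snp <- parse_variant_id(table$snp)
  data.frame(pos_start = pos$start, snp_pos = snp$pos,
             neglogq = -log10(pmax(table$fdr, 1e-300)))
}

#' Gmodel significance dot matrix plot
#'
#' @param table a pair-level association table.
#' @param path output image file (png).
#' @return `path`, invisibly.
#' @export
dot_matrix_plot <- function(table, path) {
  d <- dot_matrix_data(table)
  p <- ggplot(d, aes(x = .data$snp_pos, y = .data$pos_start,
                     size = .data$neglogq)) +
    geom_point(alpha = 0.6, colour = "steelblue") +
    labs(x = "SNP position", y = "Cytosine position",
         size = expression(-log[10](q))) +
    theme_bw()
  save_plot(p, path)
}
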