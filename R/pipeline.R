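#' Run the EWAS pipeline end to end
#'
#' Orchestrates, per methylation context: reading per-sample bedGraph
#' calls (coverage filter), uniting them into one matrix, optional
#' restriction to DMPs / DMRs or averaging over union-DMRs, variation and
#' missing-data filtering, beta-distribution imputation, and the Emodel /
#' Gmodel / GxE scans with a global BH correction. Gmodel and GxE run only
#' when genotypes are supplied. Output follows the standard layout:
#' `input/` (env.txt, cov.txt, snps.txt, gxe.txt,
#' bed/\{unfiltered,filtered,imputed\}), and `positions/` or `regions/`
#' (averaged DMR input) with one directory per model.
#'
#' @param samples a [sample_frame()] or path to a headerless sample sheet.
#' @param methylation_dir directory with one subdirectory per context
#'   (`CpG`, `CHG`, `CHH`), each holding `<sample>.bedGraph` files.
#' @param outdir output directory.
#' @param snps optional VCF path (or a [genotype_matrix()]); enables
#'   Gmodel and GxE.
#' @param dmps optional character vector of DMP BED files (one per
#'   pairwise comparison); rows are restricted to their union.
#' @param dmrs optional character vector of DMR BED files.
#' @param dmrs_averaged with `dmrs`: average methylation over union-DMRs
#'   instead of keeping per-position rows.
#' @param udmr_fraction minimum supporting fraction for union-DMRs.
#' @param udmr_merge coalesce adjacent kept union-DMR intervals.
#' @param contexts contexts to analyse (default all three).
#' @param coverage minimum per-call read coverage (default 5).
#' @param distance cis-window in bp for Gmodel/GxE (default 2000).
#' @param filter_na maximum tolerated missing fraction per position
#'   (default 0: zero tolerance).
#' @param fdr q-value cutoff for filtered outputs (default 0.1).
#' @param min_sd,min_range optional per-position variation filters
#'   (fraction scale).
#' @param min_qual,max_snp_missing,min_mac VCF site filters.
#' @param seed master seed for the imputation draws.
#' @param chunks number of row chunks for the scans (output is identical
#'   for any chunking).
#' @param plots write diagnostic plots (Q-Q, histogram, Manhattan,
#'   genotype interaction) next to the tables.
#' @param models restrict to a subset of `c("Emodel", "Gmodel", "GxE")`;
#'   default `NULL` selects automatically from the inputs (Gmodel/GxE
#'   need genotypes).
#' @return Invisibly, a nested list `result[[context]][[model]]` of
#'   association tables, plus `$matrices[[context]]` (the imputed matrix).
#' @export
run_ewas <- function(samples, methylation_dir, outdir,
                     snps = NULL, dmps = NULL, dmrs = NULL,
                     dmrs_averaged = FALSE, udmr_fraction = 0.5,
                     udmr_merge = TRUE,
                     contexts = METH_CONTEXTS,
                     coverage = 5L, distance = 2000L, filter_na = 0,
                     fdr = 0.1, min_sd = NULL, min_range = NULL,
                     min_qual = 30, max_snp_missing = 0, min_mac = 3L,
                     seed = 1L, chunks = 1L, plots = TRUE, models = NULL) {
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  config <- scan_config(distance = distance, fdr_cutoff = fdr)
  if (!is.null(dmps) && !is.null(dmrs)) {
    stop("provide DMPs or DMRs, not both")
  }
  contexts <- intersect(contexts,
                        list.dirs(methylation_dir, recursive = FALSE,
                                  full.names = FALSE))
  if (length(contexts) == 0L) {
    stop("no enabled context has a subdirectory under ", methylation_dir)
  }

  g <- NULL
  if (!is.null(snps)) {
    g <- if (is.character(snps)) {
      read_vcf_genotypes(snps, samples, min_qual = min_qual,
                         max_missing_fraction = max_snp_missing,
                         min_minor_allele_count = min_mac)
    } else snps
    if (anyNA(g$codes)) g <- impute_genotypes(g, max_snp_missing)
  }

  input_dir <- file.path(outdir, "input")
  for (d in c("unfiltered", "filtered", "imputed")) {
    dir.create(file.path(input_dir, "bed", d), recursive = TRUE,
               showWarnings = FALSE)
  }
  write_input_files(samples, g, input_dir)

  region_level <- !is.null(dmrs) && dmrs_averaged
  level_dir <- if (region_level) "regions" else "positions"

  regions <- NULL
  if (!is.null(dmps)) regions <- read_regions(dmps)
  if (!is.null(dmrs)) {
    regions <- build_union_dmrs(read_regions(dmrs),
                                min_fraction = udmr_fraction,
                                merge = udmr_merge)
  }

  result <- list(matrices = list())
  for (ctx in contexts) {
    ctx_dir <- file.path(methylation_dir, ctx)
    files <- list.files(ctx_dir, pattern = "\\.bedGraph$",
                        full.names = TRUE)
    names(files) <- sub("\\.bedGraph$", "", basename(files))
    missing <- setdiff(samples$sample_id, names(files))
    if (length(missing) > 0L) {
      stop("no bedGraph for sample(s) ", paste(missing, collapse = ", "),
           " in ", ctx_dir)
    }
    per_sample <- lapply(files[samples$sample_id], read_bedgraph,
                         min_coverage = coverage, context = ctx)
    m <- union_positions(per_sample, samples)
    message(sprintf("[%s] union matrix: %d positions", ctx, nrow(m$values)))
    write_union_bedgraph(m, file.path(input_dir, "bed", "unfiltered",
                                      paste0(ctx, ".bedGraph")))
    if (!is.null(regions)) {
      m <- if (region_level) average_over_regions(m, regions) else
        restrict_to_regions(m, regions)
      message(sprintf("[%s] after region restriction: %d rows", ctx,
                      nrow(m$values)))
    }
    m <- filter_by_variation(m, min_sd = min_sd, min_range = min_range)
    m <- filter_missing(m, filter_na)
    message(sprintf("[%s] after variation/NA filters: %d rows", ctx,
                    nrow(m$values)))
    write_union_bedgraph(m, file.path(input_dir, "bed", "filtered",
                                      paste0(ctx, ".bedGraph")))
    if (nrow(m$values) == 0L) {
      warning("no position left after filtering in context ", ctx,
              call. = FALSE)
      next
    }
    m <- impute_methylation(m, seed = seed)
    write_union_bedgraph(m, file.path(input_dir, "bed", "imputed",
                                      paste0(ctx, ".bedGraph")))
    result$matrices[[ctx]] <- m

    design <- design_matrix(samples)
    auto <- c("Emodel", if (!is.null(g)) c("Gmodel", "GxE"))
    ctx_models <- if (is.null(models)) auto else intersect(models, auto)
    if (length(ctx_models) == 0L) {
      stop("requested model(s) need genotype input (--snps)")
    }
    for (model in ctx_models) {
      tab <- switch(model,
        Emodel = chunked_scan("emodel", m, samples = samples,
                              design = design, config = config,
                              n_chunks = chunks),
        Gmodel = chunked_scan("gmodel", m, g = g, samples = samples,
                              design = design, config = config,
                              n_chunks = chunks),
        GxE = chunked_scan("gxe", m, g = g, samples = samples,
                           design = design, config = config,
                           n_chunks = chunks))
      mdir <- file.path(outdir, level_dir, model)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      write_association_table(tab,
        file.path(mdir, sprintf("%s_%s.txt", ctx, model)))
      sig <- tab[!is.na(tab$fdr) & tab$fdr < fdr, , drop = FALSE]
      write_association_table(sig,
        file.path(mdir, sprintf("%s_%s.filtered_%s.txt", ctx, model,
                                format_num(fdr))))
      message(sprintf("[%s] %s: %d tested, %d significant at q < %s",
                      ctx, model, nrow(tab), nrow(sig), format_num(fdr)))
      result[[ctx]][[model]] <- tab
      if (plots && nrow(tab) > 0L) {
        write_model_plots(tab, model, ctx, mdir, fdr, m, g, samples)
      }
    }
  }
  invisible(result)
}

write_input_files <- function(samples, g, input_dir) {
  writeLines(c("sample\tenv",
               sprintf("%s\t%s", samples$sample_id,
                       format_num(samples$env))),
             file.path(input_dir, "env.txt"))
  covs <- covariate_names(samples)
  cov_mat <- design_matrix(samples)$X
  cov_lines <- c(paste(c("sample", colnames(cov_mat)[-1L]),
                       collapse = "\t"),
                 vapply(seq_len(nrow(samples)), function(i) {
                   paste(c(samples$sample_id[i],
                           format_num(cov_mat[i, -1L])), collapse = "\t")
                 }, ""))
  if (length(covs) == 0L) cov_lines <- "sample"
  writeLines(cov_lines, file.path(input_dir, "cov.txt"))
  # gxe.txt: covariates with the environment appended, the predictor block
  # used by the interaction model
  gxe_lines <- c(paste(c("sample", colnames(cov_mat)[-1L], "env"),
                       collapse = "\t"),
                 vapply(seq_len(nrow(samples)), function(i) {
                   paste(c(samples$sample_id[i],
                           if (ncol(cov_mat) > 1L)
                             format_num(cov_mat[i, -1L]),
                           format_num(samples$env[i])), collapse = "\t")
                 }, ""))
  writeLines(gxe_lines, file.path(input_dir, "gxe.txt"))
  if (!is.null(g)) {
    lines <- c(paste(c("snp", g$samples), collapse = "\t"),
               vapply(seq_len(nrow(g$codes)), function(i) {
                 paste(c(rownames(g$codes)[i], g$codes[i, ]),
                       collapse = "\t")
               }, ""))
    writeLines(lines, file.path(input_dir, "snps.txt"))
  }
}

write_model_plots <- function(tab, model, ctx, mdir, fdr, m, g, samples) {
  qq_plot(tab$pvalue, file.path(mdir, sprintf("%s_%s_qq.png", ctx, model)))
  pvalue_histogram(tab$pvalue,
                   file.path(mdir, sprintf("%s_%s_hist.png", ctx, model)))
  if (model == "Emodel") {
    manhattan_plot(tab, fdr,
                   file.path(mdir, sprintf("%s_%s_manhattan.png", ctx,
                                           model)))
  }
  if (model == "Gmodel") {
    dot_matrix_plot(tab, file.path(mdir, sprintf("%s_%s_dots.png", ctx,
                                                 model)))
  }
  if (model == "GxE") {
    top <- tab[which.min(tab$pvalue), ]
    g_row <- g$codes[top$snp, ]
    if (length(unique(g_row)) >= 2L) {
      genotype_interaction_plot(m$values[top$id, ], g_row, samples$env,
        file.path(mdir, sprintf("%s_%s_interaction.png", ctx, model)))
    }
  }
}
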