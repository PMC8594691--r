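#' Simulation configuration
#'
#' Describes a synthetic targeted-bisulfite study: per-sample per-context
#' methylation calls with beta-binomial count structure, a biallelic SNP
#' panel in Hardy-Weinberg proportions, one numeric environment value per
#' sample and a categorical planting-site covariate, plus planted E, G and
#' GxE effects on the logit-methylation scale.
#'
#' The defaults emulate a clonal conifer common-garden design: 28 samples
#' across 3 planting sites, standard-normal environment, per-position
#' baseline methylation drawn from Beta(2, 2), negative-binomial coverage
#' with mean 15, logit-scale biological noise with SD 0.5, and a 10%
#' per-call dropout rate producing missing cells after the union step.
#'
#' @param n_samples number of samples.
#' @param n_contigs number of contigs.
#' @param positions_per_contig cytosines simulated per contig per context.
#' @param contexts methylation contexts to simulate.
#' @param contig_length contig length in bp.
#' @param a0,b0 beta parameters of the per-position baseline methylation.
#' @param n_variants number of biallelic SNPs.
#' @param maf_range minor-allele-frequency range, within (0, 0.5\].
#' @param env_mean,env_sd environment distribution (normal).
#' @param n_sites number of levels of the categorical site covariate.
#' @param site_effect_sd SD of the per-site logit offset.
#' @param noise_sd SD of the per-cell logit-scale biological noise.
#' @param effects data.frame of planted effects with columns `type`
#'   ("E", "G" or "GxE"), `context`, `contig` (1-based index), `pos_index`
#'   (1-based position index within the contig) and `size` (logit-scale
#'   effect per unit predictor); for G/GxE the nearest variant inside the
#'   cis window is the driver. An optional `maf` column pins the driver
#'   variant's minor-allele frequency, and an optional `base` column pins
#'   the target position's baseline methylation fraction, so that a
#'   recovery experiment measures detection of a well-identified effect
#'   (a logit-scale effect at a baseline near 0 or 1 is invisible on the
#'   bounded fraction scale) instead of averaging over driver frequency
#'   and baseline. `NULL` for a null configuration.
#' @param missing_rate per-call dropout probability.
#' @param cis_window bp window used to pick the driver variant of a
#'   planted G/GxE effect (matches the scan's cis pairing distance).
#' @param coverage_mean,coverage_size negative-binomial coverage (mean and
#'   size/overdispersion).
#' @param seed master seed.
#' @return list of settings (class `SimConfig`).
#' @export
sim_config <- function(n_samples = 28L, n_contigs = 2L,
                       positions_per_contig = 100L, contexts = "CpG",
                       contig_length = 50000L,
                       a0 = 2, b0 = 2, n_variants = 20L,
                       maf_range = c(0.1, 0.5),
                       env_mean = 0, env_sd = 1,
                       n_sites = 3L, site_effect_sd = 0.3,
                       noise_sd = 0.5,
                       effects = NULL, missing_rate = 0.1,
                       cis_window = 2000L,
                       coverage_mean = 15, coverage_size = 5,
                       seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  contexts <- match.arg(contexts, METH_CONTEXTS, several.ok = TRUE)
  cfg <- list(n_samples = as.integer(n_samples),
              n_contigs = as.integer(n_contigs),
              positions_per_contig = as.integer(positions_per_contig),
              contexts = contexts,
              contig_length = as.integer(contig_length),
              a0 = a0, b0 = b0, n_variants = as.integer(n_variants),
              maf_range = maf_range, env_mean = env_mean, env_sd = env_sd,
              n_sites = as.integer(n_sites),
              site_effect_sd = site_effect_sd, noise_sd = noise_sd,
              effects = effects, missing_rate = missing_rate,
              cis_window = as.integer(cis_window),
              coverage_mean = coverage_mean, coverage_size = coverage_size,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a study in memory
#'
#' Draws the full synthetic study described by a [sim_config()]: sample
#' sheet, per-sample per-context methylation records (6-column bedGraph
#' dialect, with dropout producing missing data), genotypes, and the truth
#' table of planted effects.
#'
#' @param config a [sim_config()].
#' @return list with `samples` (a [sample_frame()]), `records` (per
#'   context: named list of per-sample record data.frames), `genotypes`
#'   (a [genotype_matrix()]), `truth` (data.frame of planted effects with
#'   resolved coordinates), and `variants_df`.
#' @export
simulate_ewas_data <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%02d", seq_len(n))
  env <- rnorm(n, config$env_mean, config$env_sd)
  site <- paste0("site", ((seq_len(n) - 1L) %% config$n_sites) + 1L)
  samples <- sample_frame(sample_ids, env,
                          data.frame(cov1 = site,
                                     stringsAsFactors = FALSE))
  site_offset <- rnorm(config$n_sites, 0, config$site_effect_sd)
  names(site_offset) <- paste0("site", seq_len(config$n_sites))

  contigs <- sprintf("contig%02d", seq_len(config$n_contigs))

  # variant panel: positions spread over contigs, HWE genotypes
  maf <- runif(config$n_variants, config$maf_range[1], config$maf_range[2])
  var_contig <- contigs[((seq_len(config$n_variants) - 1L) %%
                           config$n_contigs) + 1L]
  var_pos <- integer(config$n_variants)
  for (ch in contigs) {
    k <- sum(var_contig == ch)
    var_pos[var_contig == ch] <-
      sort(sample.int(config$contig_length - 1L, k)) + 1L
  }
  dosage <- matrix(0L, config$n_variants, n)
  for (v in seq_len(config$n_variants)) {
    dosage[v, ] <- rbinom(n, 2L, maf[v])
  }
  variants_df <- data.frame(chrom = var_contig, pos = var_pos,
                            ref = "C", alt = "T", qual = 60,
                            stringsAsFactors = FALSE)
  ord <- order(variants_df$chrom, variants_df$pos, method = "radix")
  variants_df <- variants_df[ord, , drop = FALSE]
  rownames(variants_df) <- NULL
  dosage <- dosage[ord, , drop = FALSE]

  records <- list(); truth <- list()
  for (ctx in config$contexts) {
    per_contig_pos <- lapply(contigs, function(ch) {
      sort(sample.int(config$contig_length - 1L,
                      config$positions_per_contig))
    })
    positions <- data.frame(
      chrom = rep(contigs, each = config$positions_per_contig),
      start = unlist(per_contig_pos), stringsAsFactors = FALSE)
    positions$end <- positions$start + 1L
    npos <- nrow(positions)
    base <- rbeta(npos, config$a0, config$b0)
    base <- pmin(pmax(base, 0.02), 0.98)  # keep logit finite
    logit_mu <- matrix(qlogis(base), npos, n)
    logit_mu <- logit_mu + matrix(site_offset[site], npos, n, byrow = TRUE)

    eff <- config$effects
    if (!is.null(eff)) eff <- eff[eff$context == ctx, , drop = FALSE]
    if (!is.null(eff) && nrow(eff) > 0L) {
      for (k in seq_len(nrow(eff))) {
        ch <- contigs[eff$contig[k]]
        on_contig <- which(positions$chrom == ch)
        driver <- NA_character_
        if (eff$type[k] %in% c("G", "GxE")) {
          cand <- which(variants_df$chrom == ch)
          if (length(cand) == 0L) stop("no variant on contig ", ch)
          # plant only where a driver exists inside the cis window so the
          # scan's pairing can see the effect
          var_starts <- variants_df$pos[cand] - 1L
          near <- vapply(positions$start[on_contig], function(p) {
            min(abs(var_starts - p)) <= config$cis_window
          }, logical(1L))
          testable <- on_contig[near]
          if (length(testable) < eff$pos_index[k]) {
            stop("fewer than ", eff$pos_index[k],
                 " positions within the cis window of a variant on ", ch)
          }
          row_i <- testable[eff$pos_index[k]]
          v <- cand[which.min(abs(var_starts - positions$start[row_i]))]
          driver <- variant_id(variants_df[v, , drop = FALSE])
          if (!is.null(eff$maf) && !is.na(eff$maf[k])) {
            dosage[v, ] <- rbinom(n, 2L, eff$maf[k])
          }
          pred <- dosage[v, ]
          if (eff$type[k] == "GxE") pred <- pred * env
        } else {
          row_i <- on_contig[eff$pos_index[k]]
          pred <- env
        }
        if (!is.null(eff$base) && !is.na(eff$base[k])) {
          logit_mu[row_i, ] <- qlogis(eff$base[k]) + site_offset[site]
        }
        logit_mu[row_i, ] <- logit_mu[row_i, ] + eff$size[k] * pred
        truth[[length(truth) + 1L]] <- data.frame(
          context = ctx, chrom = ch, start = positions$start[row_i],
          end = positions$end[row_i], type = eff$type[k],
          size = eff$size[k], snp = driver, stringsAsFactors = FALSE)
      }
    }
    p_true <- plogis(logit_mu + matrix(rnorm(npos * n, 0, config$noise_sd),
                                       npos, n))
    coverage <- matrix(rnbinom(npos * n, mu = config$coverage_mean,
                               size = config$coverage_size), npos, n)
    meth_counts <- matrix(rbinom(npos * n, as.vector(coverage),
                                 as.vector(p_true)), npos, n)
    dropout <- matrix(runif(npos * n) < config$missing_rate, npos, n)
    keep_cell <- !dropout & coverage > 0L

    records[[ctx]] <- lapply(seq_len(n), function(s) {
      keep <- keep_cell[, s]
      data.frame(chrom = positions$chrom[keep],
                 start = positions$start[keep],
                 end = positions$end[keep],
                 context = ctx,
                 value = meth_counts[keep, s] / coverage[keep, s],
                 coverage = coverage[keep, s],
                 stringsAsFactors = FALSE)
    })
    names(records[[ctx]]) <- sample_ids
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(context = character(0), chrom = character(0),
               start = integer(0), end = integer(0), type = character(0),
               size = numeric(0), snp = character(0),
               stringsAsFactors = FALSE)
  gt_strings <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L],
                       nrow = config$n_variants)
  codes <- t(apply(gt_strings, 1L, encode_genotype))
  genotypes <- genotype_matrix(variants_df, sample_ids, codes)
  list(samples = samples, records = records, genotypes = genotypes,
       truth = truth, variants_df = variants_df)
}

write_minimal_vcf <- function(variants_df, gt_codes_dosage, sample_ids,
                              path) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", sample_ids),
                    collapse = "\t"))
  gt <- matrix(c("0/0", "0/1", "1/1")[gt_codes_dosage + 1L],
               nrow = nrow(variants_df))
  gt[is.na(gt_codes_dosage)] <- "./."
  body <- vapply(seq_len(nrow(variants_df)), function(i) {
    paste(c(variants_df$chrom[i], variants_df$pos[i], ".",
            variants_df$ref[i], variants_df$alt[i],
            format_num(variants_df$qual[i]), "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

write_bedgraph_records <- function(records, path) {
  if (nrow(records) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  cm <- as.integer(round(records$value * records$coverage))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", records$chrom, records$start,
                   records$end, format_num(records$value * 100), cm,
                   records$coverage - cm)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a complete on-disk input bundle
#'
#' Writes everything a pipeline run needs: per-sample 6-column bedGraphs
#' under `methylation/<context>/<sample>.bedGraph`, a biallelic VCF
#' (`snps.vcf`), a headerless sample sheet (`samples.tsv`) and a truth TSV
#' of planted effects (`truth.tsv`). Fully reproducible from the config
#' seed: the same seed yields a byte-identical bundle.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return The in-memory study (as [simulate_ewas_data()]), invisibly.
#' @export
simulate_dataset <- function(config = sim_config(), outdir) {
  sim <- simulate_ewas_data(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (ctx in names(sim$records)) {
    d <- file.path(outdir, "methylation", ctx)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (s in names(sim$records[[ctx]])) {
      write_bedgraph_records(sim$records[[ctx]][[s]],
                             file.path(d, paste0(s, ".bedGraph")))
    }
  }
  dosage <- code_to_alt_dosage(sim$genotypes)
  write_minimal_vcf(sim$genotypes$variants, dosage, sim$genotypes$samples,
                    file.path(outdir, "snps.vcf"))
  sheet <- cbind(sim$samples$sample_id, format_num(sim$samples$env),
                 as.matrix(as.data.frame(sim$samples)[,
                   covariate_names(sim$samples), drop = FALSE]))
  writeLines(apply(sheet, 1L, paste, collapse = "\t"),
             file.path(outdir, "samples.tsv"))
  tr <- sim$truth
  tr_lines <- c(paste(colnames(tr), collapse = "\t"),
                if (nrow(tr) > 0L) vapply(seq_len(nrow(tr)), function(i) {
                  paste(c(tr$context[i], tr$chrom[i], tr$start[i],
                          tr$end[i], tr$type[i], format_num(tr$size[i]),
                          tr$snp[i]), collapse = "\t")
                }, ""))
  writeLines(tr_lines, file.path(outdir, "truth.tsv"))
  invisible(sim)
}

# invert the 1/2/3 coding back to alt-allele dosage for VCF output: code 2
# is always het; for homozygotes the orientation depends on which allele
# is major, recovered from the per-variant code frequencies
code_to_alt_dosage <- function(g) {
  codes <- g$codes
  out <- matrix(NA_integer_, nrow(codes), ncol(codes))
  for (i in seq_len(nrow(codes))) {
    v <- codes[i, ]
    n1 <- sum(v == 1L, na.rm = TRUE); n3 <- sum(v == 3L, na.rm = TRUE)
    het <- sum(v == 2L, na.rm = TRUE)
    # code 1 = major homozygote; decide whether REF or ALT is major such
    # that encode_genotype() round-trips: ties resolved to REF major
    major_count <- 2L * n1 + het; minor_count <- 2L * n3 + het
    ref_major <- major_count >= minor_count
    out[i, ] <- ifelse(is.na(v), NA_integer_,
                       ifelse(v == 2L, 1L,
                              ifelse(v == 1L, if (ref_major) 0L else 2L,
                                     if (ref_major) 2L else 0L)))
  }
  out
}

#' Build the union methylation matrix of a simulated study
#'
#' Convenience wrapper: unite the per-sample records of one context.
#'
#' @param sim output of [simulate_ewas_data()].
#' @param context methylation context.
#' @return A [methylation_matrix()].
#' @export
sim_union_matrix <- function(sim, context = "CpG") {
  union_positions(sim$records[[context]], sim$samples)
}

#' Write the tiny worked example bundle
#'
#' A fixed, hand-checkable study: 4 samples, 10 CpG positions on one
#' contig, 3 SNPs, 2 DMR comparison files, and a sample sheet with one
#' categorical covariate. All numbers are literal constants, so the bundle
#' is byte-identical on every regeneration and the planted slope at the
#' first position can be verified by hand against the Emodel output.
#'
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
make_worked_example <- function(outdir) {
  dir.create(file.path(outdir, "methylation", "CpG"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "dmrs"), showWarnings = FALSE)
  samples <- c("S1", "S2", "S3", "S4")
  env <- c(1, 2, 3, 4)
  site <- c("north", "north", "south", "south")
  writeLines(sprintf("%s\t%s\t%s", samples, format_num(env), site),
             file.path(outdir, "samples.tsv"))
  starts <- c(100L, 150L, 200L, 260L, 320L, 400L, 480L, 560L, 640L, 720L)
  # position 1 tracks env almost linearly (slope 0.11 after adjusting for
  # the site covariate, computable by hand via within-site centering); an
  # exactly linear row would have zero residual and be dropped as
  # non-finite by the scan
  # within-site increments differ between the two sites in every row, so
  # no row is an exact (zero-residual) fit of the site + env model
  vals <- rbind(
    c(0.10, 0.20, 0.30, 0.42),
    c(0.50, 0.52, 0.46, 0.50),
    c(0.80, 0.74, 0.82, 0.78),
    c(0.20, 0.26, 0.22, 0.16),
    c(0.60, 0.58, 0.61, 0.65),
    c(0.40, 0.46, 0.36, 0.44),
    c(0.30, 0.28, 0.36, 0.32),
    c(0.70, 0.73, 0.66, 0.64),
    c(0.55, 0.50, 0.52, 0.58),
    c(0.25, 0.28, 0.22, 0.26))
  coverage <- 20L
  for (s in seq_along(samples)) {
    rec <- data.frame(chrom = "contig01", start = starts,
                      end = starts + 1L, context = "CpG",
                      value = vals[, s], coverage = coverage)
    write_bedgraph_records(rec,
      file.path(outdir, "methylation", "CpG",
                paste0(samples[s], ".bedGraph")))
  }
  vcf_variants <- data.frame(chrom = "contig01",
                             pos = c(120L, 300L, 650L),
                             ref = "C", alt = "T", qual = 60,
                             stringsAsFactors = FALSE)
  dosage <- rbind(c(0L, 1L, 1L, 1L),
                  c(0L, 1L, 1L, 2L),
                  c(2L, 1L, 1L, 0L))
  write_minimal_vcf(vcf_variants, dosage, samples,
                    file.path(outdir, "snps.vcf"))
  writeLines(c("contig01\t90\t210", "contig01\t300\t500"),
             file.path(outdir, "dmrs", "AB.bed"))
  writeLines(c("contig01\t140\t340", "contig01\t600\t700"),
             file.path(outdir, "dmrs", "AC.bed"))
  invisible(outdir)
}
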