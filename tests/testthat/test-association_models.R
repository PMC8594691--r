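test_that("residualization projects out the design", {
  s <- toy_samples(3L)
  d <- design_matrix(s, covariates = character(0))
  expect_equal(residualize(c(1, 2, 3), d), c(-1, 0, 1))

  # idempotence on an already-orthogonal vector
  y <- c(-1, 0, 1)
  expect_equal(residualize(y, d), y, tolerance = 1e-12)

  # equals dense OLS residuals on random instances
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50
    sf <- sample_frame(sprintf("S%02d", 1:n), rnorm(n),
                       data.frame(cov1 = rnorm(n),
                                  cov2 = sample(c("u", "v"), n, TRUE),
                                  cov3 = runif(n)))
    dm <- design_matrix(sf)
    y <- rnorm(n)
    r <- residualize(y, dm)
    ref <- residuals(lm(y ~ cov1 + factor(cov2) + cov3, data = sf))
    expect_equal(unname(r), unname(ref), tolerance = 1e-10)
    expect_lt(max(abs(crossprod(dm$X, r))), 1e-8 * sqrt(sum(y^2)))
  }
})

test_that("design matrix validates rank and degrees of freedom", {
  s <- toy_samples(4L, covariates = data.frame(a = c("x", "x", "y", "y")))
  d <- design_matrix(s)
  expect_equal(d$rank, 2L)
  # collinear covariates are refused
  s2 <- toy_samples(6L, covariates = data.frame(a = 1:6, b = 2 * (1:6)))
  expect_error(design_matrix(s2), "rank deficient")
  # too few residual df
  s3 <- toy_samples(3L, covariates = data.frame(a = c("x", "y", "z")))
  expect_error(design_matrix(s3), "too few samples")
})

test_that("Emodel reproduces closed-form slopes and drops exact fits", {
  s <- toy_samples(3L, env = c(1, 2, 3))
  m <- toy_matrix(rbind(c(0.1, 0.2, 0.4)))
  tab <- emodel_scan(m, s, design_matrix(s))
  expect_equal(tab$beta, 0.15)  # Sxy/Sxx = 0.3/2

  # an exact linear relation has zero residual: non-finite stat, dropped
  m2 <- toy_matrix(rbind(c(0.1, 0.2, 0.3), c(0.1, 0.25, 0.33)))
  tab2 <- emodel_scan(m2, s, design_matrix(s))
  expect_equal(tab2$id, "c1:200-201")
  cfg_keep <- scan_config(drop_nonfinite = FALSE)
  tab3 <- emodel_scan(m2, s, design_matrix(s), cfg_keep)
  expect_equal(nrow(tab3), 2L)
  expect_false(is.finite(tab3$stat[1]))

  expect_error(emodel_scan(m, toy_samples(3L, env = c(1, 1, 1)),
                           design_matrix(s)), "constant")
})

test_that("all three scans match naive per-row OLS refits", {
  inst <- random_instance(7, n = 50L, npos = 12L, nvar = 3L)
  d <- design_matrix(inst$samples)
  cfg <- scan_config(all_pairs = TRUE)
  E <- inst$samples$env

  e_tab <- emodel_scan(inst$m, inst$samples, d, cfg)
  for (i in seq_len(nrow(e_tab))) {
    ref <- lm_oracle(inst$m$values[e_tab$id[i], ], inst$samples,
                     list(E = E), "E")
    expect_equal(e_tab$beta[i], ref$beta, tolerance = 1e-8)
    expect_equal(e_tab$stat[i], ref$stat, tolerance = 1e-8)
    expect_equal(e_tab$pvalue[i], ref$pvalue, tolerance = 1e-8)
  }

  g_tab <- gmodel_scan(inst$m, inst$g, d, cfg)
  expect_equal(nrow(g_tab), 12L * 3L)
  for (i in sample(nrow(g_tab), 10)) {
    G <- as.numeric(inst$g$codes[g_tab$snp[i], ])
    ref <- lm_oracle(inst$m$values[g_tab$id[i], ], inst$samples,
                     list(G = G), "G")
    expect_equal(g_tab$beta[i], ref$beta, tolerance = 1e-8)
    expect_equal(g_tab$stat[i], ref$stat, tolerance = 1e-8)
  }

  x_tab <- gxe_scan(inst$m, inst$g, inst$samples, d, cfg)
  for (i in sample(nrow(x_tab), 10)) {
    G <- as.numeric(inst$g$codes[x_tab$snp[i], ])
    ref <- lm_oracle(inst$m$values[x_tab$id[i], ], inst$samples,
                     list(G = G, E = E), "G:E")
    expect_equal(x_tab$beta[i], ref$beta, tolerance = 1e-8)
    expect_equal(x_tab$stat[i], ref$stat, tolerance = 1e-8)
    expect_equal(x_tab$pvalue[i], ref$pvalue, tolerance = 1e-8)
  }
})

test_that("Emodel is equivariant under scaling of E and matches Pearson", {
  inst <- random_instance(13, n = 30L, npos = 5L)
  d <- design_matrix(inst$samples)
  base <- emodel_scan(inst$m, inst$samples, d)
  scaled_samples <- inst$samples
  scaled_samples$env <- inst$samples$env * 4
  scaled <- emodel_scan(inst$m, scaled_samples, d)
  expect_equal(scaled$beta, base$beta / 4, tolerance = 1e-12)
  expect_equal(scaled$stat, base$stat, tolerance = 1e-12)
  expect_equal(scaled$pvalue, base$pvalue, tolerance = 1e-12)

  # with no covariates the t statistic is the Pearson-correlation t
  s0 <- sample_frame(inst$samples$sample_id, inst$samples$env)
  d0 <- design_matrix(s0)
  t0 <- emodel_scan(inst$m, s0, d0)
  n <- nrow(s0)
  for (i in seq_len(nrow(t0))) {
    r <- cor(inst$m$values[t0$id[i], ], s0$env)
    expect_equal(t0$stat[i], r * sqrt((n - 2) / (1 - r^2)),
                 tolerance = 1e-10)
  }
})

test_that("Gmodel pairs by cis distance and is permutation invariant", {
  s <- toy_samples(6L, env = rnorm(6))
  m <- toy_matrix(rbind(c(0.1, 0.1, 0.2, 0.2, 0.3, 0.3)),
                  starts = 1000L)
  # variant 3000 bp away is outside a 2000 bp window
  far <- genotype_matrix(
    data.frame(chrom = "c1", pos = 4000L, ref = "C", alt = "T",
               qual = 60), s$sample_id,
    matrix(c(1L, 1L, 2L, 2L, 3L, 3L), 1))
  d <- design_matrix(s)
  expect_warning(t_far <- gmodel_scan(m, far, d,
                                      scan_config(distance = 2000L)),
                 "no \\(position, variant\\) pair")
  expect_equal(nrow(t_far), 0L)

  near <- genotype_matrix(
    data.frame(chrom = "c1", pos = 1500L, ref = "C", alt = "T",
               qual = 60), s$sample_id,
    matrix(c(1L, 1L, 2L, 2L, 3L, 3L), 1))
  # the constructed fit is exact (zero residual), so keep non-finite rows
  cfg_keep <- scan_config(distance = 2000L, drop_nonfinite = FALSE)
  tab <- gmodel_scan(m, near, d, cfg_keep)
  expect_equal(tab$beta, 0.1)  # 0.1 methylation per code step

  # coherent sample permutation leaves statistics unchanged
  set.seed(5)
  perm <- sample(6)
  s_p <- sample_frame(s$sample_id[perm], s$env[perm])
  m_p <- methylation_matrix(m$positions, s_p$sample_id,
                            m$values[, perm, drop = FALSE])
  g_p <- genotype_matrix(near$variants, s_p$sample_id,
                         near$codes[, perm, drop = FALSE])
  tab_p <- gmodel_scan(m_p, g_p, design_matrix(s_p), cfg_keep)
  expect_equal(tab_p$beta, tab$beta, tolerance = 1e-12)
  expect_equal(tab_p$stat, tab$stat)

  # constant variants are skipped
  const <- genotype_matrix(near$variants, s$sample_id,
                           matrix(rep(2L, 6), 1))
  suppressMessages(tc <- gmodel_scan(m, const, d))
  expect_equal(nrow(tc), 0L)
})

test_that("GxE recovers a linear interaction and skips one-class variants", {
  # spec-style linear generation: M = 0.3 + 0.05 G E + noise; the fitted
  # interaction should cover the truth in about 95% of replicates
  set.seed(99)
  n <- 50
  covered <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    G <- sample(1:3, n, TRUE)
    E <- rnorm(n)
    M <- 0.3 + 0.05 * G * E + rnorm(n, 0, 0.05)
    M <- pmin(pmax(M, 0), 1)
    s <- sample_frame(sprintf("S%02d", 1:n), E)
    m <- toy_matrix(matrix(M, 1), starts = 100L, samples = s$sample_id)
    g <- genotype_matrix(data.frame(chrom = "c1", pos = 101L, ref = "C",
                                    alt = "T", qual = 60),
                         s$sample_id, matrix(as.integer(G), 1))
    tab <- gxe_scan(m, g, s, design_matrix(s))
    ci_half <- qt(0.975, n - 4) * tab$beta / tab$stat
    if (abs(tab$beta - 0.05) <= ci_half) covered <- covered + 1L
  }
  expect_gte(covered / reps, 0.9)

  # a variant with a single genotype class yields no testable pair
  s <- toy_samples(10L, env = rnorm(10))
  m <- toy_matrix(matrix(runif(10), 1), starts = 100L)
  g1 <- genotype_matrix(data.frame(chrom = "c1", pos = 101L, ref = "C",
                                   alt = "T", qual = 60),
                        s$sample_id, matrix(rep(1L, 10), 1))
  suppressMessages(expect_equal(nrow(gxe_scan(m, g1, s, design_matrix(s))), 0L))
})

test_that("BH step-up matches hand examples and a reference oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "finite")

  set.seed(77)
  for (r in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # step-up property: q non-decreasing in p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("chunked scans merge to the exact unchunked result", {
  inst <- random_instance(21, n = 40L, npos = 60L, nvar = 4L)
  d <- design_matrix(inst$samples)
  cfg <- scan_config(all_pairs = TRUE)
  for (model in c("emodel", "gmodel", "gxe")) {
    one <- chunked_scan(model, inst$m, g = inst$g,
                        samples = inst$samples, design = d,
                        config = cfg, n_chunks = 1L)
    ten <- chunked_scan(model, inst$m, g = inst$g,
                        samples = inst$samples, design = d,
                        config = cfg, n_chunks = 10L)
    expect_identical(one, ten)
  }

  # duplicate keys across chunks are an error
  tab <- plantewas:::new_association_table(
    id = "c1:1-2", beta = 0.1, stat = 1, pvalue = 0.5)
  expect_error(merge_chunked(list(tab, tab)), "duplicate")

  # single chunk: identity plus FDR
  single <- merge_chunked(list(tab))
  expect_equal(single$fdr, 0.5)
})
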