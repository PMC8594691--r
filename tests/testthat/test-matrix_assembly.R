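make_records <- function(starts, values, chrom = "c1", context = "CpG") {
  data.frame(chrom = chrom, start = starts, end = starts + 1L,
             context = context, value = values, coverage = 10L,
             stringsAsFactors = FALSE)
}

test_that("union of per-sample calls matches set semantics", {
  samples <- toy_samples(2L)
  per <- list(S1 = make_records(10L, 0.2),
              S2 = make_records(c(10L, 20L), c(0.4, 0.6)))
  m <- union_positions(per, samples)
  expect_equal(nrow(m$values), 2L)
  expect_true(is.na(m$values["c1:20-21", "S1"]))
  expect_equal(m$values["c1:10-11", ], c(S1 = 0.2, S2 = 0.4))

  # single sample: identity
  m1 <- union_positions(per["S1"], toy_samples(1L))
  expect_equal(nrow(m1$values), 1L)
  expect_equal(unname(m1$values[1, 1]), 0.2)

  # disjoint positions in k samples: k rows with k-1 missing each
  k <- 4L
  per_k <- lapply(seq_len(k), function(i) {
    make_records(i * 100L, 0.5)
  })
  names(per_k) <- paste0("S", seq_len(k))
  mk <- union_positions(per_k, toy_samples(k))
  expect_equal(nrow(mk$values), k)
  expect_equal(unname(rowSums(is.na(mk$values))), rep(k - 1, k))

  # property: row count equals |union of position sets|
  for (seed in 1:5) {
    set.seed(seed)
    per_r <- lapply(1:3, function(i) {
      st <- sort(sample(seq(10L, 500L, by = 10L), 20L))
      make_records(st, runif(20))
    })
    names(per_r) <- paste0("S", 1:3)
    mu <- union_positions(per_r, toy_samples(3L))
    expect_equal(nrow(mu$values),
                 length(unique(unlist(lapply(per_r, `[[`, "start")))))
  }
})

test_that("union matrix agrees with bedtools unionbedg on the same input", {
  dir <- withr::local_tempdir()
  set.seed(11)
  per <- lapply(1:3, function(i) {
    st <- sort(sample(seq(0L, 300L, by = 10L), 12L))
    make_records(st, round(runif(12), 3))
  })
  names(per) <- paste0("S", 1:3)
  files <- vapply(names(per), function(s) {
    f <- file.path(dir, paste0(s, ".bg"))
    writeLines(sprintf("%s\t%d\t%d\t%g", per[[s]]$chrom, per[[s]]$start,
                       per[[s]]$end, per[[s]]$value), f)
    f
  }, "")
  out <- system2("bedtools", c("unionbedg", "-filler", "NA", "-i", files),
                 stdout = TRUE)
  bt <- read.table(text = out, sep = "\t", na.strings = "NA")
  m <- union_positions(per, toy_samples(3L))
  expect_equal(nrow(m$values), nrow(bt))
  expect_equal(m$positions$start, bt$V2)
  expect_equal(unname(m$values), unname(as.matrix(bt[, 4:6])))
})

test_that("DMP restriction keeps the union across comparisons", {
  m <- toy_matrix(rbind(0.1, 0.2), starts = c(10L, 20L))
  dmps <- region_set("c1", 20L, 21L, "AB")
  r <- restrict_to_dmps(m, dmps)
  expect_equal(nrow(r$values), 1L)
  expect_equal(r$positions$start, 20L)

  both <- region_set(c("c1", "c1"), c(10L, 20L), c(11L, 21L),
                     c("AB", "AC"))
  expect_equal(nrow(restrict_to_dmps(m, both)$values), 2L)

  off <- region_set("c1", 50L, 51L, "AB")
  expect_warning(r0 <- restrict_to_dmps(m, off), "no matrix position")
  expect_equal(nrow(r0$values), 0L)
})

test_that("union-DMR construction honours the supporting fraction", {
  # three comparisons, middle covered by two of three: kept at X = 0.5,
  # dropped at X = 1
  dmrs <- region_set(c("c1", "c1", "c1"), c(100L, 150L, 700L),
                     c(300L, 400L, 900L), c("AB", "AC", "BC"))
  u <- build_union_dmrs(dmrs, min_fraction = 0.5)
  expect_equal(u$start, 150L)
  expect_equal(u$end, 300L)
  expect_equal(nrow(build_union_dmrs(dmrs, min_fraction = 1)), 0L)

  # AB/AC intervals with a declared third (empty) comparison BC: only the
  # doubly covered elementary interval reaches 2/3 support at X = 0.5
  d2 <- region_set(c("c1", "c1"), c(100L, 200L), c(300L, 400L),
                   c("AB", "AC"))
  attr(d2, "comparisons") <- c("AB", "AC", "BC")
  u2 <- build_union_dmrs(d2, min_fraction = 0.5, merge = FALSE)
  expect_equal(u2$start, 200L)
  expect_equal(u2$end, 300L)

  # single comparison returned unchanged
  d1 <- region_set("c1", c(10L, 50L), c(20L, 60L), "AB")
  attr(d1, "comparisons") <- "AB"
  expect_identical(build_union_dmrs(d1, 0.5), d1)

  expect_error(build_union_dmrs(dmrs, 0), "min_fraction")
  expect_error(build_union_dmrs(dmrs, 1.2), "min_fraction")
})

test_that("union-DMRs equal the per-base brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n_comp <- sample(2:4, 1)
    labels <- LETTERS[seq_len(n_comp)]
    parts <- lapply(labels, function(lab) {
      k <- sample(1:4, 1)
      st <- sort(sample(seq(0L, 900L, by = 10L), k))
      wd <- sample(seq(20L, 200L, by = 10L), k, replace = TRUE)
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        "c1", IRanges::IRanges(st + 1L, st + wd)))
      data.frame(chrom = "c1", start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr), label = lab)
    })
    df <- do.call(rbind, parts)
    dmrs <- region_set(df$chrom, df$start, df$end, df$label)
    attr(dmrs, "comparisons") <- labels
    x <- runif(1, 0.2, 1)
    for (merge in c(TRUE, FALSE)) {
      got <- build_union_dmrs(dmrs, x, merge = merge)
      want <- udmr_oracle(dmrs, x, merge = merge)
      expect_equal(got$start, want$start,
                   info = sprintf("seed %d merge %s", seed, merge))
      expect_equal(got$end, want$end,
                   info = sprintf("seed %d merge %s", seed, merge))
    }
  }
})

test_that("union-DMR limits: X -> 0+ gives the union, X = 1 the intersection", {
  dmrs <- region_set(c("c1", "c1"), c(100L, 200L), c(300L, 400L),
                     c("AB", "AC"))
  full <- build_union_dmrs(dmrs, min_fraction = 1e-9)
  expect_equal(full$start, 100L); expect_equal(full$end, 400L)
  inter <- build_union_dmrs(dmrs, min_fraction = 1)
  expect_equal(inter$start, 200L); expect_equal(inter$end, 300L)
})

test_that("region averaging uses the non-missing mean per sample", {
  m <- toy_matrix(rbind(c(0.2, 0.2, NA),
                        c(0.4, NA, NA),
                        c(0.9, 0.9, 0.9)),
                  starts = c(100L, 150L, 500L))
  regions <- region_set(c("c1", "c1", "c1"), c(90L, 480L, 600L),
                        c(200L, 520L, 700L), "uDMR")
  expect_message(a <- average_over_regions(m, regions), "1 region")
  expect_equal(nrow(a$values), 2L)
  expect_equal(unname(a$values[1, ]), c(0.3, 0.2, NA))  # mean, partial, all-NA
  expect_equal(rownames(a$values)[1], "c1:90-200")

  # invariant to position and sample order
  perm <- c(3L, 1L, 2L)
  m2 <- methylation_matrix(m$positions[perm, ], m$samples,
                           m$values[perm, ])
  a2 <- suppressMessages(average_over_regions(m2, regions))
  expect_equal(a2$values, a$values)

  expect_error(average_over_regions(m,
    region_set(c("c1", "c1"), c(90L, 100L), c(200L, 300L), "u")),
    "non-overlapping")
})

test_that("region restriction never double-counts nested/abutting regions", {
  m <- toy_matrix(matrix(runif(15), 5), starts = c(100L, 150L, 200L,
                                                   250L, 300L))
  nested <- region_set(c("c1", "c1", "c1"), c(90L, 140L, 210L),
                       c(260L, 220L, 320L), c("A", "B", "C"))
  r <- restrict_to_regions(m, nested)
  expect_equal(r$positions$start, c(100L, 150L, 200L, 250L, 300L))
  expect_equal(nrow(r$values), 5L)

  empty <- nested[0, , drop = FALSE]
  expect_equal(nrow(restrict_to_regions(m, empty)$values), 0L) |>
    suppressWarnings()
})

test_that("variation filter applies SD and range thresholds", {
  m <- toy_matrix(rbind(c(0.5, 0.5, 0.5),
                        c(0.2, 0.4, 0.6),
                        c(0.50, 0.52, 0.55),
                        c(0.1, NA, NA)))
  # constant row removed under any positive threshold
  expect_equal(nrow(filter_by_variation(m, min_sd = 1e-6)$values), 2L)
  # range filter: 0.4 >= 0.10 kept, 0.05 dropped
  fr <- filter_by_variation(m, min_range = 0.10)
  expect_equal(fr$positions$start, 200L)
  # the published CG setting: SD >= 0.028
  fs <- filter_by_variation(m, min_sd = 0.028)
  expect_true("c1:200-201" %in% rownames(fs$values))
  expect_false("c1:300-301" %in% rownames(fs$values))
  # row with < 2 non-missing values dropped when a threshold is set
  expect_false("c1:400-401" %in% rownames(fs$values))
  # no thresholds: identity
  expect_identical(filter_by_variation(m), m)
})
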