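test_that("binning conserves totals and matches hand placement", {
  g <- ref_genome(c(chrI = strrep("ACGT", 1000)))  # 4 kb
  pos <- data.frame(chrom = "chrI", pos = c(100, 900, 1100))
  bc <- bin_reads(pos, g, 1000)
  expect_equal(bc$count, c(2L, 1L, 0L, 0L))
  expect_equal(attr(bc, "total"), 3L)
  expect_equal(bc$end[4], 4000)
  expect_error(bin_reads(data.frame(chrom = "chrI", pos = 4000), g, 1000),
               "beyond chromosome end")
  expect_error(bin_reads(data.frame(chrom = "chrX", pos = 1), g, 1000),
               "absent")
  # short terminal bin
  g2 <- ref_genome(c(chrI = strrep("A", 2500)))
  part <- bin_genome(g2, 1000)
  expect_equal(part$end, c(1000, 2000, 2500))

  set.seed(91)
  n <- 20000
  u <- bin_reads(data.frame(chrom = "chrI",
                            pos = sample(0:3999, n, TRUE)), g, 1000)
  expect_equal(attr(u, "total"), n)
  # uniform reads: chi-square over the 4 equal bins behaves multinomially
  chi <- sum((u$count - n / 4)^2 / (n / 4))
  expect_lt(chi, qchisq(0.999, df = 3))
})

test_that("fold enrichment arithmetic and control-zero handling", {
  expect_equal(fold_enrichment(40, 1000, 10, 1000), 4)
  expect_equal(fold_enrichment(25, 500, 25, 500), 1)
  # c = 0: finite and strictly increasing in s
  folds <- fold_enrichment(c(1, 5, 50), 1000, 0, 1000)
  expect_true(all(is.finite(folds)))
  expect_true(all(diff(folds) > 0))
  # the pseudocount leaves nonzero control bins untouched
  expect_equal(fold_enrichment(40, 1000, 10, 1000, pseudocount = 5),
               fold_enrichment(40, 1000, 10, 1000, pseudocount = 0.5))
})

test_that("two-tailed binomial p matches exhaustive enumeration", {
  # s = 0, S = 10, p0 = 0.5: outcomes {0, 10} are minimal-likelihood
  expect_equal(binomial_pvalue_two_tailed(0, 10, 0.5), 2 / 1024,
               tolerance = 1e-12)
  # observing the mode gives p = 1
  expect_equal(binomial_pvalue_two_tailed(5, 10, 0.5), 1)
  expect_equal(binomial_pvalue_two_tailed(2, 7, 3 / 8), 1)

  set.seed(92)
  for (i in 1:200) {
    S <- sample(1:500, 1)
    s <- sample(0:S, 1)
    p0 <- runif(1)
    p <- binomial_pvalue_two_tailed(s, S, p0)
    expect_equal(p, oracle_binom_p(s, S, p0), tolerance = 1e-9)
    expect_equal(p, binom.test(s, S, p0)$p.value, tolerance = 1e-9)
  }
  # large-count path agrees with stats::binom.test too
  expect_equal(binomial_pvalue_two_tailed(150, 100000, 0.001),
               binom.test(150, 100000, 0.001)$p.value, tolerance = 1e-9)
})

test_that("robust fold lower bound is conservative and consistent", {
  expect_equal(robust_fold_lower(0, 1000, 10, 1000), 0)
  point <- fold_enrichment(1000, 10000, 10, 10000)
  lower <- robust_fold_lower(1000, 10000, 10, 10000)
  expect_lt(lower, point)
  expect_gt(lower, 0)
  set.seed(93)
  for (i in 1:50) {
    S <- sample(100:5000, 1)
    C <- sample(100:5000, 1)
    s <- sample(0:S, 1)
    c <- sample(0:C, 1)
    expect_lte(robust_fold_lower(s, S, c, C),
               fold_enrichment(s, S, c, C) + 1e-12)
  }
  # converges to the point fold as counts scale at fixed proportions
  errs <- vapply(c(1, 10, 100), function(scale) {
    abs(robust_fold_lower(40 * scale, 1000 * scale, 10 * scale,
                          1000 * scale) - 4)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("call_enriched finds exactly the planted bin under Bonferroni", {
  g <- ref_genome(c(chrI = strrep("A", 100000)))  # 100 bins of 1 kb
  part <- bin_genome(g, 1000)
  sample <- binned_counts(part, c(rep(99L, 42), 200L, rep(99L, 57)), 1000)
  control <- binned_counts(part, c(rep(101L, 42), 10L, rep(101L, 57)), 1000)
  res <- call_enriched(sample, control, min_fold = 4,
                       policy = correction_policy("bonferroni_bins",
                                                  alpha = 0.05))
  expect_equal(sum(res$significant), 1)
  hit <- res[res$significant, ]
  expect_equal(hit$start, 42000)
  expect_lt(hit$p, 0.05 / 100)
  expect_gt(hit$robust_fold_lower, 4)

  # identical counts: no calls under any policy
  same <- call_enriched(sample, sample, min_fold = 4)
  expect_equal(sum(same$significant), 0)
  expect_true(all(abs(same$fold[same$tested] - 1) < 1e-12))

  # per-gene policy reproduces the 0.05 / (2 * n_genes) threshold
  pg <- correction_policy("per_gene", n_genes = 250)
  expect_equal(pg$alpha, 0.05 / 500)
  res_pg <- call_enriched(sample, control, min_fold = 2, policy = pg)
  expect_equal(attr(res_pg, "threshold"), 1e-04)
  expect_true(res_pg[res_pg$start == 42000, ]$significant)
  expect_error(correction_policy("per_gene"), "n_genes")

  # mismatched partitions refuse to compare
  g2 <- ref_genome(c(chrI = strrep("A", 50000)))
  other <- binned_counts(bin_genome(g2, 1000), rep(1L, 50), 1000)
  expect_error(call_enriched(sample, other), "different partitions")
})

test_that("calls are invariant under chromosome relabeling order", {
  set.seed(94)
  g_ab <- ref_genome(c(a = strrep("A", 20000), b = strrep("C", 20000)))
  g_ba <- ref_genome(c(b = strrep("C", 20000), a = strrep("A", 20000)))
  pos <- data.frame(chrom = sample(c("a", "b"), 5000, TRUE),
                    pos = sample(0:19999, 5000, TRUE))
  pos_s <- pos
  take <- pos_s$chrom == "a" & pos_s$pos < 1000
  pos_s <- rbind(pos_s, pos_s[take, ], pos_s[take, ], pos_s[take, ],
                 pos_s[take, ], pos_s[take, ], pos_s[take, ], pos_s[take, ])
  res1 <- call_enriched(bin_reads(pos_s, g_ab, 1000),
                        bin_reads(pos, g_ab, 1000))
  res2 <- call_enriched(bin_reads(pos_s, g_ba, 1000),
                        bin_reads(pos, g_ba, 1000))
  expect_equal(as.data.frame(res1), as.data.frame(res2))
})

test_that("mitochondrial internal control and replicate correlation", {
  g <- ref_genome(c(chrI = strrep("A", 10000), chrM = strrep("C", 2000)))
  set.seed(95)
  ctrl_pos <- data.frame(chrom = sample(c("chrI", "chrM"), 6000, TRUE,
                                        prob = c(10000, 2000)),
                         pos = NA)
  ctrl_pos$pos <- ifelse(ctrl_pos$chrom == "chrI",
                         sample(0:9999, 6000, TRUE),
                         sample(0:1999, 6000, TRUE))
  enr_pos <- data.frame(chrom = sample(c("chrI", "chrM"), 6000, TRUE,
                                       prob = c(1, 3)),
                        pos = NA)
  enr_pos$pos <- ifelse(enr_pos$chrom == "chrI",
                        sample(0:9999, 6000, TRUE),
                        sample(0:1999, 6000, TRUE))
  sc <- bin_reads(ctrl_pos, g, 1000)
  se <- bin_reads(enr_pos, g, 1000)
  expect_gt(mito_control_enrichment(se, sc, "chrM"), 3)
  expect_equal(mito_control_enrichment(se, se, "chrM"), 1)
  expect_error(mito_control_enrichment(se, sc, "chrMT"), "not in the partition")

  expect_equal(replicate_log_coverage_correlation(se, se), 1)
  # independent low-mean Poisson tracks decorrelate
  gg <- ref_genome(c(chrI = strrep("A", 1000000)))
  part <- bin_genome(gg, 100)  # 10,000 bins
  a <- binned_counts(part, rpois(10000, 2), 100)
  b <- binned_counts(part, rpois(10000, 2), 100)
  expect_lt(abs(replicate_log_coverage_correlation(a, b)), 0.1)
  tiny <- binned_counts(bin_genome(ref_genome(c(x = strrep("A", 150))), 100),
                        c(1L, 1L), 100)
  expect_error(replicate_log_coverage_correlation(tiny, tiny), "fewer than 3")
})

test_that("enrichment BED round-trips calls with their statistics", {
  g <- ref_genome(c(chrI = strrep("A", 5000)))
  part <- bin_genome(g, 1000)
  sample <- binned_counts(part, c(300L, 10L, 10L, 10L, 10L), 1000)
  control <- binned_counts(part, c(20L, 80L, 80L, 80L, 80L), 1000)
  res <- call_enriched(sample, control)
  expect_equal(sum(res$significant), 1)
  path <- withr::local_tempfile(fileext = ".bed")
  write_enrichment_bed(res, path)
  back <- read.table(path, sep = "\t",
                     col.names = c("chrom", "start", "end", "name", "score",
                                   "strand", "p", "significant"))
  expect_equal(nrow(back), 1)
  expect_equal(back$start, 0)
  expect_equal(back$score, res$fold[1], tolerance = 1e-6)
  expect_equal(back$significant, 1)
  # empty call set still yields a valid (empty) file
  none <- call_enriched(sample, sample)
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_enrichment_bed(none, path2)
  expect_equal(length(readLines(path2)), 0)
})
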