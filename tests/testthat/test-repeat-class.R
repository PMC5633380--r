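test_that("k-mer index enumerates every position under canonical form", {
  g <- ref_genome(c(chr = "ACGTACGT"))
  idx <- build_kmer_index(g, 4)
  expect_equal(nrow(idx$table), 5)
  acgt <- idx$table[idx$table$kmer == "ACGT", ]
  expect_equal(acgt$pos, c(0L, 4L))

  # k equal to chromosome length: one entry per chromosome
  g2 <- ref_genome(c(a = "ACGTAC", b = "GGGTTT"))
  idx2 <- build_kmer_index(g2, 6)
  expect_equal(nrow(idx2$table), 2)

  # N-containing k-mers are skipped
  g3 <- ref_genome(c(a = "ACGTNACGT"))
  idx3 <- build_kmer_index(g3, 4)
  expect_equal(nrow(idx3$table), 2)  # only the two N-free windows
  expect_equal(idx3$n_skipped, 4)

  expect_error(build_kmer_index(g2, 10), "exceeds")
})

test_that("index contents equal a brute-force canonical dictionary", {
  set.seed(81)
  g <- ref_genome(c(chrI = random_dna(4000), chrII = random_dna(2000)))
  k <- 8  # short enough that repeated k-mers arise by chance
  idx <- build_kmer_index(g, k)
  brute <- list()
  for (chrom in names(unclass(g))) {
    s <- unclass(g)[[chrom]]
    for (i in seq_len(nchar(s) - k + 1)) {
      kmer <- substr(s, i, i + k - 1)
      rc <- oracle_revcomp(kmer)
      canon <- min(kmer, rc)
      brute[[length(brute) + 1]] <- data.frame(
        kmer = canon, chrom = chrom, pos = i - 1L,
        strand = if (kmer <= rc) "+" else "-")
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$kmer, brute$chrom, brute$pos), ]
  rownames(brute) <- NULL
  expect_equal(as.data.frame(idx$table), brute)
})

test_that("locate_read equals exact mapping for planted and random reads", {
  set.seed(82)
  arch <- genome_architecture(
    chrom_lengths = c(chrI = 15000L, chrII = 15000L), mito = NULL,
    focal = list(list(unit_len = 150L, copies = 5L, span = 2500L,
                      chrom = NULL)),
    dispersed = list(list(unit_len = 120L, copies_per_chrom = 1L)),
    intra = list(), focal_range = 4000L, seed = 82L)
  ref <- simulate_reference(arch)
  idx <- build_kmer_index(ref$genome, 31)
  seqs <- unclass(ref$genome)
  tr <- ref$truth$placements

  # planted unique 100-mer
  u <- substr(seqs[["chrI"]], 9001, 9100)
  expect_equal(nrow(locate_read(u, idx)), 1)
  # a read inside the focal unit occurs at all five copies, one chromosome
  f <- tr[tr$type == "focal"]
  fr <- substr(seqs[[f$chrom[1]]], f$start[1] + 11, f$start[1] + 90)
  pl <- locate_read(fr, idx)
  expect_equal(nrow(pl), 5)
  expect_equal(unique(pl$chrom), f$chrom[1])
  # oracle equivalence over planted, reverse-complemented and random reads
  reads <- c(u, fr, reverse_complement(fr), random_reads(5, 40))
  for (read in reads) {
    expect_equal(locate_read(read, idx), map_exact(read, ref$genome))
  }
  expect_error(locate_read("ACGT", idx), "shorter than k")
})

test_that("batch classification equals the per-read locate/classify chain", {
  set.seed(86)
  arch <- genome_architecture(
    chrom_lengths = c(chrI = 12000L, chrII = 12000L), mito = NULL,
    focal = list(list(unit_len = 150L, copies = 4L, span = 2000L,
                      chrom = NULL)),
    dispersed = list(list(unit_len = 120L, copies_per_chrom = 1L)),
    intra = list(list(unit_len = 130L, separation = 6000L, chrom = "chrII")),
    focal_range = 4000L, seed = 86L)
  ref <- simulate_reference(arch)
  idx <- build_kmer_index(ref$genome, 31)
  seqs <- unclass(ref$genome)
  tr <- ref$truth$placements
  reads <- c(
    vapply(seq_len(nrow(tr)), function(i) {
      substr(seqs[[tr$chrom[i]]], tr$start[i] + 6, tr$start[i] + 85)
    }, ""),
    vapply(1:20, function(i) {
      chrom <- sample(names(seqs), 1)
      at <- sample(nchar(seqs[[chrom]]) - 60, 1)
      s <- substr(seqs[[chrom]], at, at + 59)
      if (i %% 2) reverse_complement(s) else s
    }, ""),
    random_reads(5, 50))
  batch <- classify_reads(reads, idx, focal_range = 4000)
  for (i in seq_along(reads)) {
    pl <- locate_read(reads[[i]], idx)
    cl <- classify_placements(pl, 4000)
    expect_identical(batch$category[i], cl$category)
    expect_identical(batch$n_placements[i], cl$n_placements)
    if (cl$category %in% c("FOCAL_REPEAT", "INTRACHROMOSOMAL_REPEAT")) {
      expect_identical(batch$span[i], cl$span)
    }
  }
})

test_that("placement sets classify by the focal span rule", {
  mk <- function(chrom, pos) data.frame(chrom = chrom, pos = pos,
                                        strand = rep("+", length(chrom)))
  expect_equal(classify_placements(mk("chrI", 1000))$category, "UNIQUE")
  cl <- classify_placements(mk("chrI", c(1000, 200000)))
  expect_equal(cl$category, "FOCAL_REPEAT")
  expect_equal(cl$span, 199000)
  expect_equal(classify_placements(mk("chrI", c(0, 500000)))$category,
               "INTRACHROMOSOMAL_REPEAT")
  expect_equal(classify_placements(mk(c("chrI", "chrII"), c(0, 0)))$category,
               "DISPERSED_REPEAT")
  expect_equal(classify_placements(mk(character(0), integer(0)))$category,
               "UNPLACEABLE")
  # a span exactly at the cutoff is still focal
  expect_equal(classify_placements(mk("chrI", c(0, 300000)))$category,
               "FOCAL_REPEAT")
})

test_that("growing the focal range only converts intrachromosomal to focal", {
  set.seed(83)
  for (i in 1:200) {
    n <- sample(0:5, 1)
    pl <- data.frame(chrom = sample(c("chrI", "chrII"), n, TRUE),
                     pos = sample(0:600000, n), strand = rep("+", n))
    pl <- unique(pl)
    small <- classify_placements(pl, focal_range = 100000)$category
    large <- classify_placements(pl, focal_range = 400000)$category
    if (small != large) {
      expect_equal(small, "INTRACHROMOSOMAL_REPEAT")
      expect_equal(large, "FOCAL_REPEAT")
    }
  }
})

test_that("class composition sums to one and tracks construction", {
  expect_equal(unname(class_composition(rep("UNIQUE", 10))),
               c(1, 0, 0, 0, 0))
  set.seed(84)
  cats <- sample(c(rep("UNIQUE", 5000), rep("DISPERSED_REPEAT", 5000)))
  comp <- class_composition(cats)
  expect_equal(sum(comp), 1)
  expect_equal(comp[["UNIQUE"]], 0.5)
  expect_equal(comp[["DISPERSED_REPEAT"]], 0.5)
  expect_equal(class_composition(rev(cats)), comp)
  expect_error(class_composition(character(0)), "undefined")
  expect_error(class_composition("WEIRD"), "unknown")
})

test_that("pair category takes the more repetitive mate", {
  expect_equal(pair_category("UNIQUE", "FOCAL_REPEAT"), "FOCAL_REPEAT")
  expect_equal(pair_category("DISPERSED_REPEAT", "UNIQUE"),
               "DISPERSED_REPEAT")
  expect_equal(pair_category("UNIQUE", "UNPLACEABLE"), "UNPLACEABLE")
  expect_equal(pair_category(c("UNIQUE", "FOCAL_REPEAT"),
                             c("INTRACHROMOSOMAL_REPEAT", "UNIQUE")),
               c("INTRACHROMOSOMAL_REPEAT", "FOCAL_REPEAT"))
})

test_that("coverage tracks place unique reads and focal midpoints", {
  set.seed(85)
  g <- ref_genome(c(chrI = random_dna(10000)))
  cl <- data.table::data.table(
    id = c("u1", "f1", "d1"),
    category = c("UNIQUE", "FOCAL_REPEAT", "DISPERSED_REPEAT"),
    n_placements = c(1L, 3L, 2L), span = c(NA, 2000L, NA),
    chrom = c("chrI", "chrI", NA), pos = c(1500L, 3000L, NA))
  cov <- coverage_by_class(cl, g, 1000)
  u <- cov[cov$category == "UNIQUE" & cov$start == 1000, ]
  expect_equal(u$count, 1)
  expect_equal(sum(cov$count), 2)  # dispersed reads excluded from tracks

  # end-to-end: a planted focal family's reads land inside the family span
  arch <- genome_architecture(
    chrom_lengths = c(chrI = 12000L), mito = NULL,
    focal = list(list(unit_len = 150L, copies = 4L, span = 2000L,
                      chrom = NULL)),
    dispersed = list(), intra = list(), focal_range = 3000L, seed = 85L)
  ref <- simulate_reference(arch)
  idx <- build_kmer_index(ref$genome, 31)
  tr <- ref$truth$placements
  reads <- vapply(seq_len(nrow(tr)), function(i) {
    substr(unclass(ref$genome)[[tr$chrom[i]]], tr$start[i] + 21,
           tr$start[i] + 100)
  }, "")
  cls <- classify_reads(reads, idx, focal_range = 3000)
  expect_true(all(cls$category == "FOCAL_REPEAT"))
  expect_true(all(cls$pos >= min(tr$start) & cls$pos <= max(tr$end)))
  cov2 <- coverage_by_class(cls, ref$genome, 1000)
  expect_equal(sum(cov2$count), nrow(tr))
})

test_that("bedgraph export drops zero bins and round-trips totals", {
  g <- ref_genome(c(chrI = strrep("ACGT", 1000)))
  pos <- data.frame(chrom = "chrI", pos = c(100, 900, 1100))
  bc <- bin_reads(pos, g, 1000)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(bc, path)
  back <- read.table(path, sep = "\t")
  expect_equal(nrow(back), 2)
  expect_equal(sum(back$V4), 3)
})
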