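test_that("overlap_fraction returns the fraction of the first interval", {
  a <- genomic_intervals("chr1", 100, 200)
  b <- genomic_intervals("chr1", 150, 300)
  expect_equal(overlap_fraction(a, b), 0.5)   # exactly half: excluded by > 50%
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(genomic_intervals("chr1", 0, 10),
                                genomic_intervals("chr1", 20, 30)), 0)
  expect_equal(overlap_fraction(genomic_intervals("chr1", 0, 10),
                                genomic_intervals("chr2", 0, 10)), 0)
})

test_that("overlap length is symmetric even when fractions are not", {
  set.seed(42)
  for (i in 1:50) {
    s1 <- sample(0:500, 1); s2 <- sample(0:500, 1)
    a <- genomic_intervals("chr1", s1, s1 + sample(1:300, 1))
    b <- genomic_intervals("chr1", s2, s2 + sample(1:300, 1))
    expect_equal(overlap_fraction(a, b) * (a$end - a$start),
                 overlap_fraction(b, a) * (b$end - b$start))
  }
})

test_that("malformed intervals are rejected", {
  expect_error(genomic_intervals("chr1", 200, 100), "invalid interval")
  expect_error(genomic_intervals("chr1", -5, 10), "invalid interval")
  expect_error(validate_intervals(genomic_intervals("chr1", 0, 2000),
                                  genome_table("chr1", 1000)),
               "beyond chromosome end")
})

test_that("derive_features reproduces the hand-computed partition", {
  g <- gene_models("g1", "chr1", "+",
                   exon_starts = list(c(100L, 300L)),
                   exon_ends = list(c(200L, 500L)),
                   cds_start = 150L, cds_end = 450L)
  f <- derive_features(g, toy_genome(), tss_flank = 100, stop_flank = 200)
  expect_equal(f$intron[, c("start", "end")],
               data.frame(start = 200L, end = 300L))
  # stop codon = last 3 coding bases [447, 450); window +/- 200
  expect_equal(f$stop_codon$start, 447L - 200L)
  expect_equal(f$stop_codon$end, 450L + 200L)
  expect_equal(f$stop_codon$end - f$stop_codon$start, 403L)
  # UTR5 = exonic bases before cds_start; UTR3 after cds_end
  expect_equal(f$UTR5[, c("start", "end")],
               data.frame(start = 100L, end = 150L))
  expect_equal(f$UTR3[, c("start", "end")],
               data.frame(start = 450L, end = 500L))
  expect_equal(f$CDS[, c("start", "end")],
               data.frame(start = c(150L, 300L), end = c(200L, 450L)))
  expect_equal(f$TSS[, c("start", "end")], data.frame(start = 0L, end = 200L))
})

test_that("minus-strand genes flip TSS, stop codon and UTR assignment", {
  g <- toy_gene("-")
  f <- derive_features(g, toy_genome(), tss_flank = 100, stop_flank = 0)
  expect_equal(f$TSS[, c("start", "end")],
               data.frame(start = 400L, end = 600L))
  expect_equal(f$stop_codon[, c("start", "end")],
               data.frame(start = 150L, end = 153L))
  expect_equal(f$UTR3[, c("start", "end")],
               data.frame(start = 100L, end = 150L))
  expect_equal(f$UTR5[, c("start", "end")],
               data.frame(start = 450L, end = 500L))
})

test_that("zero genes give an all-intergenic genome", {
  g <- toy_gene()[0, ]
  f <- derive_features(g, toy_genome())
  expect_equal(nrow(f$intergenic), 1L)
  expect_equal(f$intergenic$start, 0L)
  expect_equal(f$intergenic$end, 10000L)
  for (cl in c("TSS", "UTR5", "CDS", "stop_codon", "UTR3", "intron"))
    expect_equal(nrow(f[[cl]]), 0L)
})

test_that("UTR5/CDS/UTR3 exactly partition exonic coding bases", {
  sim <- default_sim()
  f <- derive_features(sim$genes, sim$genome)
  bp <- function(df) sum(df$end - df$start)
  ex <- gene_exons(sim$genes)
  expect_equal(bp(f$UTR5) + bp(f$CDS) + bp(f$UTR3), bp(ex))
  # no pairwise overlap within the trio
  expect_equal(sum(m6adyn:::.overlap_bp_with_set(f$UTR5, f$CDS)), 0)
  expect_equal(sum(m6adyn:::.overlap_bp_with_set(f$UTR5, f$UTR3)), 0)
  expect_equal(sum(m6adyn:::.overlap_bp_with_set(f$CDS, f$UTR3)), 0)
})

test_that("CDS outside the exonic span is an annotation error", {
  expect_error(gene_models("bad", "chr1", "+",
                           exon_starts = list(c(100L)),
                           exon_ends = list(c(200L)),
                           cds_start = 50L, cds_end = 180L),
               "annotation inconsistency")
})

test_that("shuffling preserves per-chrom lengths and is seed-reproducible", {
  sim <- default_sim()
  pk <- sim$truth$peaks[sim$truth$peaks$condition == "2CLC",
                        c("chrom", "start", "end", "strand")]
  d1 <- shuffle_intervals(pk, sim$genome, seed = 5, n_draws = 3)
  d2 <- shuffle_intervals(pk, sim$genome, seed = 5, n_draws = 3)
  expect_identical(d1, d2)
  for (d in d1) {
    expect_identical(d$chrom, pk$chrom)
    expect_identical(d$end - d$start, pk$end - pk$start)
    expect_identical(d$strand, pk$strand)
    validate_intervals(d, sim$genome)
  }
})

test_that("a peak as long as its chromosome has a single placement", {
  pk <- genomic_intervals("chr1", 0, 500)
  g <- genome_table("chr1", 500)
  d <- shuffle_intervals(pk, g, seed = 1, n_draws = 5)
  for (x in d) expect_equal(x$start, 0L)
  expect_error(shuffle_intervals(genomic_intervals("chr1", 0, 600,
                                                   strand = "."),
                                 genome_table("chr1", 500), seed = 1),
               "beyond chromosome end")
})

test_that("shuffled starts are uniform over valid placements", {
  pk <- genomic_intervals("chr1", 0, 100)
  g <- genome_table("chr1", 1e5)
  d <- shuffle_intervals(pk, g, seed = 7, n_draws = 10000)
  starts <- vapply(d, function(x) x$start, numeric(1))
  expect_lt(abs(mean(starts) - (1e5 - 100) / 2) / ((1e5 - 100) / 2), 0.01)
})
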