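test_that("gene m6A status follows the > 50%-of-peak rule over exons + stop window", {
  g <- toy_gene()                       # exons [100,200)+[300,500), CDS end 450
  expect_false(any(gene_m6a_status(genomic_intervals(character(0),
                                                     integer(0), integer(0)),
                                   g)$status))
  inside <- genomic_intervals("chr1", 320, 420)
  st <- gene_m6a_status(inside, g)
  expect_true(st$status)
  expect_equal(st$n_peaks, 1L)
  # peak mostly in the intron does not count (stop window disabled so the
  # gene region is the exons alone)
  intronic <- genomic_intervals("chr1", 190, 290)   # 10/100 exonic
  expect_false(gene_m6a_status(intronic, g, stop_flank = 0)$status)
  # stop-codon window rescues a peak hanging off the 3' end
  tail_pk <- genomic_intervals("chr1", 480, 600)    # inside stop +/- 200
  expect_true(gene_m6a_status(tail_pk, g, stop_flank = 200)$status)
  expect_false(gene_m6a_status(tail_pk, g, stop_flank = 0)$status)
})

test_that("status from called peaks matches ground truth when the caller performs", {
  accs <- recs <- numeric(0)
  for (s in 31:34) {
    sim <- simulate_annotation(sim_config(seed = s))
    ip <- simulate_coverage(sim, "2CLC", "IP")
    inp <- simulate_coverage(sim, "2CLC", "input")
    pk <- call_peaks(ip, inp)
    st <- gene_m6a_status(pk, sim$genes, condition = "2CLC")
    accs <- c(accs, mean(st$status == sim$truth$gene$m6a_2CLC))
    recs <- c(recs, peak_benchmark(
      pk, sim$truth$peaks[sim$truth$peaks$condition == "2CLC", ])$recall)
  }
  expect_gte(mean(recs), 0.9)
  expect_gte(mean(accs), 0.95)
})

test_that("intensity is zero for identical tracks and matches arithmetic", {
  g <- toy_gene()
  counts <- list(chr1 = rep(5, 200))
  a <- coverage_track(counts, 50, label = "IP")
  b <- coverage_track(counts, 50, label = "input")
  expect_equal(m6a_intensity(a, b, g)$intensity, 0)
  # IP RPM 15 vs input RPM 3 over the region -> log2(16/4) = 2
  ipc <- list(chr1 = rep(0, 200)); inc <- list(chr1 = rep(0, 200))
  # stop200 region for the + gene: [247, 650); bins 5..12 (0-based 4..12)
  ipc$chr1[6:13] <- 100; inc$chr1[6:13] <- 100
  ip <- coverage_track(ipc, 50, label = "IP",
                       library_size = sum(ipc$chr1) * 1e6 / 15)
  inp <- coverage_track(inc, 50, label = "input",
                        library_size = sum(inc$chr1) * 1e6 / 3)
  got <- m6a_intensity(ip, inp, g)$intensity
  expect_equal(got, 2, tolerance = 1e-6)
})

test_that("intensity is invariant under equal sequencing-depth scaling", {
  sim <- default_sim()
  ip <- simulate_coverage(sim, "2CLC", "IP")
  inp <- simulate_coverage(sim, "2CLC", "input")
  i1 <- m6a_intensity(ip, inp, sim$genes)
  # tripling depth: counts and library sizes scale together, RPM unchanged
  ip3 <- coverage_track(lapply(ip$counts, `*`, 3), ip$bin_size, "IP")
  inp3 <- coverage_track(lapply(inp$counts, `*`, 3), inp$bin_size, "input")
  i2 <- m6a_intensity(ip3, inp3, sim$genes)
  expect_equal(i1$intensity, i2$intensity)
})

test_that("m6A+ genes show higher intensity than m6A- genes on simulation", {
  sim <- default_sim()
  ip <- simulate_coverage(sim, "2CLC", "IP")
  inp <- simulate_coverage(sim, "2CLC", "input")
  iv <- m6a_intensity(ip, inp, sim$genes)
  truth <- sim$truth$gene
  a <- iv$intensity[truth$m6a_2CLC]; b <- iv$intensity[!truth$m6a_2CLC]
  expect_lt(wilcoxon_rank_sum(a, b)$p_value, 0.01)
  expect_gt(mean(a), mean(b))
})

test_that("metagene profile is flat on uniform coverage and localises a spike", {
  feat <- genomic_intervals("chr1", 1000, 3000)
  flat <- coverage_track(list(chr1 = rep(10, 200)), 50, label = "IP")
  flat_in <- coverage_track(list(chr1 = rep(10, 200)), 50, label = "input")
  prof <- metagene_profile(flat, flat_in, feat, n_bins = 20)
  expect_equal(length(unique(round(prof$ip_mean, 9))), 1L)
  # single spike at 75% of the feature
  spk <- rep(10, 200); spk[51] <- 1000   # bin 51 covers [2500, 2550)
  ips <- coverage_track(list(chr1 = spk), 50, label = "IP")
  prof2 <- metagene_profile(ips, flat_in, feat, n_bins = 20)
  expect_equal(which.max(prof2$ip_mean), 16L)  # (2500-1000)/2000 -> bin 16
})

test_that("metagene profile of a minus-strand feature is mirrored", {
  spk <- rep(5, 200); spk[30:33] <- 300
  ip <- coverage_track(list(chr1 = spk), 50, label = "IP")
  inp <- coverage_track(list(chr1 = rep(5, 200)), 50, label = "input")
  fwd <- metagene_profile(ip, inp, genomic_intervals("chr1", 0, 10000, "+"),
                          n_bins = 50)
  rev_ <- metagene_profile(ip, inp, genomic_intervals("chr1", 0, 10000, "-"),
                           n_bins = 50)
  expect_equal(fwd$ip_mean, rev(rev_$ip_mean))
})

test_that("simulated IP profiles peak near the stop codon while input stays flat", {
  sim <- default_sim()
  ip <- simulate_coverage(sim, "2CLC", "IP")
  inp <- simulate_coverage(sim, "2CLC", "input")
  st <- sim$truth$gene$m6a_2CLC
  prof <- metagene_profile(ip, inp, sim$genes[st, ], n_bins = 25)
  ratio <- (prof$ip_mean + 1e-3) / (prof$input_mean + 1e-3)
  # enrichment concentrated in the 3' half (stop-codon-proximal positions)
  expect_gt(max(ratio[13:25]), max(ratio[1:10]))
})

test_that("replicate concordance is 1 for identical replicates", {
  m <- matrix(rnorm(600), ncol = 3,
              dimnames = list(sprintf("g%03d", 1:200), c("r1", "r2", "r3")))
  m[, 2] <- m[, 1]; m[, 3] <- m[, 1]
  cc <- replicate_concordance(m, top_k = 100)
  expect_true(all(abs(cc$correlation - 1) < 1e-12))
  expect_length(cc$genes_used, 100)
})

test_that("independent noise replicates decorrelate; shared signal correlates", {
  set.seed(11)
  noise <- matrix(rnorm(4000), ncol = 2)
  cc <- replicate_concordance(noise, top_k = 2000)
  expect_lt(abs(cc$correlation[1, 2]), 0.1)
  sig <- rnorm(2000, sd = 2)
  shared <- cbind(sig + rnorm(2000, sd = 0.5), sig + rnorm(2000, sd = 0.5),
                  rnorm(2000, sd = 2))
  cs <- replicate_concordance(shared, top_k = 2000)
  expect_gt(cs$correlation[1, 2], cs$correlation[1, 3])
})

test_that("m6A fraction by expression decile behaves at the extremes", {
  st <- data.frame(gene_id = sprintf("g%d", 1:500), condition = "2CLC",
                   status = TRUE, n_peaks = 1L)
  e <- stats::setNames(rexp(500), st$gene_id)
  fr <- m6a_by_expression_bin(st, e)
  expect_true(all(fr$frac_m6a == 1))
  st$status <- rep(c(TRUE, FALSE), 250)
  fr2 <- m6a_by_expression_bin(st, e)
  expect_true(all(fr2$ci_lo <= fr2$frac_m6a & fr2$frac_m6a <= fr2$ci_hi))
})

test_that("expression-coupled methylation yields a rising decile trend", {
  set.seed(21)
  e <- stats::setNames(sort(rexp(1000)), sprintf("g%d", 1:1000))
  p <- seq(0.1, 0.9, length.out = 1000)
  st <- data.frame(gene_id = names(e), condition = "2CLC",
                   status = runif(1000) < p, n_peaks = 1L)
  fr <- m6a_by_expression_bin(st, e)
  expect_gt(stats::cor(fr$bin, fr$frac_m6a, method = "spearman"), 0)
})

test_that("set_overlap returns exact Venn partition cardinalities", {
  s <- list(A = as.character(1:10), B = as.character(6:15),
            C = c("1", "6", "15"))
  ov <- set_overlap(s)
  expect_equal(unname(ov["A&B&C"]), 1L)            # {6}
  expect_equal(unname(ov["A&B"]), 4L)              # {7,8,9,10}
  expect_equal(unname(ov["A&C"]), 1L)              # {1}
  expect_equal(unname(ov["B&C"]), 1L)              # {15}
  expect_equal(sum(ov), attr(ov, "union"))
  disj <- set_overlap(list(X = c("a"), Y = c("b")))
  expect_equal(unname(disj["X&Y"]), 0L)
  same <- set_overlap(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(unname(same["X&Y"]), 2L)
})
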