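test_that("annotation generation is deterministic and structurally valid", {
  cfg <- sim_config(seed = 42)
  s1 <- simulate_annotation(cfg)
  s2 <- simulate_annotation(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$te, s2$te)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  validate_gene_models(s1$genes)
  expect_equal(nrow(s1$genes), 20L)
  expect_equal(nrow(s1$te), 40L)
  expect_equal(as.vector(table(s1$te$te_class)[c("DNA", "SINE", "LINE",
                                                 "LTR")]),
               rep(10L, 4))
  # genes pairwise non-overlapping
  sp <- gene_spans(s1$genes)
  for (ch in unique(sp$chrom)) {
    d <- sp[sp$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # TEs in intergenic space: no overlap with gene spans
  expect_equal(sum(m6adyn:::.overlap_bp_with_set(s1$te, sp)), 0)
  # MERVL is an LTR family with full-length flags
  expect_true(all(s1$te$te_class[s1$te$te_family == "MERVL"] == "LTR"))
  expect_true(any(s1$te$full_length[s1$te$te_family == "MERVL"]))
})

test_that("zero genes leave a TE-and-intergenic genome", {
  s <- simulate_annotation(sim_config(seed = 3, n_genes = 0))
  expect_equal(nrow(s$genes), 0L)
  expect_equal(nrow(s$te), 40L)
  expect_equal(nrow(s$truth$gene), 0L)
})

test_that("an over-packed genome raises a capacity error", {
  expect_error(simulate_annotation(sim_config(seed = 1, n_genes = 40,
                                              n_chroms = 1,
                                              chrom_length = 20000)),
               "capacity error")
})

test_that("true peaks lie within the feature they annotate", {
  sim <- default_sim()
  sp <- gene_spans(sim$genes)
  fl <- sim$cfg$stop_flank
  for (i in seq_len(nrow(sim$truth$peaks))) {
    p <- sim$truth$peaks[i, ]
    if (grepl("^te", p$origin)) {
      te <- sim$te[as.integer(sub("te", "", p$origin)), ]
      expect_gte(p$start, te$start); expect_lte(p$end, te$end)
    } else {
      g <- sp[sp$gene_id == p$origin, ]
      expect_gte(p$start, g$start - fl)
      expect_lte(p$end, g$end + fl)
    }
  }
})

test_that("IP coverage is enriched at true peaks by about the configured fold", {
  sim <- default_sim()
  ip <- simulate_coverage(sim, "2CLC", "IP")
  inp <- simulate_coverage(sim, "2CLC", "input")
  pk <- sim$truth$peaks[sim$truth$peaks$condition == "2CLC", ]
  count_over <- function(trk, df) sum(vapply(seq_len(nrow(df)), function(i)
    m6adyn:::.region_count(trk, df$chrom[i], df$start[i], df$end[i]),
    numeric(1)))
  ex <- gene_exons(sim$genes)
  # peak-region IP/input ratio relative to the non-peak exonic background
  # ratio recovers the configured fold (library renormalisation cancels)
  r_peak <- (count_over(ip, pk) / ip$library_size) /
    (count_over(inp, pk) / inp$library_size)
  bg <- ex[m6adyn:::.overlap_bp_with_set(ex, pk) == 0, , drop = FALSE]
  r_bg <- (count_over(ip, bg) / ip$library_size) /
    (count_over(inp, bg) / inp$library_size)
  expect_gt(r_peak / r_bg, 0.75 * sim$cfg$peak_ip_fold)
  expect_lt(r_peak / r_bg, 1.25 * sim$cfg$peak_ip_fold)
  # same-seed reproducibility
  ip2 <- simulate_coverage(sim, "2CLC", "IP")
  expect_identical(ip$counts, ip2$counts)
})

test_that("fold-1 IP and input tracks are statistically indistinguishable", {
  cfg <- sim_config(seed = 8, peak_ip_fold = 1, noise_dispersion = 0)
  sim <- simulate_annotation(cfg)
  ip <- simulate_coverage(sim, "2CLC", "IP")
  inp <- simulate_coverage(sim, "2CLC", "input")
  a <- unlist(ip$counts); b <- unlist(inp$counts)
  expect_gt(stats::wilcox.test(a, b)$p.value, 0.01)
})

test_that("expression matrix activates ZGA genes and keeps replicates noisy", {
  sim <- expr_sim()
  ex <- simulate_expression(sim)
  expect_equal(ncol(ex$counts), 6L)
  gt <- sim$truth$gene
  m2 <- rowMeans(ex$counts[gt$gene_id, ex$conditions == "2CLC"])
  me <- rowMeans(ex$counts[gt$gene_id, ex$conditions == "ESC"])
  zga <- gt$category == "ZGA"
  expect_gt(median(m2[zga] / pmax(me[zga], 1)), 4)
  # MERVL row highest among TE families in 2CLC
  te_rows <- grep("^TE:", rownames(ex$counts), value = TRUE)
  m2te <- rowMeans(ex$counts[te_rows, ex$conditions == "2CLC", drop = FALSE])
  expect_equal(names(which.max(m2te)), "TE:MERVL")
})

test_that("flat activation (fc 1) produces no systematic DEGs", {
  sim <- simulate_annotation(sim_config(seed = 5, n_genes = 200,
                                        n_chroms = 4, chrom_length = 400000,
                                        fc_zga_2clc = 1, frac_other_up = 0,
                                        n_te_copies = c(DNA = 2, SINE = 2,
                                                        LINE = 2, LTR = 2)))
  ex <- simulate_expression(sim)
  degs <- call_degs(ex$counts, ex$conditions)
  expect_lt(mean(degs$direction != "ns"), 0.05)
})

test_that("single-cell generator encodes the transition and decay structure", {
  sim <- expr_sim(seed = 13, n_genes = 150)
  sc <- simulate_single_cell(sim)
  expect_equal(ncol(sc$counts), sum(sim$cfg$n_cells))
  expect_setequal(unique(sc$true_states),
                  c("2CLC", "transient", "pluripotent"))
  # m6A+ ZGA genes decline more steeply than m6A- along the trajectory
  norm <- normalize_cells(sc$counts)
  mean_by <- function(genes, state)
    mean(norm[genes, sc$true_states == state, drop = FALSE])
  drop_pos <- mean_by(sc$zga_m6a_pos, "2CLC") -
    mean_by(sc$zga_m6a_pos, "pluripotent")
  drop_neg <- mean_by(sc$zga_m6a_neg, "2CLC") -
    mean_by(sc$zga_m6a_neg, "pluripotent")
  expect_gt(drop_pos, drop_neg)
  # a state with zero cells is absent downstream
  cfg0 <- sim_config(seed = 13, n_genes = 150, n_chroms = 4,
                     chrom_length = 500000,
                     n_te_copies = c(DNA = 5, SINE = 5, LINE = 5, LTR = 5),
                     n_cells = c("2CLC" = 20, transient = 0,
                                 pluripotent = 20))
  sc0 <- simulate_single_cell(simulate_annotation(cfg0))
  expect_false("transient" %in% sc0$true_states)
})

test_that("decay generator matches its closed form", {
  sim <- default_sim()
  # k = ln2/2 per hour -> expected value 0.5 at t = 2 h
  cfg <- sim_config(seed = 2, decay_rate_m6a = log(2) / 2, decay_noise = 0)
  sim2 <- simulate_annotation(cfg)
  dc <- simulate_decay(sim2, timepoints = c(0, 2, 4))
  pos <- dc$courses[dc$courses$gene %in% dc$m6a_pos &
                      dc$courses$condition == "ctrl", ]
  expect_equal(pos$rel_expr[pos$time_h == 2], rep(0.5, sum(pos$time_h == 2)))
  expect_equal(pos$rel_expr[pos$time_h == 0], rep(1, sum(pos$time_h == 0)))
})

test_that("simulated data round-trips through the plain-text writers", {
  sim <- default_sim()
  dir <- withr::local_tempdir()
  write_sim_data(sim, dir)
  expect_equal(read_genome_table(file.path(dir, "genome.tsv")), sim$genome)
  expect_equal(read_gene_models(file.path(dir, "genes.tsv")), sim$genes)
  te2 <- read_te_annotation(file.path(dir, "te.tsv"))
  expect_equal(te2$start, sim$te$start)
  expect_equal(te2$te_family, sim$te$te_family)
  pk <- read_bed(file.path(dir, "true_peaks_2CLC.bed"))
  tp <- sim$truth$peaks[sim$truth$peaks$condition == "2CLC", ]
  expect_equal(pk$start, tp$start)
  expect_equal(pk$end, tp$end)
})
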