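make_status <- function(genes, s2, se) {
  rbind(data.frame(gene_id = genes, condition = "2CLC", status = s2),
        data.frame(gene_id = genes, condition = "ESC", status = se))
}

test_that("dynamics classification matches the gain/keep/lose/none mapping", {
  st <- make_status(c("a", "b", "c", "d"),
                    s2 = c(TRUE, TRUE, FALSE, FALSE),
                    se = c(FALSE, TRUE, TRUE, FALSE))
  cl <- classify_m6a_dynamics(st)
  expect_equal(stats::setNames(cl$class, cl$gene_id),
               c(a = "gain", b = "keep", c = "lose", d = "none"))
})

test_that("classification is total and idempotent over many random tables", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:100)
  s2 <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  se <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  cl <- classify_m6a_dynamics(make_status(genes, s2, se))
  expected <- ifelse(s2 & !se, "gain",
              ifelse(s2 & se, "keep", ifelse(!s2 & se, "lose", "none")))
  expect_equal(cl$class, expected)
  expect_identical(classify_m6a_dynamics(make_status(genes, s2, se)), cl)
  expect_error(classify_m6a_dynamics(
    make_status(genes, s2, se)[1:150, ]), "missing condition")
})

test_that("DEG calling applies strict FC > 2 and FDR < 0.05 cut-offs", {
  sim <- expr_sim()
  ex <- simulate_expression(sim)
  degs <- call_degs(ex$counts, ex$conditions)
  up <- degs[degs$direction == "up", ]
  expect_true(all(2^up$log2fc > 2 & up$q_value < 0.05))
  ns <- degs[degs$direction == "ns", ]
  expect_true(all(2^abs(ns$log2fc) <= 2 | ns$q_value >= 0.05))
  # >= 95% of ZGA genes recovered as up-DEGs at activation fold 8
  zga <- sim$truth$gene$gene_id[sim$truth$gene$category == "ZGA"]
  expect_gte(mean(zga %in% up$gene_id), 0.95)
})

test_that("swapping the contrast flips directions and negates log2FC", {
  sim <- expr_sim()
  ex <- simulate_expression(sim)
  a <- call_degs(ex$counts, ex$conditions, "2CLC", "ESC")
  b <- call_degs(ex$counts, ex$conditions, "ESC", "2CLC")
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$direction == "up", b$direction == "down")
})

test_that("insufficient replication is an error", {
  m <- matrix(rpois(30, 50), ncol = 3,
              dimnames = list(sprintf("g%d", 1:10), NULL))
  expect_error(call_degs(m, c("A", "A", "B"), "A", "B"),
               "insufficient replication")
})

test_that("fold changes separate by dynamics class when coupled by the simulator", {
  sim <- expr_sim()
  ex <- simulate_expression(sim)
  degs <- call_degs(ex$counts, ex$conditions)
  gt <- sim$truth$gene
  cl <- classify_m6a_dynamics(make_status(gt$gene_id, gt$m6a_2CLC,
                                          gt$m6a_ESC))
  res <- fc_by_dynamics_class(degs, cl)
  s <- res$summary
  # ZGA genes (mostly gain) are activated: gain median above none median
  expect_gt(s$median_log2fc[s$class == "gain"],
            s$median_log2fc[s$class == "none"])
  expect_true(all(res$tests$p_value > 0 & res$tests$p_value <= 1))
  # an empty class is omitted with a warning
  cl2 <- cl[cl$class != "lose", ]
  degs2 <- degs[degs$gene_id %in% cl2$gene_id, ]
  expect_warning(fc_by_dynamics_class(degs2, cl2), "omitted")
})

test_that("ZGA association builds the Fig-2E-style table and detects coupling", {
  sim <- expr_sim()
  ex <- simulate_expression(sim)
  degs <- call_degs(ex$counts, ex$conditions)
  gt <- sim$truth$gene
  status <- data.frame(gene_id = gt$gene_id, condition = "2CLC",
                       status = gt$m6a_2CLC, n_peaks = NA)
  zga <- gt$gene_id[gt$category == "ZGA"]
  res <- zga_m6a_association(degs, status, zga)
  expect_equal(sum(res$table), sum(degs$direction == "up"))
  expect_gt(res$fisher$odds_ratio, 1)
  expect_lt(res$fisher$p_value, 0.01)
  # with intensities, the contrast compares m6A+ ZGA vs m6A+ non-ZGA
  iv <- data.frame(gene_id = gt$gene_id,
                   intensity = rnorm(nrow(gt)) + 2 * gt$m6a_2CLC)
  res2 <- zga_m6a_association(degs, status, zga, intensity = iv)
  expect_true(is.numeric(res2$intensity_contrast$p_value))
  expect_error(zga_m6a_association(degs[degs$direction != "up", ],
                                   status, zga), "degenerate table")
})

test_that("the association test holds its nominal level under independence", {
  set.seed(77)
  rej <- replicate(500, {
    genes <- sprintf("g%d", 1:150)
    degs <- data.frame(gene_id = genes, mean_a = 1, mean_b = 1, log2fc = 2,
                       p_value = 0.001, q_value = 0.001, direction = "up")
    status <- data.frame(gene_id = genes, condition = "2CLC",
                         status = runif(150) < 0.3)
    zga <- genes[1:60]
    zga_m6a_association(degs, status, zga)$fisher$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("top up-DEG table ranks by expression with deterministic tie-break", {
  degs <- data.frame(gene_id = c("d", "b", "a", "c", "e"),
                     mean_a = c(5, 10, 10, 50, 3),
                     mean_b = 1, log2fc = c(3, 3, 3, 3, 0.5),
                     p_value = 0.001, q_value = 0.001,
                     direction = c("up", "up", "up", "up", "ns"))
  status <- data.frame(gene_id = letters[1:5], condition = "2CLC",
                       status = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  top <- top_updeg_annotation(degs, status, zga_set = c("a", "c"), n = 3)
  expect_equal(top$gene_id, c("c", "a", "b"))   # 50, then 10-tie a before b
  expect_equal(top$is_zga, c(TRUE, TRUE, FALSE))
  expect_equal(top$m6a, c(TRUE, TRUE, FALSE))
  # n larger than available returns everything that passes the filter
  top_all <- top_updeg_annotation(degs, status, zga_set = "a", n = 50)
  expect_equal(nrow(top_all), 4L)
})

test_that("top table on simulated data is dominated by ZGA genes", {
  sim <- expr_sim()
  ex <- simulate_expression(sim)
  degs <- call_degs(ex$counts, ex$conditions)
  gt <- sim$truth$gene
  status <- data.frame(gene_id = gt$gene_id, condition = "2CLC",
                       status = gt$m6a_2CLC)
  top <- top_updeg_annotation(degs, status,
                              zga_set = gt$gene_id[gt$category == "ZGA"])
  expect_gte(mean(top$is_zga), 0.5)
})
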