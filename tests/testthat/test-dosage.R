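test_that("monoallelic percentage counts only informative genes", {
  ann <- tiny_annotation()
  calls <- data.frame(
    cell_id = c(rep("c1", 5), "c2"),
    gene_id = c("GX1", "GX1", "GX1", "GX2", "GX2", "GA1"),
    chromosome = c("X", "X", "X", "X", "X", "10"),
    state = c("monoallelic", "monoallelic", "monoallelic", "biallelic",
              "discarded", "biallelic"),
    stringsAsFactors = FALSE
  )
  # c1: 3 mono + 1 bi on X (discarded ignored) -> 75%; c2: no informative X
  out <- monoallelic_fraction(calls, ann, "X")
  expect_equal(out$pct_monoallelic[out$cell_id == "c1"], 75)
  expect_true(is.na(out$pct_monoallelic[out$cell_id == "c2"]))
  # excluded genes leave numerator and denominator
  out2 <- monoallelic_fraction(calls, ann, "X", excluded = "GX2")
  expect_equal(out2$pct_monoallelic[out2$cell_id == "c1"], 100)
})

test_that("stage trend is exact on monotone input and errors on constants", {
  cells <- paste0("c", 1:6)
  meta <- tiny_meta(cells, stage = stage_levels())
  vals <- data.frame(cell_id = cells, pct_monoallelic = c(5, 10, 20, 40, 60, 90))
  tr <- stage_trend(vals, meta)
  expect_gt(tr$r, 0.95)
  one_per_stage <- data.frame(cell_id = cells,
                              pct_monoallelic = seq(10, 60, by = 10))
  expect_equal(stage_trend(one_per_stage, meta)$r, 1, tolerance = 1e-12)

  const <- data.frame(cell_id = cells, pct_monoallelic = rep(50, 6))
  expect_error(stage_trend(const, meta), "constant")
})

test_that("a randomly permuted fraction shows no stage trend", {
  set.seed(17)
  cells <- paste0("c", 1:100)
  meta <- tiny_meta(cells, stage = sample(c("morula", "early_blastocyst",
                                            "late_blastocyst"), 100, TRUE))
  vals <- data.frame(cell_id = cells, pct_monoallelic = sample(seq(0, 100, 1), 100, TRUE))
  tr <- stage_trend(vals, meta)
  expect_lt(abs(tr$r), 0.2)
})

test_that("group comparison matches exact Mann-Whitney enumeration", {
  res <- group_compare(c(1, 2, 3), c(101, 102, 103))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)        # minimal two-sided p at n = 3,3
  expect_equal(res$direction, -1)

  same <- group_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)

  expect_error(group_compare(numeric(0), 1:3), "non-empty")
})

test_that("significance stars use the figure-legend bins", {
  expect_equal(xciscope:::p_stars(c(0.04, 0.06, 9e-4, 5e-5, 0.05)),
               c("*", "ns", "***", "****", "*"))
})

test_that("expression medians honour per-cell calls and the 0.1 FPKM floor", {
  ann <- tiny_annotation()
  cells <- c("c1", "c2")
  meta <- tiny_meta(cells, stage = "morula")
  m <- matrix(c(5, 0.05,   # GX1
                3, 7,      # GX2
                1, 1,      # GA1
                1, 1,      # GA2
                0, 0),     # GY1
              nrow = 5, byrow = TRUE,
              dimnames = list(ann$gene_id, cells))
  fpkm <- expr_matrix(m, "FPKM")
  calls <- data.frame(
    cell_id = c("c1", "c1", "c2"),
    gene_id = c("GX1", "GX2", "GX1"),
    chromosome = "X",
    state = c("biallelic", "biallelic", "biallelic"),
    stringsAsFactors = FALSE
  )
  em <- expression_medians(fpkm, calls, meta, ann, "biallelic")
  # c1: median(5, 3) = 4; c2: GX1 below the floor -> no gene -> NA
  expect_equal(em$medians$median_fpkm[em$medians$cell_id == "c1"], 4)
  expect_true(is.na(em$medians$median_fpkm[em$medians$cell_id == "c2"]))

  none <- expression_medians(fpkm, calls, meta, ann, "monoallelic")
  expect_true(all(is.na(none$medians$median_fpkm)))

  # gene order in the matrix is irrelevant
  fpkm_rev <- expr_matrix(m[rev(seq_len(nrow(m))), ], "FPKM")
  em2 <- expression_medians(fpkm_rev, calls, meta, ann, "biallelic")
  expect_equal(em$medians, em2$medians)
})

test_that("dampening verdict is indeterminate without usable medians", {
  ann <- tiny_annotation()
  cells <- c("c1", "c2")
  meta <- tiny_meta(cells, stage = c("morula", "early_blastocyst"))
  zeros <- tiny_expr(rep(0, 10), genes = ann$gene_id, cells = cells)
  calls <- data.frame(cell_id = character(), gene_id = character(),
                      chromosome = character(), state = character(),
                      stringsAsFactors = FALSE)
  res <- dampening_test(zeros, calls, meta, ann)
  expect_equal(res$verdict, "indeterminate")
  expect_true(all(is.na(res$medians$median_fpkm)))
})

test_that("X:A ratio is exactly 1 on identical expression multisets", {
  ann <- tiny_annotation()
  cells <- c("c1", "c2")
  m <- tiny_expr(rep(2.5, 10), genes = ann$gene_id, cells = cells)
  xa <- xa_ratio_global(m, ann)
  expect_equal(xa$xa_ratio, c(1, 1))
  expect_equal(xa$n_autosomal, c(2L, 2L))  # the Y gene never joins the pool

  # empty X pool -> missing, not a number
  m2 <- unclass(m)
  m2[c("GX1", "GX2"), "c1"] <- 0
  xa2 <- xa_ratio_global(expr_matrix(m2, "FPKM"), ann)
  expect_true(is.na(xa2$xa_ratio[xa2$cell_id == "c1"]))
})

test_that("degenerate bootstrap pools reproduce the global estimator exactly", {
  set.seed(4)
  genes_x <- sprintf("X%03d", 1:100)
  genes_a <- sprintf("A%03d", 1:100)
  ann <- data.frame(
    gene_id = c(genes_x, genes_a),
    chromosome = rep(c("X", "7"), each = 100),
    start = 1L, end = 100L, is_escapee_or_par = FALSE,
    stringsAsFactors = FALSE
  )
  m <- tiny_expr(stats::rlnorm(200, 2, 1) + 0.2, genes = ann$gene_id,
                 cells = "c1")
  glob <- xa_ratio_global(m, ann)
  boot <- xa_ratio_bootstrap(m, ann, n_genes = 100L, n_reps = 50L, seed = 9L)
  expect_equal(boot$xa_ratio_bootstrap, glob$xa_ratio, tolerance = 1e-12)
  expect_equal(boot$boot_q025, boot$boot_q975)  # every replication identical

  # determinism under a fixed seed
  boot2 <- xa_ratio_bootstrap(m, ann, n_genes = 100L, n_reps = 50L, seed = 9L)
  expect_identical(boot, boot2)
})
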