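test_that("identical seed and scenario give identical datasets", {
  sc <- sim_scenario(seed = 99L)
  d1 <- simulate_dataset(sc)
  d2 <- simulate_dataset(sc)
  expect_identical(d1$allele_counts, d2$allele_counts)
  expect_identical(unclass(d1$fpkm), unclass(d2$fpkm))
  expect_identical(d1$cell_meta, d2$cell_meta)
})

test_that("complete silencing makes every heterozygous X SNP monoallelic", {
  sc <- female_cohort_scenario(p_mono = 1, stages = "late_blastocyst",
                               seed = 5L)
  sc$allelic_noise <- 0
  d <- simulate_dataset(sc)
  x <- d$allele_counts[d$allele_counts$chromosome == "X", ]
  covered <- x[x$ref_count + x$alt_count > 0, ]
  expect_gt(nrow(covered), 100L)
  expect_true(all(covered$ref_count == 0 | covered$alt_count == 0))
})

test_that("without silencing the alt-allele fraction centres on one half", {
  # binomial oracle: each deep-covered het X SNP draws alt reads at p = 0.5
  sc <- female_cohort_scenario(p_mono = 0, stages = "late_blastocyst",
                               n_embryos_per_stage = 6L,
                               cells_per_embryo = 12L, seed = 6L)
  sc$allelic_noise <- 0
  d <- simulate_dataset(sc)
  x <- d$allele_counts[d$allele_counts$chromosome == "X", ]
  tot <- x$ref_count + x$alt_count
  frac <- x$alt_count[tot > 0] / tot[tot > 0]
  expect_gte(length(frac), 1e4)
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("dosage algebra holds in the pure regimes", {
  # noise-free construction: X output per cell is base * u * (active alleles)
  layout <- make_layout(stage = "late_blastocyst", sex = c("male", "female"),
                        n_embryos = 1L, cells_per_embryo = 2L)
  base_args <- list(
    embryos = layout, n_genes_X = 50L, n_genes_autosome = 50L, n_genes_Y = 2L,
    n_escapee = 0L, maternal_fraction = 0, cell_noise_sdlog = 0,
    upregulation_factor = 2, seed = 3L
  )
  no_xci <- do.call(sim_scenario, c(base_args, list(p_mono = 0)))
  full_xci <- do.call(sim_scenario, c(base_args, list(p_mono = 1)))
  d0 <- simulate_dataset(no_xci)
  d1 <- simulate_dataset(full_xci)
  xg <- d0$annotation$gene_id[d0$annotation$chromosome == "X"]
  male <- grep("_m_", colnames(d0$fpkm), value = TRUE)
  female <- grep("_f_", colnames(d0$fpkm), value = TRUE)
  # female without XCI = 2 x male (both alleles active, same u)
  expect_equal(unclass(d0$fpkm)[xg, female[1]],
               2 * unclass(d0$fpkm)[xg, male[1]])
  # female with complete XCI = male (one active allele each)
  expect_equal(unclass(d1$fpkm)[xg, female[1]],
               unclass(d1$fpkm)[xg, male[1]])
  # autosomes identical across regimes and sexes
  ag <- d0$annotation$gene_id[d0$annotation$chromosome == "10"]
  expect_equal(unclass(d0$fpkm)[ag, female[1]], unclass(d0$fpkm)[ag, male[1]])
})

test_that("expression matrices equal the summed allelic truth", {
  d <- simulate_dataset(sim_scenario(seed = 8L))
  tg <- d$truth$genes
  tot <- tg$expr_ref + tg$expr_alt
  flat <- as.vector(unclass(d$fpkm)[cbind(match(tg$gene_id, rownames(d$fpkm)),
                                          match(tg$cell_id, colnames(d$fpkm)))])
  expect_equal(flat, tot, tolerance = 1e-12)
  # TPM is the same latent abundance renormalised per cell
  expect_equal(colSums(unclass(d$tpm)), rep(1e6, ncol(d$tpm)),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("Y genes are silent in females and in pre-EGA cells", {
  layout <- make_layout(stage = c("zygote", "4cell", "late_blastocyst"),
                        sex = "male", n_embryos = 1L, cells_per_embryo = 2L)
  layout <- rbind(layout, make_layout(stage = "late_blastocyst", sex = "female",
                                      n_embryos = 1L, cells_per_embryo = 2L))
  d <- simulate_dataset(sim_scenario(embryos = layout, seed = 2L))
  yg <- d$annotation$gene_id[d$annotation$chromosome == "Y"]
  sex_of <- layout$sex[match(d$cell_meta$embryo_id, layout$embryo_id)]
  pre <- d$cell_meta$cell_id[d$cell_meta$stage %in% c("zygote", "4cell")]
  fem <- setdiff(d$cell_meta$cell_id[sex_of == "female"], pre)
  male_late <- setdiff(d$cell_meta$cell_id, c(pre, fem))
  expect_true(all(unclass(d$fpkm)[yg, pre] == 0))
  expect_true(all(unclass(d$fpkm)[yg, fem] == 0))
  expect_true(all(unclass(d$fpkm)[yg, male_late] > 0))
})

test_that("higher silencing probability raises the downstream monoallelic rate", {
  grid <- c(0, 0.3, 0.6, 0.9)
  rates <- vapply(seq_along(grid), function(i) {
    sc <- female_cohort_scenario(p_mono = grid[i], stages = "late_blastocyst",
                                 n_embryos_per_stage = 2L,
                                 cells_per_embryo = 6L, seed = 100L + i)
    d <- simulate_dataset(sc)
    calls <- ase_chain(d)$gene_calls
    x <- calls[calls$chromosome == "X" &
                 calls$state %in% c("monoallelic", "biallelic"), ]
    mean(x$state == "monoallelic")
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("scenario validation rejects inconsistent inputs", {
  expect_error(sim_scenario(p_mono = c(blastula = 0.5)), "unknown stage")
  expect_error(sim_scenario(allelic_noise = 1.5), "probabilities")
  expect_error(sim_scenario(upregulation_factor = 0), "must be > 0")
  expect_error(sim_scenario(n_escapee = 9999), "n_escapee")
})

test_that("the reference cohort layout matches the published design", {
  sc <- make_reference_layout()
  expect_equal(nrow(sc$embryos), 14L)
  expect_equal(sum(sc$embryos$sex == "female"), 5L)
  expect_equal(sum(sc$embryos$n_cells), 196L)
  expect_equal(sum(sc$embryos$n_cells_pass), 124L)
  stages <- table(sc$embryos$stage)
  expect_equal(as.integer(stages[c("zygote", "4cell", "8cell", "morula",
                                   "early_blastocyst", "late_blastocyst")]),
               c(3L, 1L, 2L, 3L, 3L, 2L))
})
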