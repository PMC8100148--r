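test_that("embryo genotypes pool cells and apply coverage and MAF floors", {
  meta <- tiny_meta(c("c1", "c2"), embryo_id = "E1")
  counts <- data.frame(
    cell_id = c("c1", "c2", "c1", "c1"),
    chromosome = c("X", "X", "X", "10"),
    position = c(100L, 100L, 200L, 300L),
    ref = "A", alt = "G",
    ref_count = c(20L, 10L, 36L, 10L),
    alt_count = c(5L, 5L, 2L, 5L),
    stringsAsFactors = FALSE
  )
  gt <- build_embryo_genotype(counts, meta)
  # pos 100: pooled 30/10, maf 0.25 -> het; pos 200: 36/2, maf 0.05 -> out;
  # pos 300: coverage 15 -> out regardless of ratio
  expect_equal(gt$position, 100L)
  expect_equal(gt$pooled_ref, 30L)
  expect_equal(gt$pooled_alt, 10L)
})

test_that("SNP classification follows the allelic-frequency brackets", {
  rec <- data.frame(
    cell_id = "c", chromosome = "X", position = 1:4, ref = "A", alt = "G",
    ref_count = c(18L, 10L, 19L, 2L),
    alt_count = c(2L, 10L, 0L, 18L),
    stringsAsFactors = FALSE
  )
  out <- classify_snp(rec)
  expect_equal(out$state, c("mono_ref", "biallelic", "uninformative", "mono_alt"))
  expect_equal(out$alt_fraction[1], 0.10)
})

test_that("SNP classification is symmetric under ref/alt swap", {
  set.seed(1)
  rec <- data.frame(
    cell_id = "c", chromosome = "X", position = seq_len(200),
    ref = "A", alt = "G",
    ref_count = sample(0:40, 200, replace = TRUE),
    alt_count = sample(0:40, 200, replace = TRUE),
    stringsAsFactors = FALSE
  )
  fwd <- classify_snp(rec)$state
  swapped <- rec
  swapped$ref_count <- rec$alt_count
  swapped$alt_count <- rec$ref_count
  rev <- classify_snp(swapped)$state
  map <- c(mono_ref = "mono_alt", mono_alt = "mono_ref",
           biallelic = "biallelic", uninformative = "uninformative")
  expect_equal(rev, unname(map[fwd]))
})

test_that("gene calls aggregate SNP agreement and disagreement", {
  ann <- tiny_annotation()
  # all SNPs fall inside GX1 (X: 1000-1999)
  mk <- function(states) {
    calls <- do.call(rbind, lapply(seq_along(states), function(i) {
      snp_call_row("c1", "X", 1000L + i, states[i])
    }))
    call_genes(calls, ann)
  }
  two_mono <- mk(c("mono_ref", "mono_ref"))
  expect_equal(two_mono$state, "monoallelic")
  expect_equal(two_mono$mono_allele, "ref_haplotype")

  conflict <- mk(c("mono_ref", "biallelic"))
  expect_equal(conflict$state, "discarded")

  mixed <- mk(c("mono_ref", "mono_alt"))
  expect_equal(mixed$state, "monoallelic")
  expect_equal(mixed$mono_allele, "mixed")

  silent <- mk(c("uninformative", "uninformative"))
  expect_equal(silent$state, "uninformative")

  both_bi <- mk(c("biallelic", "biallelic"))
  expect_equal(both_bi$state, "biallelic")
  expect_equal(both_bi$mono_allele, "n/a")
})

test_that("the informative-state partition is exhaustive and exclusive", {
  d <- simulate_dataset(female_cohort_scenario(
    p_mono = 0.5, stages = "late_blastocyst", n_embryos_per_stage = 2L,
    cells_per_embryo = 4L, seed = 77L))
  calls <- ase_chain(d)$gene_calls
  expect_true(all(calls$state %in%
                    c("monoallelic", "biallelic", "discarded", "uninformative")))
  expect_equal(anyDuplicated(calls[, c("cell_id", "gene_id")]), 0L)
})

test_that("the X exclusion set combines flags and post-8-cell male biallelics", {
  ann <- tiny_annotation()
  ann$is_escapee_or_par[ann$gene_id == "GX2"] <- TRUE
  meta <- tiny_meta(c("m_morula", "m_8cell"),
                    embryo_id = c("EM1", "EM2"),
                    stage = c("morula", "8cell"))
  sex_calls <- data.frame(embryo_id = c("EM1", "EM2"),
                          call = c("male", "male"), stringsAsFactors = FALSE)
  gene_calls <- data.frame(
    cell_id = c("m_morula", "m_8cell", "m_morula"),
    gene_id = c("GX1", "GX1", "GA1"),
    chromosome = c("X", "X", "10"),
    state = "biallelic",
    stringsAsFactors = FALSE
  )
  excl <- x_exclusion_filter(gene_calls, ann, sex_calls, meta)
  # GX1 biallelic in a male morula cell -> excluded; flag adds GX2;
  # the autosomal gene and 8-cell evidence alone never exclude
  expect_setequal(excl, c("GX1", "GX2"))

  only8 <- gene_calls[gene_calls$cell_id == "m_8cell", , drop = FALSE]
  meta8 <- meta[meta$cell_id == "m_8cell", , drop = FALSE]
  expect_warning(excl8 <- x_exclusion_filter(only8, ann, sex_calls, meta8),
                 "only the supplied exclusion flags")
  expect_equal(excl8, "GX2")
})

test_that("informative counts match simulator truth and ignore cell order", {
  d <- simulate_dataset(female_cohort_scenario(
    p_mono = 0.3, stages = "late_blastocyst", n_embryos_per_stage = 2L,
    cells_per_embryo = 6L, seed = 55L))
  chain <- ase_chain(d)
  tab <- tabulate_informative(chain$gene_calls, d$annotation, chain$snp_calls)
  shuffled <- chain$gene_calls[rev(seq_len(nrow(chain$gene_calls))), ]
  tab2 <- tabulate_informative(shuffled, d$annotation, chain$snp_calls)
  expect_equal(tab, tab2)
  # the only X genes reported informative are heterozygous in some embryo
  het_x <- unique(d$truth$het$gene_id[d$truth$het$het &
                                        grepl("G_X", d$truth$het$gene_id)])
  inf_x <- unique(chain$gene_calls$gene_id[
    chain$gene_calls$chromosome == "X" &
      chain$gene_calls$state %in% c("monoallelic", "biallelic")])
  expect_true(all(inf_x %in% het_x))
  expect_equal(tab$n_informative_genes[tab$chromosome == "X"], length(inf_x))

  empty <- tabulate_informative(chain$gene_calls[0, ], d$annotation,
                                chain$snp_calls[0, ])
  expect_true(all(empty$n_informative_genes == 0L))
  expect_true(all(empty$n_het_positions == 0L))
})
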