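# Small in-code fixtures shared across test files.

tiny_annotation <- function() {
  data.frame(
    gene_id = c("GX1", "GX2", "GA1", "GA2", "GY1"),
    chromosome = c("X", "X", "10", "10", "Y"),
    start = c(1000L, 5000L, 1000L, 5000L, 1000L),
    end = c(1999L, 5999L, 1999L, 5999L, 1999L),
    is_escapee_or_par = FALSE,
    stringsAsFactors = FALSE
  )
}

tiny_meta <- function(cell_id, embryo_id = cell_id, stage = "morula",
                      lineage = "morula", mapped_reads = 3e6) {
  data.frame(cell_id = cell_id, embryo_id = embryo_id, stage = stage,
             lineage = lineage, mapped_reads = mapped_reads,
             stringsAsFactors = FALSE)
}

tiny_expr <- function(values, genes, cells, unit = "FPKM") {
  m <- matrix(values, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, cells))
  expr_matrix(m, unit = unit)
}

snp_call_row <- function(cell_id, chromosome, position, state) {
  data.frame(cell_id = cell_id, chromosome = chromosome, position = position,
             ref = "A", alt = "G", state = state, stringsAsFactors = FALSE)
}

# a compact post-EGA female cohort for allele-specific analyses
female_cohort_scenario <- function(p_mono, dampening_factor = 1,
                                   upregulation_factor = 1,
                                   n_embryos_per_stage = 3L,
                                   cells_per_embryo = 8L,
                                   stages = c("morula", "early_blastocyst",
                                              "late_blastocyst"),
                                   seed = 42L, ...) {
  sim_scenario(
    embryos = make_layout(stage = stages, sex = "female",
                          n_embryos = n_embryos_per_stage,
                          cells_per_embryo = cells_per_embryo),
    p_mono = p_mono,
    dampening_factor = dampening_factor,
    upregulation_factor = upregulation_factor,
    n_genes_X = 100L, n_genes_autosome = 200L, n_genes_Y = 5L,
    n_escapee = 0L,
    maternal_fraction = 0,
    depth_mean = 100, depth_dispersion = 5,
    allelic_noise = 0.005,
    seed = seed,
    ...
  )
}

# run the allele-specific calling chain on a simulated dataset
ase_chain <- function(sim, params = ase_params()) {
  genotype <- build_embryo_genotype(sim$allele_counts, sim$cell_meta, params)
  snp_calls <- cell_snp_calls(sim$allele_counts, genotype, sim$cell_meta, params)
  gene_calls <- call_genes(snp_calls, sim$annotation)
  list(genotype = genotype, snp_calls = snp_calls, gene_calls = gene_calls)
}
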