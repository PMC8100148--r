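# Allele-specific expression: embryo genotypes, per-cell SNP and gene
# allelic calls, and the X-linked exclusion filters.

#' Allele-specific-expression parameters
#'
#' Allelic-fraction brackets follow the classic 0-20% / 80-100% rule: at a
#' heterozygous SNP covered by at least `min_coverage` reads, an alternative
#' allele fraction <= `mono_low` or >= `mono_high` is monoallelic expression,
#' anything in between is biallelic. The boundaries belong to the
#' monoallelic brackets (<= / >=), keeping "0-20%" literally closed.
#' Embryo-level heterozygosity uses pooled coverage >= `embryo_het_min_coverage`
#' and pooled minor-allele fraction >= `embryo_het_min_maf` (the cell-level
#' constants mirrored at the genotype level).
#'
#' @param min_coverage Minimum reads for a SNP call in a cell (default 20).
#' @param mono_low,mono_high Monoallelic allelic-fraction brackets
#'   (default 0.20 / 0.80).
#' @param embryo_het_min_maf Minimum pooled minor-allele fraction to call a
#'   position heterozygous in an embryo (default 0.20).
#' @param embryo_het_min_coverage Minimum pooled coverage for embryo-level
#'   heterozygosity (default 20).
#' @return An `ase_params` list.
#' @export
ase_params <- function(min_coverage = 20L, mono_low = 0.20, mono_high = 0.80,
                       embryo_het_min_maf = 0.20, embryo_het_min_coverage = 20L) {
  if (!(mono_low > 0 && mono_low < mono_high && mono_high < 1)) {
    stop("need 0 < mono_low < mono_high < 1", call. = FALSE)
  }
  if (min_coverage < 1L) stop("min_coverage must be >= 1", call. = FALSE)
  structure(list(
    min_coverage = as.integer(min_coverage),
    mono_low = mono_low, mono_high = mono_high,
    embryo_het_min_maf = embryo_het_min_maf,
    embryo_het_min_coverage = as.integer(embryo_het_min_coverage)
  ), class = "ase_params")
}

#' Construct per-embryo genotypes from pooled allelic counts
#'
#' Merges the allelic counts of all cells of the same embryo and calls a
#' position heterozygous when the pooled coverage and pooled minor-allele
#' fraction clear the thresholds in `params`. Downstream per-cell calls are
#' made only at the cell's own embryo's heterozygous positions.
#'
#' @param counts Allele-count records (see [read_allele_counts()]).
#' @param meta Cell metadata mapping every `cell_id` to an `embryo_id`.
#' @param params An [ase_params()].
#' @return Data.frame of heterozygous positions: `embryo_id`, `chromosome`,
#'   `position`, `ref`, `alt`, `pooled_ref`, `pooled_alt`.
#' @export
build_embryo_genotype <- function(counts, meta, params = ase_params()) {
  dt <- data.table::as.data.table(counts)
  dt[, embryo_id := meta$embryo_id[match(dt$cell_id, meta$cell_id)]]
  if (anyNA(dt$embryo_id)) {
    orphans <- unique(dt$cell_id[is.na(dt$embryo_id)])
    stop("allele-count cell(s) missing from metadata: ",
         paste(utils::head(orphans, 5L), collapse = ", "), call. = FALSE)
  }
  pooled <- dt[, list(pooled_ref = sum(ref_count), pooled_alt = sum(alt_count)),
               by = list(embryo_id, chromosome, position, ref, alt)]
  total <- pooled$pooled_ref + pooled$pooled_alt
  maf <- ifelse(total > 0, pmin(pooled$pooled_ref, pooled$pooled_alt) / total, 0)
  het <- pooled[total >= params$embryo_het_min_coverage &
                  maf >= params$embryo_het_min_maf]
  as.data.frame(het)
}

#' Classify allelic state at SNPs
#'
#' Vectorised over a table of allele-count records (which should already be
#' restricted to positions heterozygous in the cell's embryo, see
#' [build_embryo_genotype()]). A record with fewer than `min_coverage` total
#' reads is `uninformative`; otherwise the alternative-allele fraction
#' decides: <= `mono_low` is `mono_ref`, >= `mono_high` is `mono_alt`,
#' anything between is `biallelic`.
#'
#' @param records Allele-count records.
#' @param params An [ase_params()].
#' @return The records with added `total_reads`, `alt_fraction`, `state`.
#' @export
classify_snp <- function(records, params = ase_params()) {
  total <- records$ref_count + records$alt_count
  frac <- ifelse(total > 0, records$alt_count / total, NA_real_)
  state <- rep("biallelic", nrow(records))
  state[!is.na(frac) & frac <= params$mono_low] <- "mono_ref"
  state[!is.na(frac) & frac >= params$mono_high] <- "mono_alt"
  state[total < params$min_coverage] <- "uninformative"
  out <- records
  out$total_reads <- total
  out$alt_fraction <- frac
  out$state <- state
  out
}

#' Restrict cell records to embryo-heterozygous positions and classify
#'
#' The per-cell arm of the genotyping strategy: each cell's variants are
#' kept only where its own embryo's genotype is heterozygous, then
#' classified with [classify_snp()].
#'
#' @param counts Allele-count records for all cells.
#' @param genotype Embryo genotype from [build_embryo_genotype()].
#' @param meta Cell metadata.
#' @param params An [ase_params()].
#' @return SNP calls at heterozygous positions only.
#' @export
cell_snp_calls <- function(counts, genotype, meta, params = ase_params()) {
  dt <- data.table::as.data.table(counts)
  dt[, embryo_id := meta$embryo_id[match(dt$cell_id, meta$cell_id)]]
  gt <- data.table::as.data.table(
    genotype[, c("embryo_id", "chromosome", "position", "ref", "alt")])
  keep <- merge(dt, gt, by = c("embryo_id", "chromosome", "position", "ref", "alt"))
  classify_snp(as.data.frame(keep), params)
}

#' Aggregate SNP calls into per-cell gene allelic calls
#'
#' SNPs are assigned to genes by coordinate overlap with the gene span (a
#' SNP inside two overlapping genes contributes to both, with a message).
#' Per (cell, gene): if every informative SNP is monoallelic the gene is
#' `monoallelic` (with `mono_allele` recording the common haplotype, or
#' `mixed` when different SNPs point at opposite alleles — phase being
#' unknown, both literally satisfy the monoallelic rule); if every
#' informative SNP is biallelic the gene is `biallelic`; a disagreement
#' between mono and biallelic SNPs discards the gene in that cell; no
#' informative SNP makes it `uninformative`.
#'
#' @param snp_calls SNP calls from [cell_snp_calls()] / [classify_snp()].
#' @param annotation Gene annotation.
#' @return Data.frame: `cell_id`, `gene_id`, `chromosome`, `state`,
#'   `mono_allele`, `n_snps`, `n_informative`.
#' @export
call_genes <- function(snp_calls, annotation) {
  if (nrow(snp_calls) == 0L) {
    return(data.frame(cell_id = character(), gene_id = character(),
                      chromosome = character(), state = character(),
                      mono_allele = character(), n_snps = integer(),
                      n_informative = integer(), stringsAsFactors = FALSE))
  }
  calls <- data.table::as.data.table(snp_calls)
  snps <- unique(calls[, list(chromosome, position)])
  snps[, `:=`(start = position, end = position)]
  ann <- data.table::as.data.table(
    annotation[, c("gene_id", "chromosome", "start", "end")])
  data.table::setkey(ann, chromosome, start, end)
  ov <- data.table::foverlaps(snps, ann, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) {
    return(call_genes(snp_calls[0, , drop = FALSE], annotation))
  }
  n_multi <- ov[, .N, by = list(chromosome, position)][N > 1L, .N]
  if (n_multi > 0L) {
    message(n_multi, " SNP position(s) overlap more than one gene; assigned to all")
  }
  map <- ov[, list(chromosome, position, gene_id)]
  merged <- merge(calls, map, by = c("chromosome", "position"),
                  allow.cartesian = TRUE)
  agg <- merged[, {
    informative <- state %in% c("mono_ref", "mono_alt", "biallelic")
    n_mono_ref <- sum(state == "mono_ref")
    n_mono_alt <- sum(state == "mono_alt")
    n_bi <- sum(state == "biallelic")
    n_inf <- sum(informative)
    st <- if (n_inf == 0L) "uninformative"
      else if (n_bi == 0L) "monoallelic"
      else if (n_mono_ref + n_mono_alt == 0L) "biallelic"
      else "discarded"
    ma <- if (st != "monoallelic") "n/a"
      else if (n_mono_alt == 0L) "ref_haplotype"
      else if (n_mono_ref == 0L) "alt_haplotype"
      else "mixed"
    list(state = st, mono_allele = ma, n_snps = .N, n_informative = n_inf)
  }, by = list(cell_id, gene_id)]
  chrom <- annotation$chromosome[match(agg$gene_id, annotation$gene_id)]
  out <- as.data.frame(agg)
  out$chromosome <- chrom
  out[, c("cell_id", "gene_id", "chromosome", "state", "mono_allele",
          "n_snps", "n_informative")]
}

#' X-linked gene exclusion set
#'
#' Genes removed from every downstream X-linked analysis: the supplied
#' escapee/pseudoautosomal-homologue flags, plus any X gene called
#' biallelic in at least one cell of a male embryo after the 8-cell stage —
#' in a post-EGA male the single X cannot genuinely express two alleles, so
#' such signal betrays cross-mapping from X/Y-shared or escapee loci.
#' Biallelic male signal at or before the 8-cell stage is expected (residual
#' maternal transcripts) and does not exclude a gene.
#'
#' @param gene_calls Gene calls from [call_genes()].
#' @param annotation Gene annotation.
#' @param sex_calls Sex calls from [sex_embryos()].
#' @param meta Cell metadata.
#' @return Character vector of excluded X gene ids.
#' @export
x_exclusion_filter <- function(gene_calls, annotation, sex_calls, meta) {
  flagged <- annotation$gene_id[annotation$is_escapee_or_par &
                                  annotation$chromosome == "X"]
  male_embryos <- sex_calls$embryo_id[sex_calls$call == "male"]
  post8 <- stage_rank(meta$stage) > stage_rank("8cell")
  male_late_cells <- meta$cell_id[meta$embryo_id %in% male_embryos & post8]
  if (length(male_late_cells) == 0L) {
    warning("no post-8-cell male cells available; applying only the supplied exclusion flags",
            call. = FALSE)
    male_biallelic <- character()
  } else {
    sel <- gene_calls$cell_id %in% male_late_cells &
      gene_calls$chromosome == "X" & gene_calls$state == "biallelic"
    male_biallelic <- unique(gene_calls$gene_id[sel])
  }
  sort(union(flagged, male_biallelic))
}

#' Count informative genes and heterozygous positions per chromosome
#'
#' A gene is informative if it is called monoallelic or biallelic in at
#' least one cell; a position is counted when it yields at least one
#' informative SNP call. Both counts are invariant to cell ordering.
#'
#' @param gene_calls Gene calls from [call_genes()].
#' @param annotation Gene annotation.
#' @param snp_calls Optional SNP calls; when given, per-chromosome counts of
#'   informative heterozygous positions are included.
#' @return Data.frame: `chromosome`, `n_informative_genes`
#'   (, `n_het_positions`).
#' @export
tabulate_informative <- function(gene_calls, annotation, snp_calls = NULL) {
  chroms <- sort(unique(annotation$chromosome))
  inf <- gene_calls[gene_calls$state %in% c("monoallelic", "biallelic"), , drop = FALSE]
  genes_by_chrom <- table(annotation$chromosome[
    match(unique(inf$gene_id), annotation$gene_id)])
  out <- data.frame(
    chromosome = chroms,
    n_informative_genes = as.integer(genes_by_chrom[chroms]),
    stringsAsFactors = FALSE
  )
  out$n_informative_genes[is.na(out$n_informative_genes)] <- 0L
  if (!is.null(snp_calls)) {
    inf_snps <- snp_calls[snp_calls$state %in% c("mono_ref", "mono_alt", "biallelic"),
                          c("chromosome", "position"), drop = FALSE]
    pos <- unique(inf_snps)
    pos_by_chrom <- table(pos$chromosome)
    out$n_het_positions <- as.integer(pos_by_chrom[chroms])
    out$n_het_positions[is.na(out$n_het_positions)] <- 0L
  }
  out
}
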