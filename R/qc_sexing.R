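# Cell quality filtering and embryo sexing from Y-linked expression.

#' Quality-filter parameters
#'
#' Defaults reproduce the study's filter: a cell is kept if it has at least
#' 200 detected genes (counting only genes expressed in at least 3 cells)
#' and strictly between 2e6 and 5.1e6 reads mapped to genes.
#'
#' @param min_genes_per_cell Minimum detected genes per cell.
#' @param min_cells_per_gene A gene counts as "detectable" only if expressed
#'   (> 0) in at least this many cells.
#' @param min_mapped_reads,max_mapped_reads Strict (exclusive) bounds on
#'   reads mapped to genes.
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_genes_per_cell = 200L, min_cells_per_gene = 3L,
                      min_mapped_reads = 2e6, max_mapped_reads = 5.1e6) {
  if (min_mapped_reads >= max_mapped_reads) {
    stop("min_mapped_reads must be < max_mapped_reads", call. = FALSE)
  }
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0) {
    stop("QC thresholds must be non-negative", call. = FALSE)
  }
  structure(list(
    min_genes_per_cell = as.integer(min_genes_per_cell),
    min_cells_per_gene = as.integer(min_cells_per_gene),
    min_mapped_reads = min_mapped_reads,
    max_mapped_reads = max_mapped_reads
  ), class = "qc_params")
}

#' Apply the cell-quality filter
#'
#' A cell is retained iff (a) it detects (value > 0) at least
#' `min_genes_per_cell` genes, counting only genes expressed in at least
#' `min_cells_per_gene` cells of the input matrix, and (b) its
#' `mapped_reads` lies strictly between the two read bounds. The read bounds
#' are exclusive: a cell with exactly 2e6 mapped reads is removed. The
#' filter is idempotent in the read dimension; the gene-detectability step
#' is evaluated on the matrix as given.
#'
#' @param expr An [expr_matrix()] (any unit).
#' @param meta Cell metadata with `cell_id` and `mapped_reads` for every
#'   matrix column.
#' @param params A [qc_params()].
#' @return Character vector of retained cell ids, with attribute `n_removed`.
#' @export
filter_cells <- function(expr, meta, params = qc_params()) {
  cells <- colnames(expr)
  missing_meta <- setdiff(cells, meta$cell_id)
  if (length(missing_meta) > 0L) {
    stop("cell(s) in expression matrix missing from metadata: ",
         paste(utils::head(missing_meta, 5L), collapse = ", "), call. = FALSE)
  }
  mapped <- meta$mapped_reads[match(cells, meta$cell_id)]
  detectable <- rowSums(unclass(expr) > 0) >= params$min_cells_per_gene
  n_detected <- colSums(unclass(expr)[detectable, , drop = FALSE] > 0)
  keep <- n_detected >= params$min_genes_per_cell &
    mapped > params$min_mapped_reads & mapped < params$max_mapped_reads
  out <- cells[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Build the clean Y-linked gene panel for sexing
#'
#' Y-chromosome genes minus (a) any gene expressed (TPM >= `tpm_min`) in at
#' least one pre-EGA (zygote or 4-cell) cell — at those stages the
#' transcriptome is maternal, so apparent Y expression betrays cross-mapping
#' from X/Y-shared regions — and (b) genes on the escapee/pseudoautosomal
#' exclusion list.
#'
#' @param tpm A TPM [expr_matrix()].
#' @param annotation Gene annotation (see [read_annotation()]).
#' @param meta Cell metadata covering the matrix columns.
#' @param tpm_min Expression threshold (default 1: "expressed" means
#'   TPM >= 1).
#' @return Character vector of panel gene ids.
#' @export
build_y_gene_panel <- function(tpm, annotation, meta, tpm_min = 1) {
  assert_unit(tpm, "TPM")
  y_genes <- annotation$gene_id[annotation$chromosome == "Y"]
  if (length(y_genes) == 0L) {
    stop("annotation contains no Y-linked genes; sexing is impossible", call. = FALSE)
  }
  y_genes <- setdiff(y_genes, annotation$gene_id[annotation$is_escapee_or_par])
  pre_ega_cells <- intersect(
    meta$cell_id[meta$stage %in% c("zygote", "4cell")], colnames(tpm))
  if (length(pre_ega_cells) > 0L) {
    y_in_matrix <- intersect(y_genes, rownames(tpm))
    sub <- unclass(tpm)[y_in_matrix, pre_ega_cells, drop = FALSE]
    tainted <- y_in_matrix[rowSums(sub >= tpm_min) > 0]
    y_genes <- setdiff(y_genes, tainted)
  }
  y_genes
}

#' Sex embryos from Y-panel expression
#'
#' Each post-EGA embryo is scored by (1) the number of panel genes expressed
#' (TPM >= `tpm_min`) in at least one of its cells and (2) its cells'
#' summed panel TPM. An embryo is called male iff at least one panel gene is
#' expressed in at least `min_cells_expressed` of its cells; within each
#' stage the per-cell summed panel TPMs of the two called groups are
#' compared with a two-sided unpaired Wilcoxon (Mann-Whitney) test, reported
#' as evidence. Zygote and 4-cell embryos are always `unsexed` (maternal
#' transcriptome). A stage with a single embryo is called on absolute
#' evidence alone (no test) with a caveat message.
#'
#' @param tpm A TPM [expr_matrix()] (QC-filtered cells).
#' @param panel Y-gene panel from [build_y_gene_panel()].
#' @param meta Cell metadata covering the matrix columns.
#' @param tpm_min Expression threshold (default 1).
#' @param min_cells_expressed Cells in which a panel gene must be expressed
#'   to call male (default 2; robust to a single stray read).
#' @return Data.frame: `embryo_id`, `stage`, `call`, `n_y_genes_expressed`,
#'   `median_panel_tpm`, `statistic`, `p_value`.
#' @export
sex_embryos <- function(tpm, panel, meta, tpm_min = 1, min_cells_expressed = 2L) {
  assert_unit(tpm, "TPM")
  meta <- meta[meta$cell_id %in% colnames(tpm), , drop = FALSE]
  panel <- intersect(panel, rownames(tpm))
  embryos <- unique(meta[, c("embryo_id", "stage")])
  vals <- unclass(tpm)[panel, meta$cell_id, drop = FALSE]
  per_cell_sum <- colSums(vals)

  res <- lapply(seq_len(nrow(embryos)), function(i) {
    eid <- embryos$embryo_id[i]
    st <- embryos$stage[i]
    cells <- meta$cell_id[meta$embryo_id == eid]
    sub <- vals[, cells, drop = FALSE]
    n_y <- sum(rowSums(sub >= tpm_min) > 0)
    gene_cells <- rowSums(sub >= tpm_min)
    med <- stats::median(per_cell_sum[cells])
    if (st %in% c("zygote", "4cell")) {
      call <- "unsexed"
    } else if (length(panel) == 0L) {
      call <- "unsexed"
    } else {
      effective_min <- min(min_cells_expressed, length(cells))
      call <- if (any(gene_cells >= effective_min)) "male" else "female"
    }
    data.frame(embryo_id = eid, stage = st, call = call,
               n_y_genes_expressed = n_y, median_panel_tpm = med,
               statistic = NA_real_, p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)

  # within-stage Wilcoxon evidence: per-cell summed panel TPM, males vs females
  for (st in setdiff(unique(out$stage), c("zygote", "4cell"))) {
    stage_embryos <- out$embryo_id[out$stage == st]
    if (length(stage_embryos) < 2L) {
      message("stage ", st, " has a single embryo; sex called on absolute Y evidence only")
      next
    }
    males <- out$embryo_id[out$stage == st & out$call == "male"]
    females <- out$embryo_id[out$stage == st & out$call == "female"]
    if (length(males) == 0L || length(females) == 0L) next
    x <- per_cell_sum[meta$cell_id[meta$embryo_id %in% males]]
    y <- per_cell_sum[meta$cell_id[meta$embryo_id %in% females]]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    out$statistic[out$stage == st] <- unname(wt$statistic)
    out$p_value[out$stage == st] <- wt$p.value
  }
  rownames(out) <- NULL
  out
}
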