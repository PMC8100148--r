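# Dosage-compensation statistics: monoallelic-fraction trajectories, the
# dampening test, expression-level medians, X:A ratios and the gene-
# resampling bootstrap, plus the shared Wilcoxon group comparison.

#' Per-cell monoallelic percentage on a chromosome
#'
#' 100 * monoallelic / (monoallelic + biallelic) over a cell's informative
#' genes on the chromosome, after removing `excluded` genes. Discarded and
#' uninformative genes enter neither numerator nor denominator. A cell with
#' no informative gene is reported `NA` (missing), never 0.
#'
#' @param gene_calls Gene calls from [call_genes()].
#' @param annotation Gene annotation.
#' @param chromosome Chromosome to restrict to (e.g. `"X"` or `"10"`).
#' @param excluded Gene ids to drop (e.g. from [x_exclusion_filter()]).
#' @return Data.frame: `cell_id`, `n_mono`, `n_informative`, `pct_monoallelic`.
#' @export
monoallelic_fraction <- function(gene_calls, annotation, chromosome = "X",
                                 excluded = character()) {
  sel <- gene_calls[gene_calls$chromosome == chromosome &
                      !(gene_calls$gene_id %in% excluded), , drop = FALSE]
  cells <- unique(gene_calls$cell_id)
  dt <- data.table::as.data.table(sel)
  agg <- dt[state %in% c("monoallelic", "biallelic"),
            list(n_mono = sum(state == "monoallelic"), n_informative = .N),
            by = cell_id]
  out <- data.frame(cell_id = cells, stringsAsFactors = FALSE)
  i <- match(out$cell_id, agg$cell_id)
  out$n_mono <- agg$n_mono[i]
  out$n_informative <- agg$n_informative[i]
  out$n_mono[is.na(out$n_mono)] <- 0L
  out$n_informative[is.na(out$n_informative)] <- 0L
  out$pct_monoallelic <- ifelse(out$n_informative > 0,
                                100 * out$n_mono / out$n_informative, NA_real_)
  out
}

#' Correlation of monoallelic fraction with developmental stage
#'
#' Pearson correlation between per-cell values and the ordinal stage rank
#' (zygote = 1 ... late blastocyst = 6, equally spaced). Cells with missing
#' values are dropped.
#'
#' @param values Data.frame with `cell_id` and a value column.
#' @param meta Cell metadata supplying stages.
#' @param value_col Name of the value column (default `"pct_monoallelic"`).
#' @return List: `r`, `p_value`, `n`.
#' @export
stage_trend <- function(values, meta, value_col = "pct_monoallelic") {
  v <- values[[value_col]]
  st <- meta$stage[match(values$cell_id, meta$cell_id)]
  ok <- !is.na(v) & !is.na(st)
  v <- v[ok]
  rank <- stage_rank(st[ok])
  if (length(v) < 3L || length(unique(rank)) < 2L) {
    stop("stage trend needs >= 3 cells spanning >= 2 stages", call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    stop("stage trend undefined: values are constant", call. = FALSE)
  }
  ct <- stats::cor.test(v, rank, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(v))
}

#' Two-group unpaired Wilcoxon comparison
#'
#' Two-sided Mann-Whitney test between two per-cell value vectors, with the
#' significance stars used in the figure conventions: `****` for p <= 1e-4,
#' `***` for p <= 1e-3, `*` for p <= 0.05, `ns` otherwise. Exact p-values
#' are used where the sample sizes and ties permit.
#'
#' @param x,y Numeric vectors (both non-empty after NA removal).
#' @param label_x,label_y Group labels for the output row.
#' @return One-row data.frame: `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value`, `direction` (sign of median difference `x - y`), `stars`.
#' @export
group_compare <- function(x, y, label_x = "group1", label_y = "group2") {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("group_compare requires two non-empty groups", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  dmed <- stats::median(x) - stats::median(y)
  data.frame(
    group1 = label_x, group2 = label_y,
    n1 = length(x), n2 = length(y),
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    direction = sign(dmed),
    stars = p_stars(wt$p.value),
    stringsAsFactors = FALSE
  )
}

#' @noRd
p_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.05, "*", "ns")))
}

#' Per-cell median expression over selected X-linked gene sets
#'
#' For each cell, the median FPKM over the selected genes with FPKM
#' strictly above `fpkm_min` (default 0.1). Selectors: `"biallelic"` and
#' `"monoallelic"` use each cell's own allelic calls (a gene contributes to
#' a cell's median only with that cell's call); `"all_X"` uses every
#' X-linked gene regardless of informativity. Genes in `excluded` are
#' always removed. Cells whose selected set is empty are `NA`. Consecutive
#' developmental stages are then compared per cell group with the unpaired
#' Wilcoxon test.
#'
#' @param fpkm An FPKM [expr_matrix()].
#' @param gene_calls Gene calls (needed for the allelic selectors).
#' @param meta Cell metadata (restricted to the cells to analyse, e.g. one
#'   sex).
#' @param annotation Gene annotation.
#' @param selector `"biallelic"`, `"monoallelic"` or `"all_X"`.
#' @param excluded Excluded X gene ids.
#' @param fpkm_min Strict expression threshold (default 0.1 FPKM).
#' @return List: `medians` (cell_id, stage, median_fpkm), `comparisons`
#'   (consecutive-stage Wilcoxon results).
#' @export
expression_medians <- function(fpkm, gene_calls, meta, annotation,
                               selector = c("biallelic", "monoallelic", "all_X"),
                               excluded = character(), fpkm_min = 0.1) {
  selector <- match.arg(selector)
  assert_unit(fpkm, "FPKM")
  cells <- intersect(meta$cell_id, colnames(fpkm))
  vals <- unclass(fpkm)
  x_genes <- setdiff(annotation$gene_id[annotation$chromosome == "X"], excluded)

  med <- vapply(cells, function(cl) {
    genes <- if (selector == "all_X") {
      x_genes
    } else {
      want <- if (selector == "biallelic") "biallelic" else "monoallelic"
      sel <- gene_calls$cell_id == cl & gene_calls$chromosome == "X" &
        gene_calls$state == want & !(gene_calls$gene_id %in% excluded)
      unique(gene_calls$gene_id[sel])
    }
    genes <- intersect(genes, rownames(fpkm))
    if (length(genes) == 0L) return(NA_real_)
    v <- vals[genes, cl]
    v <- v[v > fpkm_min]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))

  medians <- data.frame(
    cell_id = cells,
    stage = meta$stage[match(cells, meta$cell_id)],
    median_fpkm = unname(med),
    stringsAsFactors = FALSE
  )
  comparisons <- compare_consecutive_stages(medians, "median_fpkm")
  list(medians = medians, comparisons = comparisons)
}

#' @noRd
compare_consecutive_stages <- function(df, value_col) {
  present <- intersect(stage_levels(), unique(df$stage))
  rows <- list()
  if (length(present) >= 2L) {
    for (i in seq_len(length(present) - 1L)) {
      a <- df[[value_col]][df$stage == present[i]]
      b <- df[[value_col]][df$stage == present[i + 1L]]
      a <- a[!is.na(a)]
      b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) {
        message("skipping comparison ", present[i], " vs ", present[i + 1L],
                ": fewer than 2 cells with defined values in a group")
        next
      }
      rows[[length(rows) + 1L]] <-
        group_compare(b, a, label_x = present[i + 1L], label_y = present[i])
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(), statistic = numeric(),
                      p_value = numeric(), direction = numeric(),
                      stars = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Test for X-chromosome dampening
#'
#' Dampening — both active X alleles lowering their output — predicts a
#' DECREASE over development of the expression of genes that are still
#' biallelically expressed. The test takes each (female) cell's median FPKM
#' over its biallelically called X genes above 0.1 FPKM and compares
#' consecutive stages with the unpaired Wilcoxon test. The verdict is
#' `"detected"` iff some consecutive-stage comparison shows a significant
#' (alpha = 0.05) decrease; `"not_detected"` when comparisons exist but
#' none does; `"indeterminate"` when no comparison could be made.
#'
#' @inheritParams expression_medians
#' @param alpha Significance level for the decrease (default 0.05).
#' @return List: `medians`, `comparisons`, `verdict`.
#' @export
dampening_test <- function(fpkm, gene_calls, meta, annotation,
                           excluded = character(), fpkm_min = 0.1,
                           alpha = 0.05) {
  em <- expression_medians(fpkm, gene_calls, meta, annotation,
                           selector = "biallelic", excluded = excluded,
                           fpkm_min = fpkm_min)
  cmp <- em$comparisons
  verdict <- if (nrow(cmp) == 0L) {
    "indeterminate"
  } else if (any(cmp$p_value <= alpha & cmp$direction < 0, na.rm = TRUE)) {
    "detected"
  } else {
    "not_detected"
  }
  list(medians = em$medians, comparisons = cmp, verdict = verdict)
}

#' Per-cell X:autosome expression ratio (all expressed genes)
#'
#' For each cell: median FPKM over expressed X genes (FPKM > `fpkm_min`,
#' minus `excluded`) divided by median FPKM over expressed autosomal genes.
#' Y-linked genes never enter the autosomal pool. Cells with an empty pool
#' on either side are `NA`.
#'
#' @param fpkm An FPKM [expr_matrix()].
#' @param annotation Gene annotation.
#' @param excluded Excluded X gene ids.
#' @param fpkm_min Strict expression threshold (default 0.1).
#' @return Data.frame: `cell_id`, `n_x`, `n_autosomal`, `xa_ratio`.
#' @export
xa_ratio_global <- function(fpkm, annotation, excluded = character(),
                            fpkm_min = 0.1) {
  assert_unit(fpkm, "FPKM")
  vals <- unclass(fpkm)
  x_genes <- intersect(
    setdiff(annotation$gene_id[annotation$chromosome == "X"], excluded),
    rownames(fpkm))
  a_genes <- intersect(
    annotation$gene_id[!(annotation$chromosome %in% c("X", "Y"))],
    rownames(fpkm))
  res <- lapply(colnames(fpkm), function(cl) {
    xv <- vals[x_genes, cl]
    av <- vals[a_genes, cl]
    xv <- xv[xv > fpkm_min]
    av <- av[av > fpkm_min]
    data.frame(cell_id = cl, n_x = length(xv), n_autosomal = length(av),
               xa_ratio = if (length(xv) == 0L || length(av) == 0L) NA_real_
                          else stats::median(xv) / stats::median(av),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bootstrap X:A ratio from random gene panels
#'
#' The resampling estimator: per replication, sample `n_genes` expressed
#' X-linked and `n_genes` expressed autosomal genes without replacement
#' from the cell's own expressed pools and take the ratio of their medians;
#' the cell's estimate is the median over `n_reps` replications. When a
#' pool holds fewer than `n_genes` genes the sample size is reduced to the
#' pool size (with a message). Deterministic under `seed`.
#'
#' @inheritParams xa_ratio_global
#' @param n_genes Genes sampled per pool per replication (default 100).
#' @param n_reps Bootstrap replications (default 2000).
#' @param seed Integer seed for the resampling.
#' @return Data.frame: `cell_id`, `n_x`, `n_autosomal`,
#'   `xa_ratio_bootstrap` (median over replications), `boot_q025`,
#'   `boot_q975`.
#' @export
xa_ratio_bootstrap <- function(fpkm, annotation, excluded = character(),
                               fpkm_min = 0.1, n_genes = 100L, n_reps = 2000L,
                               seed = 1L) {
  assert_unit(fpkm, "FPKM")
  set.seed(as.integer(seed))
  vals <- unclass(fpkm)
  x_genes <- intersect(
    setdiff(annotation$gene_id[annotation$chromosome == "X"], excluded),
    rownames(fpkm))
  a_genes <- intersect(
    annotation$gene_id[!(annotation$chromosome %in% c("X", "Y"))],
    rownames(fpkm))
  shrunk <- FALSE
  res <- lapply(colnames(fpkm), function(cl) {
    xv <- vals[x_genes, cl]
    av <- vals[a_genes, cl]
    xv <- xv[xv > fpkm_min]
    av <- av[av > fpkm_min]
    if (length(xv) == 0L || length(av) == 0L) {
      return(data.frame(cell_id = cl, n_x = length(xv), n_autosomal = length(av),
                        xa_ratio_bootstrap = NA_real_,
                        boot_q025 = NA_real_, boot_q975 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    kx <- min(n_genes, length(xv))
    ka <- min(n_genes, length(av))
    if (kx < n_genes || ka < n_genes) shrunk <<- TRUE
    reps <- vapply(seq_len(n_reps), function(i) {
      stats::median(xv[sample.int(length(xv), kx)]) /
        stats::median(av[sample.int(length(av), ka)])
    }, numeric(1))
    q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    data.frame(cell_id = cl, n_x = length(xv), n_autosomal = length(av),
               xa_ratio_bootstrap = stats::median(reps),
               boot_q025 = q[1L], boot_q975 = q[2L],
               stringsAsFactors = FALSE)
  })
  if (shrunk) {
    message("some cells had fewer than ", n_genes,
            " expressed genes in a pool; sample size reduced to the pool size")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
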