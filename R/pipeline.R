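# End-to-end orchestration: simulate (or take loaded inputs), QC, sexing,
# allele-specific calling, exclusion filtering, dosage statistics, report.

#' Run the full dosage-compensation pipeline
#'
#' Sequences every stage on either a simulated dataset (give `scenario`) or
#' pre-loaded inputs (give `data`, a list with `allele_counts`, `fpkm`,
#' `tpm`, `annotation`, `cell_meta`). The run is deterministic given the
#' inputs and `seed`; the bootstrap uses a child seed derived from it so
#' that stage can be re-run in isolation.
#'
#' Stages: cell QC filter -> Y-panel construction and embryo sexing ->
#' embryo genotypes -> per-cell SNP and gene allelic calls -> X exclusion
#' filter -> monoallelic fractions (X and a control autosome) with stage
#' trends -> dampening test and expression medians -> X:A ratios (global
#' and bootstrap) -> report tables.
#'
#' @param scenario A [sim_scenario()] (simulation mode), or `NULL`.
#' @param data Pre-loaded inputs (non-simulation mode), or `NULL`.
#' @param qc [qc_params()].
#' @param ase [ase_params()].
#' @param control_chrom Control autosome for the monoallelic-fraction
#'   comparison (default `"10"`).
#' @param fpkm_min Strict expression threshold (default 0.1 FPKM).
#' @param boot_genes,boot_reps Bootstrap panel size and replications.
#' @param seed Global seed; defaults to the scenario's seed.
#' @param out_dir If non-NULL, report tables are written there.
#' @return List with `cell_summaries`, `comparisons`, `sex_calls`,
#'   `gene_calls`, `snp_calls`, `excluded_x_genes`, `informative_counts`,
#'   `trends`, `dampening`, counts and the seed.
#' @export
run_pipeline <- function(scenario = NULL, data = NULL,
                         qc = qc_params(), ase = ase_params(),
                         control_chrom = "10", fpkm_min = 0.1,
                         boot_genes = 100L, boot_reps = 2000L,
                         seed = NULL, out_dir = NULL) {
  if (is.null(data)) {
    if (is.null(scenario)) {
      stop("give either a simulation scenario or pre-loaded data", call. = FALSE)
    }
    data <- simulate_dataset(scenario)
  } else {
    for (nm in c("allele_counts", "fpkm", "tpm", "annotation", "cell_meta")) {
      if (is.null(data[[nm]])) stop("data is missing element: ", nm, call. = FALSE)
    }
  }
  if (is.null(seed)) {
    seed <- if (!is.null(scenario)) scenario$seed else 1L
  }
  seed <- as.integer(seed)
  boot_seed <- seed + 1L

  meta_all <- data$cell_meta
  n_total <- nrow(meta_all)

  ## QC --------------------------------------------------------------------
  retained <- filter_cells(data$fpkm, meta_all, qc)
  meta <- meta_all[meta_all$cell_id %in% retained, , drop = FALSE]
  fpkm <- expr_matrix(unclass(data$fpkm)[, retained, drop = FALSE], "FPKM")
  tpm <- expr_matrix(unclass(data$tpm)[, retained, drop = FALSE], "TPM")
  counts <- data$allele_counts[data$allele_counts$cell_id %in% retained, , drop = FALSE]
  ann <- data$annotation

  ## sexing ----------------------------------------------------------------
  panel <- build_y_gene_panel(tpm, ann, meta)
  sex_calls <- sex_embryos(tpm, panel, meta)
  meta$sex <- sex_calls$call[match(meta$embryo_id, sex_calls$embryo_id)]
  meta$sex[is.na(meta$sex)] <- "unsexed"

  ## allele-specific calls --------------------------------------------------
  genotype <- build_embryo_genotype(counts, meta, ase)
  snp_calls <- cell_snp_calls(counts, genotype, meta, ase)
  gene_calls <- call_genes(snp_calls, ann)
  excluded <- x_exclusion_filter(gene_calls, ann, sex_calls, meta)
  informative <- tabulate_informative(gene_calls, ann, snp_calls)

  ## dosage statistics ------------------------------------------------------
  mono_x <- monoallelic_fraction(gene_calls, ann, "X", excluded)
  mono_ctrl <- monoallelic_fraction(gene_calls, ann, control_chrom)

  trends <- list()
  comparisons <- list()
  for (sx in c("female", "male")) {
    cells_sx <- meta$cell_id[meta$sex == sx]
    sub <- mono_x[mono_x$cell_id %in% cells_sx, , drop = FALSE]
    trends[[paste0("mono_X_", sx)]] <- tryCatch(
      stage_trend(sub, meta), error = function(e) NULL)
    sub_c <- mono_ctrl[mono_ctrl$cell_id %in% cells_sx, , drop = FALSE]
    trends[[paste0("mono_ctrl_", sx)]] <- tryCatch(
      stage_trend(sub_c, meta), error = function(e) NULL)
  }

  meta_f <- meta[meta$sex == "female", , drop = FALSE]
  meta_m <- meta[meta$sex == "male", , drop = FALSE]

  damp <- if (nrow(meta_f) > 0L) {
    dampening_test(fpkm, gene_calls, meta_f, ann, excluded, fpkm_min)
  } else {
    list(medians = NULL, comparisons = NULL, verdict = "indeterminate")
  }
  if (!is.null(damp$comparisons) && nrow(damp$comparisons) > 0L) {
    comparisons$dampening_biallelic_female <- damp$comparisons
  }

  med_mono_f <- if (nrow(meta_f) > 0L) {
    expression_medians(fpkm, gene_calls, meta_f, ann, "monoallelic",
                       excluded, fpkm_min)
  } else NULL
  if (!is.null(med_mono_f) && nrow(med_mono_f$comparisons) > 0L) {
    comparisons$monoallelic_median_female <- med_mono_f$comparisons
  }
  med_all <- list()
  for (sx in c("female", "male")) {
    msub <- meta[meta$sex == sx, , drop = FALSE]
    if (nrow(msub) == 0L) next
    med_all[[sx]] <- expression_medians(fpkm, gene_calls, msub, ann, "all_X",
                                        excluded, fpkm_min)
    if (nrow(med_all[[sx]]$comparisons) > 0L) {
      comparisons[[paste0("all_X_median_", sx)]] <- med_all[[sx]]$comparisons
    }
  }

  xa <- xa_ratio_global(fpkm, ann, excluded, fpkm_min)
  xa_boot <- xa_ratio_bootstrap(fpkm, ann, excluded, fpkm_min,
                                n_genes = boot_genes, n_reps = boot_reps,
                                seed = boot_seed)

  # male vs female X:A per stage
  for (st in intersect(stage_levels(), unique(meta$stage))) {
    xm <- xa$xa_ratio[xa$cell_id %in% meta_m$cell_id[meta_m$stage == st]]
    xf <- xa$xa_ratio[xa$cell_id %in% meta_f$cell_id[meta_f$stage == st]]
    if (sum(!is.na(xm)) >= 2L && sum(!is.na(xf)) >= 2L) {
      comparisons[[paste0("xa_male_vs_female_", st)]] <-
        group_compare(xm, xf, paste0("male_", st), paste0("female_", st))
    }
  }

  comparisons_df <- if (length(comparisons) > 0L) {
    stacked <- Map(function(nm, df) cbind(analysis = nm, df),
                   names(comparisons), comparisons)
    out <- do.call(rbind, stacked)
    rownames(out) <- NULL
    out
  } else {
    data.frame(analysis = character(), group1 = character(), group2 = character(),
               n1 = integer(), n2 = integer(), statistic = numeric(),
               p_value = numeric(), direction = numeric(), stars = character(),
               stringsAsFactors = FALSE)
  }

  ## per-cell summary table -------------------------------------------------
  cs <- data.frame(
    cell_id = meta$cell_id,
    embryo_id = meta$embryo_id,
    stage = meta$stage,
    sex = meta$sex,
    stringsAsFactors = FALSE
  )
  cs$pct_monoallelic_X <- mono_x$pct_monoallelic[match(cs$cell_id, mono_x$cell_id)]
  cs$pct_monoallelic_control <- mono_ctrl$pct_monoallelic[match(cs$cell_id, mono_ctrl$cell_id)]
  pull_median <- function(obj) {
    if (is.null(obj)) return(rep(NA_real_, nrow(cs)))
    obj$medians$median_fpkm[match(cs$cell_id, obj$medians$cell_id)]
  }
  cs$median_biallelic_fpkm <- pull_median(damp)
  cs$median_monoallelic_fpkm <- pull_median(med_mono_f)
  all_meds <- rep(NA_real_, nrow(cs))
  for (sx in names(med_all)) {
    i <- match(med_all[[sx]]$medians$cell_id, cs$cell_id)
    all_meds[i] <- med_all[[sx]]$medians$median_fpkm
  }
  cs$median_all_X_fpkm <- all_meds
  cs$xa_ratio_global <- xa$xa_ratio[match(cs$cell_id, xa$cell_id)]
  cs$xa_ratio_bootstrap <- xa_boot$xa_ratio_bootstrap[match(cs$cell_id, xa_boot$cell_id)]

  results <- list(
    cell_summaries = cs,
    comparisons = comparisons_df,
    sex_calls = sex_calls,
    gene_calls = gene_calls,
    snp_calls = snp_calls,
    genotype = genotype,
    excluded_x_genes = excluded,
    informative_counts = informative,
    trends = trends,
    dampening = damp["verdict"],
    dampening_comparisons = damp$comparisons,
    y_panel = panel,
    n_cells_total = n_total,
    n_cells_retained = length(retained),
    seed = seed
  )
  if (!is.null(out_dir)) write_report(results, out_dir)
  results
}
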