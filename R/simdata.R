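# Synthetic cohort generator.
#
# Emulates the data structure of a preimplantation-embryo scRNA-seq study:
# per-cell expression (FPKM + TPM), per-cell per-SNP allele counts, gene
# annotation and cell metadata, under configurable dosage-compensation
# regimes (progressive X inactivation, X dampening, active-X upregulation).
#
# Generative model, per cell c of stage t and gene g with per-allele base
# abundance b_g ~ logNormal(meanlog, sdlog):
#   autosome            ref = alt = b_g
#   Y gene              male: b_g (single copy); female: 0
#   X gene, male        maternal-haplotype allele = u_t * b_g, other 0
#   X gene, female      each ACTIVE allele = u_t * d_t * b_g; a silenced
#                       allele contributes 0; escapees are never silenced
# Silencing of gene g in female cell c is Bernoulli(p_mono(t)) on the cell's
# (or, if imprinted, the embryo's) chosen haplotype; in coherent mode a
# contiguous block of the X around an XIST-like locus is silenced instead.
# Pre-EGA maternal carryover mixes in a fraction m_t of a maternal pool that
# is biallelic at every heterozygous site and silent on Y. Allelic read
# counts at heterozygous SNPs are binomial (optionally beta-binomial) draws
# at negative-binomial depths, with symmetric allele-miscall noise eps
# folded into the allele probability: p' = p(1-eps) + (1-p)eps.

#' Build an embryo layout table
#'
#' Convenience constructor for the `embryos` slot of [sim_scenario()]: one
#' row per embryo with its stage, (true) sex, number of cells and number of
#' cells planted to survive the read-depth quality filter.
#'
#' @param stage,sex Vectors (recycled against each other) of stage labels and
#'   sexes (`"male"`/`"female"`).
#' @param n_embryos Embryos per (stage, sex) combination.
#' @param cells_per_embryo Cells in each embryo.
#' @param cells_pass Cells per embryo planted to pass QC (default: all).
#' @return Data.frame with columns `embryo_id`, `stage`, `sex`, `n_cells`,
#'   `n_cells_pass`.
#' @export
make_layout <- function(stage, sex, n_embryos = 1L, cells_per_embryo = 8L,
                        cells_pass = cells_per_embryo) {
  grid <- data.frame(stage = stage, sex = sex, stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = n_embryos), , drop = FALSE]
  assert_stages(grid$stage)
  data.frame(
    embryo_id = sprintf("E%02d_%s_%s", seq_len(nrow(grid)),
                        grid$stage, substr(grid$sex, 1L, 1L)),
    stage = grid$stage,
    sex = grid$sex,
    n_cells = cells_per_embryo,
    n_cells_pass = cells_pass,
    stringsAsFactors = FALSE
  )
}

# resolve a scalar or named per-stage parameter into a full per-stage vector
#' @noRd
per_stage_param <- function(x, neutral, what) {
  lv <- stage_levels()
  if (is.null(names(x))) {
    if (length(x) == 1L) {
      out <- rep(as.numeric(x), length(lv))
      names(out) <- lv
      return(out)
    }
    if (length(x) == length(lv)) {
      out <- as.numeric(x)
      names(out) <- lv
      return(out)
    }
    stop(sprintf("%s must be a scalar or a named per-stage vector", what), call. = FALSE)
  }
  bad <- setdiff(names(x), lv)
  if (length(bad) > 0L) {
    stop(sprintf("%s given for unknown stage(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- rep(neutral, length(lv))
  names(out) <- lv
  out[names(x)] <- as.numeric(x)
  out
}

#' Parameterise a synthetic cohort
#'
#' Returns a validated `sim_scenario` object describing a full synthetic
#' dataset: the embryo/cell layout, gene content, the dosage-compensation
#' regime (per-stage silencing probability `p_mono`, upregulation factor
#' `upregulation_factor`, dampening factor `dampening_factor`), maternal
#' transcript carryover, and the sequencing-depth/noise model. Stage-resolved
#' parameters accept a scalar (applied to every stage) or a named vector
#' keyed by [stage_levels()]; unnamed stages keep the neutral value.
#'
#' @param embryos Embryo layout, see [make_layout()].
#' @param n_genes_X,n_genes_autosome,n_genes_Y Gene counts. Autosomal genes
#'   are spread round-robin over `autosomes`.
#' @param autosomes Autosome names; keep `"10"` present if the chromosome-10
#'   control analysis will be run.
#' @param n_escapee Number of X genes flagged as escaping silencing.
#' @param snps_per_gene Heterozygous SNVs simulated per heterozygous gene.
#' @param het_snp_prob Probability a (non-Y) gene is heterozygous in a given
#'   embryo.
#' @param base_meanlog,base_sdlog Log-normal parameters of per-allele base
#'   abundance (FPKM scale).
#' @param upregulation_factor Multiplicative boost on each ACTIVE X allele
#'   (1 = none, 2 = full single-X upregulation). Scalar or per-stage.
#' @param dampening_factor Multiplicative factor on every active X allele of
#'   female cells (1 = none; < 1 models dampening). Scalar or per-stage.
#' @param p_mono Per-stage probability that an X-linked gene in a female cell
#'   has been silenced on one haplotype. Scalar or per-stage.
#' @param imprinted If `TRUE` the silenced haplotype is fixed per embryo;
#'   otherwise each cell draws its own haplotype (random XCI).
#' @param coherent If `TRUE`, silencing hits a contiguous block of X genes
#'   centred on an XIST-like locus (fraction `p_mono` of the chromosome)
#'   rather than independent genes.
#' @param maternal_fraction Per-stage fraction of the transcriptome that is
#'   residual maternal mRNA (biallelic on X, silent on Y).
#' @param depth_mean,depth_dispersion Negative-binomial per-SNP read depth
#'   (mean and size).
#' @param allelic_noise Per-read probability of registering the wrong allele.
#' @param allelic_overdispersion Beta-binomial overdispersion rho in [0,1);
#'   0 (default) gives pure binomial sampling.
#' @param cell_noise_sdlog Log-normal sd of per-gene-per-cell expression
#'   noise (applied to a gene's total, preserving its allelic fraction).
#' @param seed Integer seed; identical seed + scenario gives identical output.
#' @return A `sim_scenario` object (list).
#' @export
sim_scenario <- function(embryos = make_layout(
                           stage = c("morula", "morula", "late_blastocyst", "late_blastocyst"),
                           sex = c("male", "female", "male", "female"),
                           n_embryos = 2L, cells_per_embryo = 8L),
                         n_genes_X = 150L, n_genes_autosome = 1000L, n_genes_Y = 5L,
                         autosomes = c("1", "2", "3", "10"),
                         n_escapee = 10L,
                         snps_per_gene = 2L, het_snp_prob = 0.8,
                         base_meanlog = 3, base_sdlog = 1,
                         upregulation_factor = 1,
                         dampening_factor = 1,
                         p_mono = 0,
                         imprinted = FALSE, coherent = FALSE,
                         maternal_fraction = c(zygote = 1, "4cell" = 1, "8cell" = 0.3,
                                               morula = 0.05),
                         depth_mean = 60, depth_dispersion = 5,
                         allelic_noise = 0.005, allelic_overdispersion = 0,
                         cell_noise_sdlog = 0.15,
                         seed = 1L) {
  embryos <- as.data.frame(embryos, stringsAsFactors = FALSE)
  need <- c("embryo_id", "stage", "sex", "n_cells")
  if (!all(need %in% names(embryos))) {
    stop("embryo layout needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(embryos$n_cells_pass)) embryos$n_cells_pass <- embryos$n_cells
  assert_stages(embryos$stage)
  if (!all(embryos$sex %in% c("male", "female"))) {
    stop("embryo sex must be 'male' or 'female' (truth label)", call. = FALSE)
  }
  if (any(embryos$n_cells_pass > embryos$n_cells | embryos$n_cells < 1L)) {
    stop("need 1 <= n_cells_pass <= n_cells for every embryo", call. = FALSE)
  }
  sc <- list(
    embryos = embryos,
    n_genes_X = as.integer(n_genes_X),
    n_genes_autosome = as.integer(n_genes_autosome),
    n_genes_Y = as.integer(n_genes_Y),
    autosomes = as.character(autosomes),
    n_escapee = as.integer(n_escapee),
    snps_per_gene = as.integer(snps_per_gene),
    het_snp_prob = het_snp_prob,
    base_meanlog = base_meanlog, base_sdlog = base_sdlog,
    upregulation_factor = per_stage_param(upregulation_factor, 1, "upregulation_factor"),
    dampening_factor = per_stage_param(dampening_factor, 1, "dampening_factor"),
    p_mono = per_stage_param(p_mono, 0, "p_mono"),
    imprinted = isTRUE(imprinted),
    coherent = isTRUE(coherent),
    maternal_fraction = per_stage_param(maternal_fraction, 0, "maternal_fraction"),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    allelic_noise = allelic_noise,
    allelic_overdispersion = allelic_overdispersion,
    cell_noise_sdlog = cell_noise_sdlog,
    seed = as.integer(seed)
  )
  probs <- c(sc$het_snp_prob, sc$p_mono, sc$maternal_fraction, sc$allelic_noise)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities (het_snp_prob, p_mono, maternal_fraction, allelic_noise) must lie in [0,1]",
         call. = FALSE)
  }
  if (any(sc$upregulation_factor <= 0) || any(sc$dampening_factor <= 0)) {
    stop("upregulation_factor and dampening_factor must be > 0", call. = FALSE)
  }
  if (sc$allelic_overdispersion < 0 || sc$allelic_overdispersion >= 1) {
    stop("allelic_overdispersion must lie in [0,1)", call. = FALSE)
  }
  if (sc$n_escapee > sc$n_genes_X) stop("n_escapee exceeds n_genes_X", call. = FALSE)
  if (sc$snps_per_gene < 0L) stop("snps_per_gene must be >= 0", call. = FALSE)
  class(sc) <- "sim_scenario"
  sc
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> %d embryos / %d cells; %d X + %d autosomal + %d Y genes; seed %d\n",
    nrow(x$embryos), sum(x$embryos$n_cells),
    x$n_genes_X, x$n_genes_autosome, x$n_genes_Y, x$seed))
  invisible(x)
}

#' Scenario mirroring the reference marmoset cohort layout
#'
#' A 14-embryo preimplantation cohort — 3 zygotes, one 4-cell, two 8-cell,
#' 3 compacted morulas, 3 early and 2 late blastocysts; 5 embryos female —
#' with the published per-embryo cell counts before (196 total) and after
#' (124 total) the read-depth quality filter. Pre-EGA embryos (zygote,
#' 4-cell) cannot be sexed from Y expression, so their truth sexes here are
#' an arbitrary assignment.
#'
#' @param ... Passed on to [sim_scenario()] to override non-layout defaults.
#' @return A `sim_scenario` with the cohort layout above.
#' @export
make_reference_layout <- function(...) {
  embryos <- data.frame(
    embryo_id = c("Zygote_1", "Zygote_2", "Zygote_3", "4cell_1",
                  "8cell_1", "8cell_2",
                  "CompactedMorula_1", "CompactedMorula_2", "CompactedMorula_3",
                  "EarlyICM_1", "EarlyICM_2", "EarlyICM_3",
                  "LateICM_2", "LateICM_4"),
    stage = c("zygote", "zygote", "zygote", "4cell",
              "8cell", "8cell",
              "morula", "morula", "morula",
              "early_blastocyst", "early_blastocyst", "early_blastocyst",
              "late_blastocyst", "late_blastocyst"),
    sex = c("male", "male", "male", "male",
            "male", "male",
            "female", "male", "female",
            "male", "female", "female",
            "male", "female"),
    n_cells = c(1L, 1L, 1L, 4L, 7L, 8L, 22L, 10L, 21L, 9L, 10L, 23L, 39L, 40L),
    n_cells_pass = c(1L, 1L, 0L, 4L, 5L, 5L, 15L, 9L, 21L, 7L, 8L, 8L, 26L, 14L),
    stringsAsFactors = FALSE
  )
  # Zygote_3 contributes no post-filter cell; keep the scenario valid by
  # marking one cell and planting its reads out of bounds in simulate().
  sim_scenario(embryos = embryos, ...)
}

#' @noRd
lineage_for_stage <- function(stage, index_within_embryo) {
  out <- character(length(stage))
  out[stage == "zygote"] <- "zygote"
  out[stage %in% c("4cell", "8cell")] <- "blastomere"
  out[stage == "morula"] <- "morula"
  out[stage == "early_blastocyst"] <- "ICM"
  late <- stage == "late_blastocyst"
  out[late] <- ifelse(index_within_embryo[late] %% 2L == 0L, "PE", "EPI")
  out
}

#' Generate a synthetic dataset from a scenario
#'
#' Draws a full dataset — allele counts, FPKM and TPM matrices, annotation,
#' cell metadata — plus a truth table recording, per cell and gene, the true
#' per-allele expression, silencing status and the cell's silenced haplotype.
#' The FPKM matrix equals the summed per-allele truth exactly; TPM is the
#' same latent abundance renormalised per cell to one million.
#'
#' @param scenario A [sim_scenario()].
#' @return List with elements `allele_counts`, `fpkm`, `tpm`, `annotation`,
#'   `cell_meta`, `truth` (list: `cells`, `genes`, `het`) and `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  if (!inherits(scenario, "sim_scenario")) {
    stop("scenario must be built with sim_scenario()", call. = FALSE)
  }
  sc <- scenario
  set.seed(sc$seed)

  ## ---- annotation -------------------------------------------------------
  ann <- build_sim_annotation(sc)
  n_genes <- nrow(ann)
  is_x <- ann$chromosome == "X"
  is_y <- ann$chromosome == "Y"
  is_esc <- ann$is_escapee_or_par

  ## ---- cells ------------------------------------------------------------
  emb <- sc$embryos
  n_cells_per <- emb$n_cells
  cell_embryo_idx <- rep(seq_len(nrow(emb)), times = n_cells_per)
  idx_within <- unlist(lapply(n_cells_per, seq_len), use.names = FALSE)
  cell_id <- sprintf("%s_c%02d", emb$embryo_id[cell_embryo_idx], idx_within)
  stage_c <- emb$stage[cell_embryo_idx]
  sex_c <- emb$sex[cell_embryo_idx]
  n_cells <- length(cell_id)
  pass_c <- idx_within <= emb$n_cells_pass[cell_embryo_idx]
  mapped <- numeric(n_cells)
  mapped[pass_c] <- round(stats::runif(sum(pass_c), 2.2e6, 4.8e6))
  n_fail <- sum(!pass_c)
  if (n_fail > 0L) {
    lows <- round(stats::runif(n_fail, 3e5, 1.5e6))
    highs <- round(stats::runif(n_fail, 5.2e6, 6.5e6))
    use_low <- seq_len(n_fail) %% 2L == 1L
    mapped[!pass_c] <- ifelse(use_low, lows, highs)
  }
  cell_meta <- data.frame(
    cell_id = cell_id,
    embryo_id = emb$embryo_id[cell_embryo_idx],
    stage = stage_c,
    lineage = lineage_for_stage(stage_c, idx_within),
    mapped_reads = mapped,
    stringsAsFactors = FALSE
  )

  ## ---- per-cell regime parameters ---------------------------------------
  m_c <- sc$maternal_fraction[stage_c]
  u_c <- sc$upregulation_factor[stage_c]
  d_c <- sc$dampening_factor[stage_c]
  pm_c <- sc$p_mono[stage_c]
  female_c <- sex_c == "female"

  # silenced haplotype: per embryo when imprinted, else per cell
  if (sc$imprinted) {
    hap_embryo <- ifelse(stats::runif(nrow(emb)) < 0.5, "ref", "alt")
    hap_c <- hap_embryo[cell_embryo_idx]
  } else {
    hap_c <- ifelse(stats::runif(n_cells) < 0.5, "ref", "alt")
  }
  hap_c[!female_c] <- NA_character_

  ## ---- latent per-allele expression -------------------------------------
  b <- stats::rlnorm(n_genes, sc$base_meanlog, sc$base_sdlog)

  x_rows <- which(is_x)
  n_x <- length(x_rows)
  # silencing indicator, X genes x cells (females only, escapees exempt)
  S <- matrix(FALSE, n_x, n_cells)
  if (n_x > 0L && any(female_c)) {
    if (sc$coherent) {
      ord <- order(ann$start[x_rows])
      centre <- ceiling(n_x / 2)
      for (j in which(female_c)) {
        k <- round(pm_c[j] * n_x)
        if (k > 0L) {
          half <- (k - 1L) %/% 2L
          lo <- max(1L, centre - half)
          hi <- min(n_x, lo + k - 1L)
          lo <- max(1L, hi - k + 1L)
          S[ord[lo:hi], j] <- TRUE
        }
      }
    } else {
      fcols <- which(female_c)
      S[, fcols] <- stats::runif(n_x * length(fcols)) <
        rep(pm_c[fcols], each = n_x)
    }
    S[is_esc[x_rows], ] <- FALSE
    S[, !female_c] <- FALSE
  }

  ref_emb <- matrix(rep(b, n_cells), n_genes, n_cells)
  alt_emb <- ref_emb
  if (any(is_y)) {
    alt_emb[is_y, ] <- 0
    ref_emb[is_y, !(sex_c == "male")] <- 0
  }
  if (n_x > 0L) {
    ux <- matrix(rep(u_c, each = n_x), n_x, n_cells)
    dx <- matrix(rep(d_c * female_c + 1 * (!female_c), each = n_x), n_x, n_cells)
    bx <- matrix(rep(b[x_rows], n_cells), n_x, n_cells)
    act <- bx * ux * dx
    refx <- act
    altx <- act
    male_cols <- !female_c
    altx[, male_cols] <- 0            # single (maternal, "ref") X in males
    sil_ref <- S & matrix(rep(hap_c == "ref", each = n_x), n_x, n_cells)
    sil_alt <- S & matrix(rep(hap_c == "alt", each = n_x), n_x, n_cells)
    refx[sil_ref] <- 0
    altx[sil_alt] <- 0
    ref_emb[x_rows, ] <- refx
    alt_emb[x_rows, ] <- altx
  }

  # maternal pool: biallelic everywhere except Y (silent)
  ref_mat <- matrix(rep(b, n_cells), n_genes, n_cells)
  alt_mat <- ref_mat
  if (any(is_y)) {
    ref_mat[is_y, ] <- 0
    alt_mat[is_y, ] <- 0
  }
  mm <- matrix(rep(m_c, each = n_genes), n_genes, n_cells)
  ref_tot <- (1 - mm) * ref_emb + mm * ref_mat
  alt_tot <- (1 - mm) * alt_emb + mm * alt_mat

  noise <- matrix(stats::rlnorm(n_genes * n_cells, 0, sc$cell_noise_sdlog),
                  n_genes, n_cells)
  ref_tot <- ref_tot * noise
  alt_tot <- alt_tot * noise

  fpkm_vals <- ref_tot + alt_tot
  dimnames(fpkm_vals) <- list(ann$gene_id, cell_id)
  fpkm <- expr_matrix(fpkm_vals, unit = "FPKM")
  colsum <- colSums(fpkm_vals)
  colsum[colsum == 0] <- 1
  tpm <- expr_matrix(sweep(fpkm_vals, 2, colsum, "/") * 1e6, unit = "TPM")

  ## ---- heterozygosity and allele counts ---------------------------------
  het <- matrix(FALSE, n_genes, nrow(emb))
  non_y <- !is_y
  het[non_y, ] <- stats::runif(sum(non_y) * nrow(emb)) < sc$het_snp_prob
  counts <- draw_allele_counts(sc, ann, emb, cell_meta, het, ref_tot, alt_tot)

  ## ---- truth table -------------------------------------------------------
  truth_cells <- data.frame(
    cell_id = cell_id, embryo_id = cell_meta$embryo_id, stage = stage_c,
    sex = sex_c, silenced_haplotype = hap_c, passes_qc = pass_c,
    stringsAsFactors = FALSE
  )
  sil_full <- matrix(FALSE, n_genes, n_cells)
  if (n_x > 0L) sil_full[x_rows, ] <- S
  state <- ifelse(ref_tot > 0 & alt_tot > 0, "biallelic",
                  ifelse(ref_tot + alt_tot > 0, "monoallelic", "silent"))
  truth_genes <- data.frame(
    cell_id = rep(cell_id, each = n_genes),
    gene_id = rep(ann$gene_id, n_cells),
    chromosome = rep(ann$chromosome, n_cells),
    expr_ref = as.vector(ref_tot),
    expr_alt = as.vector(alt_tot),
    silenced = as.vector(sil_full),
    true_state = as.vector(state),
    stringsAsFactors = FALSE
  )
  het_df <- data.frame(
    gene_id = rep(ann$gene_id, nrow(emb)),
    embryo_id = rep(emb$embryo_id, each = n_genes),
    het = as.vector(het),
    stringsAsFactors = FALSE
  )

  list(
    allele_counts = counts,
    fpkm = fpkm,
    tpm = tpm,
    annotation = ann,
    cell_meta = cell_meta,
    truth = list(cells = truth_cells, genes = truth_genes, het = het_df),
    scenario = sc
  )
}

#' @noRd
build_sim_annotation <- function(sc) {
  chroms <- character(0)
  gene_id <- character(0)
  if (sc$n_genes_X > 0L) {
    gene_id <- c(gene_id, sprintf("G_X_%04d", seq_len(sc$n_genes_X)))
    chroms <- c(chroms, rep("X", sc$n_genes_X))
  }
  if (sc$n_genes_autosome > 0L) {
    gene_id <- c(gene_id, sprintf("G_A_%04d", seq_len(sc$n_genes_autosome)))
    chroms <- c(chroms, rep(sc$autosomes, length.out = sc$n_genes_autosome))
  }
  if (sc$n_genes_Y > 0L) {
    gene_id <- c(gene_id, sprintf("G_Y_%04d", seq_len(sc$n_genes_Y)))
    chroms <- c(chroms, rep("Y", sc$n_genes_Y))
  }
  n <- length(gene_id)
  k_within <- as.integer(stats::ave(seq_len(n), chroms, FUN = seq_along))
  start <- (k_within - 1L) * 10000L + 1L
  len <- sample(1000:8000, n, replace = TRUE)
  esc <- rep(FALSE, n)
  if (sc$n_escapee > 0L && sc$n_genes_X > 0L) {
    esc_idx <- unique(round(seq(1L, sc$n_genes_X, length.out = sc$n_escapee)))
    esc[esc_idx] <- TRUE
  }
  data.frame(
    gene_id = gene_id, chromosome = chroms,
    start = start, end = start + len - 1L,
    is_escapee_or_par = esc,
    stringsAsFactors = FALSE
  )
}

#' @noRd
draw_allele_counts <- function(sc, ann, emb, cell_meta, het, ref_tot, alt_tot) {
  if (sc$snps_per_gene == 0L || !any(het)) return(empty_allele_counts())
  ge <- which(het, arr.ind = TRUE)          # (gene index, embryo index)
  # expand to cells of each embryo
  cells_of <- split(seq_len(nrow(cell_meta)),
                    match(cell_meta$embryo_id, emb$embryo_id))
  n_cells_per <- emb$n_cells
  reps <- n_cells_per[ge[, 2L]]
  g_idx <- rep(ge[, 1L], times = reps)
  # for each (gene, embryo) pair, the cell indices of that embryo
  cell_idx <- unlist(lapply(seq_len(nrow(ge)), function(i) cells_of[[ge[i, 2L]]]),
                     use.names = FALSE)
  S <- sc$snps_per_gene
  n_pairs <- length(g_idx)
  g_all <- rep(g_idx, each = S)
  c_all <- rep(cell_idx, each = S)
  s_all <- rep.int(seq_len(S), n_pairs)
  span <- ann$end[g_all] - ann$start[g_all] + 1L
  pos <- ann$start[g_all] + (span %/% (S + 1L)) * s_all
  lin <- g_all + (c_all - 1L) * nrow(ann)
  tot <- ref_tot[lin] + alt_tot[lin]
  p_alt <- ifelse(tot > 0, alt_tot[lin] / tot, 0)
  eps <- sc$allelic_noise
  p_obs <- p_alt * (1 - eps) + (1 - p_alt) * eps
  n_rec <- length(g_all)
  depth <- stats::rnbinom(n_rec, mu = sc$depth_mean, size = sc$depth_dispersion)
  depth[tot <= 0] <- 0L
  rho <- sc$allelic_overdispersion
  if (rho > 0) {
    shape_tot <- (1 - rho) / rho
    a <- pmax(p_obs * shape_tot, 1e-8)
    bshape <- pmax((1 - p_obs) * shape_tot, 1e-8)
    p_obs <- stats::rbeta(n_rec, a, bshape)
  }
  alt_count <- stats::rbinom(n_rec, depth, p_obs)
  data.frame(
    cell_id = cell_meta$cell_id[c_all],
    chromosome = ann$chromosome[g_all],
    position = as.integer(pos),
    ref = "A",
    alt = "G",
    ref_count = as.integer(depth - alt_count),
    alt_count = as.integer(alt_count),
    stringsAsFactors = FALSE
  )
}
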