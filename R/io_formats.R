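# File formats and in-memory containers shared by the whole pipeline.
#
# Conventions:
#   * chromosomes are stored without a "chr" prefix ("X", "Y", "10", ...)
#   * genomic coordinates are 1-based inclusive (VCF convention); BED input
#     (0-based half-open) is converted at the boundary
#   * expression matrices are genes x cells with an explicit unit attribute

#' Ordered developmental stage vocabulary
#'
#' The closed, ordered set of preimplantation stages the pipeline recognises,
#' from zygote to late blastocyst. Stage ranks (1-6) follow this order and are
#' used wherever a stage must be treated as ordinal (e.g. trend tests).
#'
#' @return Character vector of the six stage labels in developmental order.
#' @export
stage_levels <- function() {
  c("zygote", "4cell", "8cell", "morula", "early_blastocyst", "late_blastocyst")
}

#' @noRd
stage_rank <- function(stage) {
  match(stage, stage_levels())
}

# strip an optional "chr" prefix so "chrX" and "X" compare equal
#' @noRd
norm_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

#' @noRd
assert_stages <- function(stage, what = "stage") {
  bad <- setdiff(unique(as.character(stage)), stage_levels())
  if (length(bad) > 0L) {
    stop(sprintf(
      "unknown %s label(s): %s; valid stages are: %s",
      what, paste(bad, collapse = ", "), paste(stage_levels(), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct an expression matrix with a declared unit
#'
#' A thin container: a non-negative numeric genes x cells matrix carrying the
#' normalisation unit as an attribute. The unit is always declared by the
#' caller, never inferred, because FPKM/TPM conversion requires gene lengths
#' that are not generally recoverable from a matrix alone.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), cells in
#'   columns (colnames = cell ids). All values must be finite and >= 0.
#' @param unit One of `"FPKM"`, `"TPM"`, `"raw_counts"`.
#' @return An `expr_matrix` object (numeric matrix with a `unit` attribute).
#' @export
expr_matrix <- function(values, unit = c("FPKM", "TPM", "raw_counts")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix must have gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene_id in expression matrix: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  neg <- which(values < 0 | !is.finite(values), arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative or non-finite expression value for gene %s in cell %s",
                 rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]]),
         call. = FALSE)
  }
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Unit of an expression matrix
#' @param x An `expr_matrix`.
#' @return The declared unit string.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("matrix carries no unit attribute; build it with expr_matrix()", call. = FALSE)
  u
}

#' @noRd
assert_unit <- function(x, unit) {
  if (!identical(expr_unit(x), unit)) {
    stop(sprintf("expected a %s matrix but got %s", unit, expr_unit(x)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read per-cell, per-SNP allele read counts
#'
#' Allelic counts are the primary input of the allele-specific analysis: for
#' every cell and every single-nucleotide variant, the number of reads
#' supporting the reference and the alternative base. Two dialects are
#' supported: a 7-column TSV (`cell_id, chromosome, position, ref, alt,
#' ref_count, alt_count`) and VCF 4.x with a per-sample `AD` (allele depth)
#' field, where each VCF sample is one cell.
#'
#' Only biallelic single-nucleotide variants are kept. Multi-allelic records
#' are skipped (not decomposed) with a warning reporting how many were
#' dropped, and indel records are skipped the same way.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A data.frame with columns `cell_id`, `chromosome`, `position`,
#'   `ref`, `alt`, `ref_count`, `alt_count`; zero rows for an empty file.
#' @export
read_allele_counts <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") read_allele_counts_tsv(path) else read_allele_counts_vcf(path)
}

#' @noRd
read_allele_counts_tsv <- function(path) {
  cols <- c("cell_id", "chromosome", "position", "ref", "alt", "ref_count", "alt_count")
  if (length(readLines(path, n = 1L)) == 0L) return(empty_allele_counts())
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = FALSE)
  if (nrow(raw) == 0L) return(empty_allele_counts())
  has_header <- identical(tolower(as.character(raw[1L, 1L])), "cell_id")
  body <- if (has_header) raw[-1L, , drop = FALSE] else raw
  offset <- if (has_header) 1L else 0L
  if (nrow(body) == 0L) return(empty_allele_counts())
  if (ncol(body) != 7L) {
    stop(sprintf("malformed allele-count TSV %s: expected 7 columns, found %d",
                 path, ncol(body)), call. = FALSE)
  }
  names(body) <- cols
  pos <- suppressWarnings(as.integer(body$position))
  rc  <- suppressWarnings(as.numeric(body$ref_count))
  ac  <- suppressWarnings(as.numeric(body$alt_count))
  bad <- which(is.na(pos) | is.na(rc) | is.na(ac) | rc < 0 | ac < 0 |
                 !body$ref %in% c("A", "C", "G", "T") |
                 !body$alt %in% c("A", "C", "G", "T") |
                 body$ref == body$alt)
  if (length(bad) > 0L) {
    stop(sprintf("malformed allele-count row at line %d of %s",
                 bad[1L] + offset, path), call. = FALSE)
  }
  out <- data.frame(
    cell_id = body$cell_id,
    chromosome = norm_chrom(body$chromosome),
    position = pos,
    ref = body$ref,
    alt = body$alt,
    ref_count = as.integer(round(rc)),
    alt_count = as.integer(round(ac)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @noRd
empty_allele_counts <- function() {
  data.frame(cell_id = character(), chromosome = character(),
             position = integer(), ref = character(), alt = character(),
             ref_count = integer(), alt_count = integer(),
             stringsAsFactors = FALSE)
}

#' @noRd
read_allele_counts_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_allele_counts())
  snv <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- snv & !multi
  n_skip <- sum(!keep)
  if (n_skip > 0L) {
    warning(sprintf("skipped %d multi-allelic or non-SNV record(s) in %s",
                    n_skip, path), call. = FALSE)
  }
  if (!any(keep)) return(empty_allele_counts())
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop("VCF carries no per-sample AD field: ", path, call. = FALSE)
  ad <- ad[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  cells <- colnames(ad)
  n_site <- nrow(fix)
  split_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  }
  counts <- split_ad(as.vector(ad))
  out <- data.frame(
    cell_id = rep(cells, each = n_site),
    chromosome = rep(norm_chrom(fix$CHROM), times = length(cells)),
    position = rep(as.integer(fix$POS), times = length(cells)),
    ref = rep(fix$REF, times = length(cells)),
    alt = rep(fix$ALT, times = length(cells)),
    ref_count = counts[, 1L],
    alt_count = counts[, 2L],
    stringsAsFactors = FALSE
  )
  out$ref_count[is.na(out$ref_count)] <- 0L
  out$alt_count[is.na(out$alt_count)] <- 0L
  rownames(out) <- NULL
  out
}

#' Write allele counts in the 7-column TSV dialect
#' @param counts Data.frame as returned by [read_allele_counts()].
#' @param path Output path.
#' @export
write_allele_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a genes x cells expression table
#'
#' Tab-separated, first column gene ids, header row of cell ids. Values must
#' be non-negative; duplicated gene ids and negative values are errors.
#'
#' @param path Path to the TSV.
#' @param unit Declared unit of the values (never inferred).
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, unit = c("FPKM", "TPM", "raw_counts")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  gene_id <- as.character(tab[[1L]])
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in expression table: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_id
  expr_matrix(m, unit = unit)
}

#' Write an expression matrix as TSV (inverse of [read_expression()])
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (BED4+)
#'
#' BED input uses 0-based half-open coordinates; they are converted once here
#' to the internal 1-based inclusive convention (`start = bed_start + 1`,
#' `end = bed_end`). An optional 5th column (0/1) flags genes on a
#' user-supplied exclusion list of inactivation escapees and pseudoautosomal
#' homologues; when absent the flag defaults to `FALSE` for every gene. The
#' list is an input: which genes escape silencing is treated as prior
#' knowledge, not something the pipeline computes.
#'
#' @param path Path to a BED4 or BED5 file (no header).
#' @return Data.frame with `gene_id`, `chromosome`, `start`, `end`,
#'   `is_escapee_or_par`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("annotation needs >= 4 BED columns: ", path, call. = FALSE)
  start <- as.integer(tab[[2L]]) + 1L
  end <- as.integer(tab[[3L]])
  if (any(is.na(start) | is.na(end) | start > end)) {
    stop("invalid coordinates (need start <= end) in ", path, call. = FALSE)
  }
  flag <- if (ncol(tab) >= 5L) as.integer(tab[[5L]]) == 1L else rep(FALSE, nrow(tab))
  out <- data.frame(
    gene_id = as.character(tab[[4L]]),
    chromosome = norm_chrom(tab[[1L]]),
    start = start,
    end = end,
    is_escapee_or_par = flag,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write gene annotation as BED5 (inverse of [read_annotation()])
#' @param annotation Data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  bed <- data.frame(
    chrom = annotation$chromosome,
    start = annotation$start - 1L,
    end = annotation$end,
    name = annotation$gene_id,
    flag = as.integer(annotation$is_escapee_or_par)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-cell metadata
#'
#' TSV with header columns `cell_id, embryo_id, stage, lineage, mapped_reads`.
#' `mapped_reads` is the number of reads assigned to genes for that cell and
#' drives the read-depth quality filter. Stage labels must come from
#' [stage_levels()].
#'
#' @param path Path to the TSV.
#' @return Data.frame of cell metadata, one row per cell.
#' @export
read_cell_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell_id", "embryo_id", "stage", "lineage", "mapped_reads")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("cell metadata missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  assert_stages(tab$stage)
  if (anyDuplicated(tab$cell_id)) {
    stop("duplicate cell_id in metadata: ",
         paste(unique(tab$cell_id[duplicated(tab$cell_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(tab$mapped_reads) | tab$mapped_reads < 0)) {
    stop("mapped_reads must be a non-negative count for every cell", call. = FALSE)
  }
  tab$mapped_reads <- as.numeric(tab$mapped_reads)
  tab[, need]
}

#' Write cell metadata (inverse of [read_cell_meta()])
#' @param meta Data.frame of cell metadata.
#' @param path Output path.
#' @export
write_cell_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the pipeline report bundle
#'
#' Emits the machine-readable tables produced by a pipeline run — per-cell
#' dosage summaries and the stage/sex comparison statistics — plus a short
#' plain-text summary, into a directory.
#'
#' @param results A list as returned by [run_pipeline()], with at least
#'   `cell_summaries` and `comparisons` data.frames.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("cell_summaries", "comparisons", "sex_calls", "informative_counts")) {
    if (!is.null(results[[nm]])) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(results[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  summary_path <- file.path(dir, "summary.txt")
  lines <- c(
    "xciscope pipeline report",
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(results$seed)) sprintf("seed: %d", results$seed),
    if (!is.null(results$n_cells_total)) sprintf("cells before QC: %d", results$n_cells_total),
    if (!is.null(results$n_cells_retained)) sprintf("cells after QC: %d", results$n_cells_retained),
    if (!is.null(results$sex_calls))
      sprintf("sexed embryos: %d male, %d female, %d unsexed",
              sum(results$sex_calls$call == "male"),
              sum(results$sex_calls$call == "female"),
              sum(results$sex_calls$call == "unsexed")),
    if (!is.null(results$excluded_x_genes))
      sprintf("X genes excluded from allele-specific analyses: %d",
              length(results$excluded_x_genes)),
    if (!is.null(results$dampening))
      sprintf("dampening verdict: %s", results$dampening$verdict)
  )
  writeLines(lines, summary_path)
  if (!is.null(results$excluded_x_genes)) {
    writeLines(results$excluded_x_genes, file.path(dir, "excluded_x_genes.txt"))
  }
  invisible(c(paths, summary_path))
}
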