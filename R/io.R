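#' Read a beta-value matrix from TSV/CSV
#'
#' Expects probe IDs in the first column and sample IDs in the header.
#' Validates that every value is numeric and inside \[0, 1\] (offending probe
#' and sample are named), and that probe IDs are unique. Empty cells become
#' missing values. Delimiter is inferred from the extension (`.csv` = comma,
#' otherwise tab); gzip-compressed files are read transparently.
#'
#' @param path Path to the file.
#' @return Numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) abort("beta matrix needs a probe-ID column plus sample columns.")
  probes <- as.character(df[[1]])
  dup <- probes[duplicated(probes)]
  if (length(dup)) {
    abort(sprintf("duplicate probe ID(s): %s", paste(unique(dup), collapse = ", ")))
  }
  vals <- df[, -1, drop = FALSE]
  notnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(notnum)) {
    abort(sprintf("non-numeric beta column(s): %s", paste(notnum, collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- probes
  as_beta_matrix(m, arg = basename(path))
}

#' Write a beta-value matrix as TSV
#'
#' @param beta Probes x samples matrix.
#' @param path Output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  beta <- as_beta_matrix(beta)
  df <- bind_cols(tibble(probe_id = rownames(beta)), as_tibble(beta))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' @param path TSV with columns `probe_id`, `gene`, `dist_to_tss_bp`,
#'   `platform_450k`, `platform_epic`.
#' @return Tibble.
#' @export
read_probe_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe_id", "gene", "dist_to_tss_bp", "platform_450k", "platform_epic")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ann
}

#' Read a gene signature table
#'
#' @param path TSV with columns `gene` and `cell_type`.
#' @return Tibble.
#' @export
read_signature <- function(path) {
  sig <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "cell_type") %in% names(sig))) {
    abort("signature file needs columns gene and cell_type.")
  }
  sig
}

#' Read a clinical table
#'
#' @param path TSV with at least `sample_id`, `time`, `event`.
#' @return Tibble.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "time", "event") %in% names(cl))) {
    abort("clinical file needs columns sample_id, time, event.")
  }
  cl
}

write_stage_tsv <- function(df, dir, name) {
  readr::write_tsv(as_tibble(df), file.path(dir, name), progress = FALSE)
}

#' Write all artifacts of a synthetic simulation to a directory
#'
#' @param panel A `reference_panel`.
#' @param cohort A `tumor_cohort` (optional).
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(panel, cohort = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(panel$beta, file.path(outdir, "reference_beta.tsv"))
  write_stage_tsv(panel$sample_info, outdir, "reference_samples.tsv")
  write_stage_tsv(panel$annotation, outdir, "probe_annotation.tsv")
  write_stage_tsv(panel$signature_a, outdir, "signature_a.tsv")
  write_stage_tsv(panel$signature_b, outdir, "signature_b.tsv")
  write_stage_tsv(panel$truth$marker_map, outdir, "truth_marker_map.tsv")
  if (!is.null(cohort)) {
    write_beta_matrix(cohort$beta, file.path(outdir, "cohort_beta.tsv"))
    write_stage_tsv(cohort$clinical, outdir, "clinical.tsv")
    expr <- bind_cols(tibble(gene = rownames(cohort$expression)),
                      as_tibble(cohort$expression))
    readr::write_tsv(expr, file.path(outdir, "expression.tsv"), progress = FALSE)
    write_stage_tsv(cohort$pten$annotation, outdir, "pten_annotation.tsv")
    write_stage_tsv(cohort$pten$mutation, outdir, "pten_mutations.tsv")
    write_stage_tsv(cohort$pten$cna, outdir, "pten_cna.tsv")
    write_stage_tsv(cohort$truth$cluster_labels, outdir, "truth_clusters.tsv")
    infil <- bind_cols(tibble(sample_id = rownames(cohort$truth$infiltration)),
                       as_tibble(cohort$truth$infiltration))
    readr::write_tsv(infil, file.path(outdir, "truth_infiltration.tsv"),
                     progress = FALSE)
    write_stage_tsv(cohort$truth$pten, outdir, "truth_pten.tsv")
  }
  invisible(outdir)
}
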