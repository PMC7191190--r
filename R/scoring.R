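#' Per-cell-type methylation scores
#'
#' For each sample and immune cell type, the score is the median beta over
#' all of that cell type's signature CpGs present in the matrix (missing
#' values omitted). A cell type none of whose CpGs are present yields a
#' missing column and a message, mirroring cohorts where no CpG survived
#' filtering.
#'
#' @param beta Beta matrix (probes x samples) or data frame.
#' @param pairs Gene-CpG pairs: an `immune_selection` object or a tibble with
#'   columns `cpg` and `cell_type`.
#' @return An `immune_scores` tibble: `sample_id` plus one column per cell
#'   type, with attributes `modality = "methylation"` and `centered = FALSE`.
#' @export
methylation_score <- function(beta, pairs) {
  beta <- as_beta_matrix(beta)
  if (inherits(pairs, "immune_selection")) pairs <- pairs$pairs
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) abort("`pairs` is empty.")
  if (!all(c("cpg", "cell_type") %in% names(pairs))) {
    abort("`pairs` needs columns cpg and cell_type.")
  }
  types <- unique(pairs$cell_type)
  scores <- purrr::map(types, function(ct) {
    cpgs <- intersect(pairs$cpg[pairs$cell_type == ct], rownames(beta))
    if (!length(cpgs)) {
      inform(sprintf("cell type '%s': no CpG present in the matrix; score is NA.", ct))
      return(rep(NA_real_, ncol(beta)))
    }
    unname(apply(beta[cpgs, , drop = FALSE], 2, median, na.rm = TRUE))
  })
  out <- bind_cols(tibble(sample_id = colnames(beta)),
                   as_tibble(setNames(scores, types)))
  new_scores(out, modality = "methylation", centered = FALSE)
}

#' Per-cell-type expression scores
#'
#' Optionally median-centers each gene across samples, then takes the median
#' over each cell type's signature genes per sample. Centered scores are the
#' cohort-mode convention; noncentered scores are used when comparing across
#' cohorts.
#'
#' @param expression Genes x samples numeric matrix (rownames = gene symbols,
#'   matched case-sensitively).
#' @param signature Data frame with `gene` and `cell_type` (e.g. from
#'   [combine_signatures()]).
#' @param center Median-center each gene across samples first?
#' @return An `immune_scores` tibble with `modality = "expression"`.
#' @export
expression_score <- function(expression, signature, center = TRUE) {
  if (is.data.frame(expression)) {
    ids <- as.character(expression[[1]])
    expression <- as.matrix(expression[, -1, drop = FALSE])
    rownames(expression) <- ids
  }
  if (!is.matrix(expression) || !is.numeric(expression)) {
    abort("`expression` must be a numeric genes x samples matrix.")
  }
  signature <- as_tibble(signature)
  genes <- intersect(signature$gene, rownames(expression))
  if (!length(genes)) abort("no overlapping genes between expression matrix and signature.")
  x <- expression[genes, , drop = FALSE]
  if (center) {
    x <- x - apply(x, 1, median, na.rm = TRUE)
  }
  types <- unique(signature$cell_type[signature$gene %in% genes])
  scores <- purrr::map(types, function(ct) {
    g <- intersect(signature$gene[signature$cell_type == ct], genes)
    unname(apply(x[g, , drop = FALSE], 2, median, na.rm = TRUE))
  })
  out <- bind_cols(tibble(sample_id = colnames(expression)),
                   as_tibble(setNames(scores, types)))
  new_scores(out, modality = "expression", centered = center)
}

new_scores <- function(df, modality, centered) {
  class(df) <- c("immune_scores", class(df))
  attr(df, "modality") <- modality
  attr(df, "centered") <- centered
  df
}

#' Dichotomize methylation scores at beta 0.7
#'
#' Scores strictly above 0.7 are hypermethylated; scores at or below 0.7 are
#' not. Applies only to methylation-modality scores (expression scores are
#' unbounded and refuse).
#'
#' @param score An `immune_scores` tibble (methylation modality) or a bare
#'   numeric vector of beta-scale scores.
#' @param threshold Cut point; default 0.7 (strictly above = hypermethylated).
#' @return Same shape as the input with values
#'   `"hypermethylated"` / `"not_hypermethylated"` (NA preserved).
#' @export
#' @examples
#' dichotomize_score(c(0.70, 0.71, 0))
dichotomize_score <- function(score, threshold = 0.7) {
  check_fraction(threshold, "threshold", open = TRUE)
  cut1 <- function(x) {
    ifelse(is.na(x), NA_character_,
           ifelse(x > threshold, "hypermethylated", "not_hypermethylated"))
  }
  if (is.numeric(score)) return(cut1(score))
  if (!inherits(score, "immune_scores")) {
    abort("`score` must be an immune_scores object or numeric vector.")
  }
  if (!identical(attr(score, "modality"), "methylation")) {
    abort("dichotomization is defined for methylation scores only.")
  }
  out <- as_tibble(score)
  for (nm in setdiff(names(out), "sample_id")) out[[nm]] <- cut1(out[[nm]])
  out
}
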