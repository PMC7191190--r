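#' Selection parameters for the immune CpG signature pipeline
#'
#' Thresholds controlling each filtering step. `mode` switches the nonimmune
#' hypermethylation sample fraction between the melanoma default (> 98% of
#' nonimmune samples with beta > 0.7) and the relaxed pan-cancer default
#' (> 90%), used when filtering against tumor cell-line methylomes whose
#' tumor types contain deviating minority lines.
#'
#' @param tss_max_distance_bp Promoter window: probes with
#'   `abs(distance to TSS) < tss_max_distance_bp` are candidates (strict).
#' @param binarize_threshold Beta below which a value is called unmethylated.
#' @param fdr_threshold Benjamini-Hochberg FDR gate on the Fisher exact test.
#' @param nonimmune_beta_threshold Beta above which a nonimmune sample counts
#'   as methylated (strict).
#' @param nonimmune_sample_fraction Required fraction of nonimmune samples
#'   above `nonimmune_beta_threshold` (strict); defaults to 0.98 or 0.90 by
#'   `mode`.
#' @param mode `"melanoma"` or `"pancancer"`.
#' @return A `selection_params` list.
#' @export
selection_params <- function(tss_max_distance_bp = 1500,
                             binarize_threshold = 0.3,
                             fdr_threshold = 0.01,
                             nonimmune_beta_threshold = 0.7,
                             nonimmune_sample_fraction = NULL,
                             mode = c("melanoma", "pancancer")) {
  mode <- match.arg(mode)
  if (is.null(nonimmune_sample_fraction)) {
    nonimmune_sample_fraction <- if (mode == "melanoma") 0.98 else 0.90
  }
  if (!is.numeric(tss_max_distance_bp) || tss_max_distance_bp <= 0) {
    abort("`tss_max_distance_bp` must be positive.")
  }
  check_fraction(binarize_threshold, "binarize_threshold", open = TRUE)
  check_fraction(fdr_threshold, "fdr_threshold", open = TRUE)
  check_fraction(nonimmune_beta_threshold, "nonimmune_beta_threshold", open = TRUE)
  check_fraction(nonimmune_sample_fraction, "nonimmune_sample_fraction", open = TRUE)
  structure(list(tss_max_distance_bp = tss_max_distance_bp,
                 binarize_threshold = binarize_threshold,
                 fdr_threshold = fdr_threshold,
                 nonimmune_beta_threshold = nonimmune_beta_threshold,
                 nonimmune_sample_fraction = nonimmune_sample_fraction,
                 mode = mode),
            class = "selection_params")
}

#' Combine two gene signatures, removing conflicting assignments
#'
#' Takes the union of two gene -> immune cell type signatures. Genes present
#' in both sources with the same cell type are kept once; genes assigned to
#' different cell types in the two sources are conflicts and removed.
#'
#' @param sig_a,sig_b Data frames with columns `gene` and `cell_type`.
#' @return A tibble (`gene`, `cell_type`, `source`) with attributes
#'   `conflicts` (tibble of removed genes) and `n_conflicts`.
#' @export
#' @examples
#' a <- data.frame(gene = c("CD19", "GZMB"), cell_type = c("B cells", "NK cells"))
#' b <- data.frame(gene = c("CD19", "GZMB"), cell_type = c("B cells", "CD8 T cells"))
#' combine_signatures(a, b)   # GZMB conflicts and is dropped
combine_signatures <- function(sig_a, sig_b) {
  check_sig <- function(s, nm) {
    if (!is.data.frame(s) || nrow(s) == 0 ||
        !all(c("gene", "cell_type") %in% names(s))) {
      abort(sprintf("`%s` must be a non-empty data frame with columns gene, cell_type.", nm))
    }
    distinct(as_tibble(s)[, c("gene", "cell_type")])
  }
  a <- check_sig(sig_a, "sig_a")
  b <- check_sig(sig_b, "sig_b")
  if (anyDuplicated(a$gene) || anyDuplicated(b$gene)) {
    abort("a signature assigns the same gene to multiple cell types; fix the input.")
  }
  merged <- dplyr::full_join(a, b, by = "gene", suffix = c("_a", "_b"))
  conflict <- !is.na(merged$cell_type_a) & !is.na(merged$cell_type_b) &
    merged$cell_type_a != merged$cell_type_b
  conflicts <- merged[conflict, ] |>
    dplyr::transmute(gene = .data$gene, cell_type_a = .data$cell_type_a,
                     cell_type_b = .data$cell_type_b)
  out <- merged[!conflict, ] |>
    mutate(
      cell_type = dplyr::coalesce(.data$cell_type_a, .data$cell_type_b),
      source = dplyr::case_when(
        !is.na(.data$cell_type_a) & !is.na(.data$cell_type_b) ~ "both",
        !is.na(.data$cell_type_a) ~ "a",
        TRUE ~ "b"
      )
    ) |>
    select("gene", "cell_type", "source") |>
    arrange(.data$gene)
  if (nrow(out) == 0) abort("no genes left after conflict removal.")
  attr(out, "conflicts") <- conflicts
  attr(out, "n_conflicts") <- nrow(conflicts)
  out
}

#' Map signature genes to candidate promoter CpGs
#'
#' Candidates are probes whose absolute distance to the TSS is strictly below
#' the promoter window, whose gene belongs to the combined signature, and
#' which are present on both the 450K and EPIC platforms.
#'
#' @param signature Combined signature from [combine_signatures()] (or any
#'   data frame with `gene`, `cell_type`).
#' @param annotation Probe annotation with columns `probe_id`, `gene`,
#'   `dist_to_tss_bp` (signed or absolute), `platform_450k`, `platform_epic`.
#' @param params A [selection_params()].
#' @return Tibble of candidate CpGs (`probe_id`, `gene`, `cell_type`,
#'   `dist_to_tss_bp`).
#' @export
map_promoter_cpgs <- function(signature, annotation,
                              params = selection_params()) {
  need <- c("probe_id", "gene", "dist_to_tss_bp", "platform_450k", "platform_epic")
  missing_cols <- setdiff(need, names(annotation))
  if (length(missing_cols)) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_tibble(annotation) |>
    filter(abs(.data$dist_to_tss_bp) < params$tss_max_distance_bp,
           .data$platform_450k, .data$platform_epic) |>
    inner_join(as_tibble(signature)[, c("gene", "cell_type")], by = "gene") |>
    select("probe_id", "gene", "cell_type", "dist_to_tss_bp") |>
    arrange(.data$probe_id)
}

#' Dichotomize beta values into methylation bins
#'
#' Values strictly below `threshold` are unmethylated (0); values at or above
#' it are methylated (1). Missing values propagate.
#'
#' @param beta Probes x samples beta matrix (or data frame).
#' @param threshold Binarization cut point in (0, 1); default 0.3.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize_beta <- function(beta, threshold = 0.3) {
  check_fraction(threshold, "threshold", open = TRUE)
  beta <- as_beta_matrix(beta)
  out <- (beta >= threshold) + 0L
  storage.mode(out) <- "integer"
  out
}

# r x 2 exact test on a (cell types x {unmethylated, methylated}) table.
# fisher.test computes the exact conditional test for r x c tables (the
# Freeman-Halton extension); a seeded Monte-Carlo p is used for large tables.
exact_rx2_test <- function(tab, mc_total = 300, mc_B = 1e5) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2 || any(colSums(tab) == sum(tab))) {
    return(list(p = 1, method = "degenerate"))
  }
  if (sum(tab) <= mc_total) {
    list(p = fisher.test(tab)$p.value, method = "exact")
  } else {
    p <- withr::with_seed(
      20200321,
      fisher.test(tab, simulate.p.value = TRUE, B = mc_B)$p.value
    )
    list(p = p, method = "monte-carlo")
  }
}

#' Fisher exact test for differential methylation across reference cell types
#'
#' For each CpG, builds the (cell types x \{unmethylated, methylated\})
#' contingency table of reference-sample counts from a binarized beta matrix
#' and computes a two-sided exact p-value (Freeman-Halton r x 2), followed by
#' Benjamini-Hochberg FDR across all candidate CpGs. Missing entries are
#' omitted from the counts; CpGs with more than `max_missing` missing
#' reference values are excluded from testing and FDR ranking (flagged).
#'
#' @param binary 0/1 matrix (probes x reference immune samples) from
#'   [binarize_beta()].
#' @param cell_types Character vector of cell-type labels, one per column.
#' @param max_missing Maximum tolerated fraction of missing values per CpG.
#' @return Tibble (`probe_id`, `p`, `fdr`, `n_used`, `method`, `excluded`).
#' @export
fisher_differential <- function(binary, cell_types, max_missing = 0.2) {
  if (is.data.frame(binary)) binary <- as_beta_matrix(binary)
  if (ncol(binary) != length(cell_types)) {
    abort("`cell_types` must have one label per column of `binary`.")
  }
  types <- unique(cell_types)
  if (length(types) < 2) abort("need at least 2 cell types.")
  if (any(table(cell_types) < 2)) abort("need at least 2 samples per cell type.")

  res <- purrr::map(seq_len(nrow(binary)), function(j) {
    x <- binary[j, ]
    miss <- mean(is.na(x))
    if (miss > max_missing || all(is.na(x))) {
      return(tibble(p = NA_real_, n_used = sum(!is.na(x)),
                    method = "excluded", excluded = TRUE))
    }
    keep <- !is.na(x)
    tab <- table(factor(cell_types[keep], levels = types),
                 factor(x[keep], levels = c(0L, 1L)))
    r <- exact_rx2_test(tab)
    tibble(p = r$p, n_used = sum(keep), method = r$method, excluded = FALSE)
  }) |> list_rbind()

  res <- bind_cols(tibble(probe_id = rownames(binary)), res)
  res$fdr <- NA_real_
  res$fdr[!res$excluded] <- p.adjust(res$p[!res$excluded], method = "BH")
  res
}

#' Hypermethylation filter against nonimmune cells and tumor lines
#'
#' A CpG passes when the fraction of nonimmune samples with beta strictly
#' above `nonimmune_beta_threshold` strictly exceeds
#' `nonimmune_sample_fraction`. Missing values are excluded from both
#' numerator and denominator; a CpG with no usable values fails (logged).
#'
#' @param beta Beta matrix restricted to nonimmune/tumor-line samples.
#' @param params A [selection_params()].
#' @return Tibble (`probe_id`, `frac_hyper`, `n_used`, `pass`).
#' @export
nonimmune_hypermethylation_filter <- function(beta, params = selection_params()) {
  beta <- as_beta_matrix(beta)
  if (ncol(beta) < 1) abort("need at least one nonimmune sample.")
  n_used <- rowSums(!is.na(beta))
  frac <- rowSums(beta > params$nonimmune_beta_threshold, na.rm = TRUE) /
    pmax(n_used, 1)
  pass <- n_used > 0 & frac > params$nonimmune_sample_fraction
  empty <- n_used == 0
  if (any(empty)) {
    inform(sprintf("%d CpG(s) had no usable nonimmune values and fail the filter.",
                   sum(empty)))
  }
  tibble(probe_id = rownames(beta), frac_hyper = ifelse(n_used > 0, frac, NA_real_),
         n_used = n_used, pass = pass)
}

#' Keep the most significant CpG per gene
#'
#' Collapses surviving candidates to exactly one CpG per gene: smallest Fisher
#' p-value, ties broken by larger beta range across the reference immune
#' samples, then by lexicographically smaller probe ID (deterministic).
#'
#' @param candidates Tibble with at least `gene`, `probe_id`, `cell_type`,
#'   `p`, `fdr`; optionally `beta_range`.
#' @return Tibble of gene-CpG pairs (`gene`, `cpg`, `cell_type`, `p`, `fdr`).
#' @export
select_best_cpg_per_gene <- function(candidates) {
  candidates <- as_tibble(candidates)
  if (!"beta_range" %in% names(candidates)) candidates$beta_range <- 0
  candidates |>
    arrange(.data$gene, .data$p, dplyr::desc(.data$beta_range), .data$probe_id) |>
    group_by(.data$gene) |>
    dplyr::slice(1) |>
    ungroup() |>
    dplyr::transmute(gene = .data$gene, cpg = .data$probe_id,
                     cell_type = .data$cell_type, p = .data$p, fdr = .data$fdr)
}

#' Run the full immune CpG selection pipeline
#'
#' Composes the selection steps: combine the two gene signatures (dropping
#' conflicts), map genes to shared-platform promoter CpGs, binarize the
#' reference immune beta values and test each candidate CpG for differential
#' methylation across cell types (Fisher exact, BH FDR), require
#' hypermethylation in nonimmune/tumor-line samples, and keep the most
#' significant CpG per gene. Records the number of genes/CpGs surviving each
#' step in a funnel report.
#'
#' @param reference A `reference_panel` (from [simulate_reference_panel()]),
#'   or a beta matrix; in the latter case supply `sample_info`, `sig_a`,
#'   `sig_b` and `annotation`.
#' @param params A [selection_params()].
#' @param sample_info Tibble (`sample_id`, `sample_type`, `cell_type`) with
#'   `sample_type` in immune / nonimmune / tumor_line.
#' @param sig_a,sig_b Signature tables (`gene`, `cell_type`).
#' @param annotation Probe annotation (see [map_promoter_cpgs()]).
#' @return An `immune_selection` object: list with `pairs` (tibble `gene`,
#'   `cpg`, `cell_type`, `p`, `fdr`), `funnel` (per-step counts), `candidates`
#'   (full candidate table), and `params`.
#' @export
run_selection <- function(reference, params = selection_params(),
                          sample_info = NULL, sig_a = NULL, sig_b = NULL,
                          annotation = NULL) {
  if (inherits(reference, "reference_panel")) {
    sample_info <- reference$sample_info
    sig_a <- sig_a %||% reference$signature_a
    sig_b <- sig_b %||% reference$signature_b
    annotation <- annotation %||% reference$annotation
    beta <- reference$beta
  } else {
    beta <- as_beta_matrix(reference)
    if (is.null(sample_info) || is.null(sig_a) || is.null(sig_b) ||
        is.null(annotation)) {
      abort("supply `sample_info`, `sig_a`, `sig_b` and `annotation` with a bare beta matrix.")
    }
  }
  stopifnot(inherits(params, "selection_params"))

  signature <- combine_signatures(sig_a, sig_b)
  candidates <- map_promoter_cpgs(signature, annotation, params)
  candidates <- candidates[candidates$probe_id %in% rownames(beta), ]
  if (nrow(candidates) == 0) abort("no candidate CpGs after promoter mapping.")

  imm <- sample_info$sample_id[sample_info$sample_type == "immune"]
  nonimm <- sample_info$sample_id[sample_info$sample_type %in%
                                    c("nonimmune", "tumor_line")]
  if (length(imm) < 4) abort("need reference immune samples (sample_type == 'immune').")
  if (length(nonimm) < 1) abort("need nonimmune/tumor-line samples for step 2.")

  beta_imm <- beta[candidates$probe_id, imm, drop = FALSE]
  cell_types <- sample_info$cell_type[match(imm, sample_info$sample_id)]
  binary <- binarize_beta(beta_imm, params$binarize_threshold)
  fisher <- fisher_differential(binary, cell_types)

  nonimm_filter <- nonimmune_hypermethylation_filter(
    beta[candidates$probe_id, nonimm, drop = FALSE], params
  )

  beta_range <- apply(beta_imm, 1, function(x) {
    if (all(is.na(x))) return(NA_real_)
    diff(range(x, na.rm = TRUE))
  })

  cand <- candidates |>
    left_join(fisher, by = "probe_id") |>
    left_join(nonimm_filter[, c("probe_id", "frac_hyper", "pass")], by = "probe_id") |>
    mutate(beta_range = beta_range[.data$probe_id],
           fisher_pass = !.data$excluded & !is.na(.data$fdr) &
             .data$fdr < params$fdr_threshold)

  surviving <- filter(cand, .data$fisher_pass, .data$pass)
  pairs <- select_best_cpg_per_gene(surviving)

  funnel <- tibble(
    step = c("signature_genes", "candidate_cpgs", "candidate_genes",
             "fisher_pass", "nonimmune_pass", "both_filters", "final_pairs"),
    n = c(nrow(signature), nrow(candidates), dplyr::n_distinct(candidates$gene),
          sum(cand$fisher_pass), sum(cand$pass, na.rm = TRUE),
          nrow(surviving), nrow(pairs))
  )

  structure(
    list(pairs = pairs, funnel = funnel, candidates = cand,
         signature = signature, params = params,
         fdr_method = "Benjamini-Hochberg"),
    class = "immune_selection"
  )
}

#' @export
print.immune_selection <- function(x, ...) {
  cat("Immune CpG selection (", x$params$mode, " mode)\n", sep = "")
  cat(sprintf("  %d gene-CpG pairs across %d cell types\n",
              nrow(x$pairs), dplyr::n_distinct(x$pairs$cell_type)))
  f <- x$funnel
  cat(paste0("  ", format(f$step, width = 16), " ", f$n, collapse = "\n"), "\n")
  invisible(x)
}
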