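#' Define the PTEN promoter CpG set
#'
#' The full set of PTEN promoter CpGs and the subset at DNase hypersensitivity
#' sites (DHS) of the promoter; the hypermethylation call uses both. DHS
#' membership is supplied as annotation (no DHS track processing).
#'
#' @param all_promoter_cpgs Character vector of PTEN promoter probe IDs, or a
#'   data frame with `probe_id` and logical `is_dhs`.
#' @param dhs_cpgs Character vector of DHS probe IDs (subset of the former);
#'   ignored when a data frame is given.
#' @return A `pten_cpg_set` list.
#' @export
pten_cpg_set <- function(all_promoter_cpgs, dhs_cpgs = NULL) {
  if (is.data.frame(all_promoter_cpgs)) {
    ann <- as_tibble(all_promoter_cpgs)
    if (!all(c("probe_id", "is_dhs") %in% names(ann))) {
      abort("annotation needs columns probe_id and is_dhs.")
    }
    dhs_cpgs <- ann$probe_id[ann$is_dhs]
    all_promoter_cpgs <- ann$probe_id
  }
  if (!length(all_promoter_cpgs) || !length(dhs_cpgs)) {
    abort("both the promoter CpG set and its DHS subset must be non-empty.")
  }
  if (!all(dhs_cpgs %in% all_promoter_cpgs)) {
    abort("`dhs_cpgs` must be a subset of `all_promoter_cpgs`.")
  }
  structure(list(all_promoter_cpgs = unique(all_promoter_cpgs),
                 dhs_cpgs = unique(dhs_cpgs)),
            class = "pten_cpg_set")
}

#' Call PTEN promoter hypermethylation per sample
#'
#' A sample is hypermethylated when strictly more than `dhs_fraction` (10%)
#' of its non-missing DHS promoter CpGs have beta strictly above `hyper_beta`
#' (0.7) AND the median beta over all promoter CpGs is strictly above
#' `median_threshold` (0.5). Samples with fewer than `min_dhs` non-missing
#' DHS CpGs are undetermined (NA, logged).
#'
#' @param beta Beta matrix (probes x samples) containing the PTEN CpGs.
#' @param cpgs A [pten_cpg_set()] (or a data frame accepted by it).
#' @param dhs_fraction Required fraction of hypermethylated DHS CpGs (strict).
#' @param hyper_beta Per-CpG hypermethylation threshold (strict).
#' @param median_threshold All-promoter median threshold (strict).
#' @param min_dhs Minimum non-missing DHS CpGs for a determinate call.
#' @return Tibble (`sample_id`, `frac_dhs_hyper`, `median_promoter_beta`,
#'   `n_dhs_used`, `hypermethylated`).
#' @export
call_pten_hypermethylation <- function(beta, cpgs, dhs_fraction = 0.10,
                                       hyper_beta = 0.7,
                                       median_threshold = 0.5,
                                       min_dhs = 5) {
  if (!inherits(cpgs, "pten_cpg_set")) cpgs <- pten_cpg_set(cpgs)
  beta <- as_beta_matrix(beta)
  prom <- intersect(cpgs$all_promoter_cpgs, rownames(beta))
  dhs <- intersect(cpgs$dhs_cpgs, rownames(beta))
  if (!length(prom) || !length(dhs)) abort("PTEN CpGs not found in the beta matrix.")

  dhs_b <- beta[dhs, , drop = FALSE]
  prom_b <- beta[prom, , drop = FALSE]
  n_dhs <- colSums(!is.na(dhs_b))
  frac <- colSums(dhs_b > hyper_beta, na.rm = TRUE) / pmax(n_dhs, 1)
  med <- apply(prom_b, 2, median, na.rm = TRUE)
  call <- frac > dhs_fraction & med > median_threshold
  undet <- n_dhs < min_dhs
  call[undet] <- NA
  if (any(undet)) {
    inform(sprintf("%d sample(s) undetermined: fewer than %d non-missing DHS CpGs.",
                   sum(undet), min_dhs))
  }
  tibble(sample_id = colnames(beta),
         frac_dhs_hyper = unname(ifelse(n_dhs > 0, frac, NA_real_)),
         median_promoter_beta = unname(med),
         n_dhs_used = unname(n_dhs),
         hypermethylated = unname(call))
}

#' Integrate PTEN alteration events
#'
#' A PTEN alteration event is promoter hypermethylation, nonsynonymous
#' mutation, or copy-number loss/deletion (logical OR). Missing modalities
#' are treated as FALSE with a per-sample completeness flag.
#'
#' @param hypermethylation Tibble from [call_pten_hypermethylation()] (or any
#'   data frame with `sample_id` and logical `hypermethylated`).
#' @param mutation Data frame with `sample_id` and logical
#'   `nonsynonymous_mutation`; may be NULL.
#' @param cna Data frame with `sample_id` and `cn_call` in
#'   loss / deletion / neutral / gain (or logical `cn_loss`); may be NULL.
#' @return A `pten_status` tibble: `sample_id`, `hypermethylated`,
#'   `nonsynonymous_mutation`, `cn_loss`, `any_event`, `complete`.
#' @export
integrate_pten_events <- function(hypermethylation, mutation = NULL, cna = NULL) {
  h <- as_tibble(hypermethylation)[, c("sample_id", "hypermethylated")]
  if (anyDuplicated(h$sample_id)) abort("duplicate sample IDs in hypermethylation calls.")
  out <- h
  out$has_meth <- !is.na(out$hypermethylated)

  if (!is.null(mutation)) {
    m <- as_tibble(mutation)[, c("sample_id", "nonsynonymous_mutation")]
    if (anyDuplicated(m$sample_id)) abort("duplicate sample IDs in mutation calls.")
    out <- left_join(out, m, by = "sample_id")
  } else {
    out$nonsynonymous_mutation <- NA
  }
  if (!is.null(cna)) {
    cn <- as_tibble(cna)
    if (anyDuplicated(cn$sample_id)) abort("duplicate sample IDs in CNA calls.")
    if (!"cn_loss" %in% names(cn)) {
      if (!"cn_call" %in% names(cn)) abort("`cna` needs cn_call or cn_loss.")
      cn$cn_loss <- cn$cn_call %in% c("loss", "deletion")
    }
    out <- left_join(out, cn[, c("sample_id", "cn_loss")], by = "sample_id")
  } else {
    out$cn_loss <- NA
  }

  out <- out |>
    mutate(
      complete = .data$has_meth & !is.na(.data$nonsynonymous_mutation) &
        !is.na(.data$cn_loss),
      hypermethylated = !is.na(.data$hypermethylated) & .data$hypermethylated,
      nonsynonymous_mutation = !is.na(.data$nonsynonymous_mutation) &
        .data$nonsynonymous_mutation,
      cn_loss = !is.na(.data$cn_loss) & .data$cn_loss,
      any_event = .data$hypermethylated | .data$nonsynonymous_mutation | .data$cn_loss
    ) |>
    select("sample_id", "hypermethylated", "nonsynonymous_mutation",
           "cn_loss", "any_event", "complete")
  class(out) <- c("pten_status", class(out))
  out
}

#' Summarize PTEN event composition per cluster
#'
#' @param status A `pten_status` tibble from [integrate_pten_events()].
#' @param labels Cluster labels (named vector, tibble, or `immune_consensus`).
#' @return Tibble with per-cluster counts and rates of each event type.
#' @export
pten_event_summary <- function(status, labels) {
  labels <- normalize_labels(labels, status$sample_id)
  status |>
    mutate(cluster = labels) |>
    group_by(.data$cluster) |>
    summarise(
      n = dplyr::n(),
      n_hypermethylated = sum(.data$hypermethylated),
      n_mutation = sum(.data$nonsynonymous_mutation),
      n_cn_loss = sum(.data$cn_loss),
      n_any_event = sum(.data$any_event),
      rate_any_event = mean(.data$any_event),
      .groups = "drop"
    )
}
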