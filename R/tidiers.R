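#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy_immunometh
#' @export
tidy.immune_selection <- function(x, ...) x$pairs

#' Tidy and summarize pipeline result objects
#'
#' `tidy()` returns the per-unit table of a result (gene-CpG pairs, sample
#' labels, centroid medians in long form); `glance()` returns a one-row
#' summary.
#'
#' @param x A result object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_immunometh
NULL

#' @rdname tidy_immunometh
#' @export
glance.immune_selection <- function(x, ...) {
  f <- setNames(as.list(x$funnel$n), x$funnel$step)
  tibble(mode = x$params$mode,
         n_signature_genes = f$signature_genes,
         n_candidate_cpgs = f$candidate_cpgs,
         n_pairs = f$final_pairs,
         n_cell_types = dplyr::n_distinct(x$pairs$cell_type))
}

#' @rdname tidy_immunometh
#' @export
tidy.immune_consensus <- function(x, ...) {
  tibble(sample_id = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy_immunometh
#' @export
glance.immune_consensus <- function(x, ...) {
  off <- x$consensus[upper.tri(x$consensus)]
  tibble(k = x$k, n_samples = length(x$labels),
         n_iter = x$settings$n_iter, subsample = x$settings$subsample,
         mean_consensus = mean(off),
         # fraction of pairwise consensus values that are decisively 0 or 1
         consensus_clarity = mean(off < 0.1 | off > 0.9))
}

#' @rdname tidy_immunometh
#' @export
tidy.immune_centroids <- function(x, ...) {
  bind_cols(tibble(probe_id = rownames(x$medians)), as_tibble(x$medians)) |>
    tidyr::pivot_longer(-"probe_id", names_to = "cluster",
                        names_prefix = "cluster", values_to = "median_beta")
}

#' @rdname tidy_immunometh
#' @export
glance.immune_centroids <- function(x, ...) {
  tibble(n_centroid_cpgs = nrow(x$medians), k = ncol(x$medians),
         kw_fdr_threshold = x$kw_fdr_threshold,
         classify_threshold = x$classify_threshold)
}

#' @rdname tidy_immunometh
#' @export
tidy.immune_scores <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "score") |>
    mutate(modality = attr(x, "modality"))
}

#' @rdname tidy_immunometh
#' @export
tidy.km_result <- function(x, ...) {
  s <- summary(x$fit)
  strata <- if (is.null(s$strata)) "all" else sub("^group=", "", as.character(s$strata))
  tibble(group = strata, time = s$time, n_risk = s$n.risk,
         n_event = s$n.event, estimate = s$surv,
         std_error = s$std.err, conf_low = s$lower, conf_high = s$upper)
}

#' @rdname tidy_immunometh
#' @export
glance.km_result <- function(x, ...) {
  tibble(logrank_p = x$logrank_p, n_groups = max(1, length(x$fit$strata)),
         horizon = x$horizon)
}

#' @export
print.immune_consensus <- function(x, ...) {
  cat(sprintf("Consensus clustering: %d samples, k = %d (%d iterations, %.0f%% subsampling)\n",
              length(x$labels), x$k, x$settings$n_iter, 100 * x$settings$subsample))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
print.immune_centroids <- function(x, ...) {
  cat(sprintf("Methylation centroids: %d CpGs x %d clusters (KW FDR < %g)\n",
              nrow(x$medians), ncol(x$medians), x$kw_fdr_threshold))
  invisible(x)
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier fit")
  if (!is.na(x$logrank_p)) cat(sprintf(" (log-rank p = %.3g)", x$logrank_p))
  cat("\n")
  print(x$fit)
  invisible(x)
}
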