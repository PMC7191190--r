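#' Monti-style consensus clustering over selected CpGs
#'
#' Repeatedly subsamples the cohort (without replacement), clusters each
#' subsample by hierarchical clustering (Ward linkage on Euclidean distance)
#' cut at `k`, and accumulates the fraction of co-sampled runs in which each
#' sample pair lands in the same cluster. Final labels come from hierarchical
#' clustering of `1 - consensus` at `k`. Cluster indices are relabelled by
#' ascending mean beta over the clustering CpGs, so cluster 1 is always the
#' methylation-low (immune-rich) group and cluster `k` the methylation-high
#' (immune-poor) group.
#'
#' @param beta Beta matrix (selected CpGs x samples) or data frame.
#' @param k Number of clusters (>= 2).
#' @param n_iter Number of resampling iterations.
#' @param subsample Fraction of samples drawn per iteration.
#' @param seed Integer seed for the resampling.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An `immune_consensus` object: list with `labels` (named integer
#'   vector), `consensus` (samples x samples matrix, diagonal 1), `k`, and
#'   `settings`.
#' @export
consensus_cluster <- function(beta, k = 3, n_iter = 1000, subsample = 0.8,
                              seed = 1, linkage = "ward.D2") {
  beta <- as_beta_matrix(beta)
  n <- ncol(beta)
  if (k < 2) abort("`k` must be >= 2.")
  if (n < 3 * k) abort(sprintf("need at least 3*k = %d samples, got %d.", 3 * k, n))
  if (any(apply(beta, 1, function(x) all(is.na(x))))) {
    abort("beta contains all-missing CpGs; drop them first.")
  }
  check_fraction(subsample, "subsample", open = TRUE)

  x <- t(beta)                       # samples x CpGs
  m <- max(2, floor(subsample * n))
  hits <- matrix(0, n, n)
  pairs <- matrix(0, n, n)
  set.seed(seed)
  for (i in seq_len(n_iter)) {
    idx <- sample.int(n, m)
    cl <- stats::cutree(stats::hclust(stats::dist(x[idx, , drop = FALSE]), linkage), k)
    co <- outer(cl, cl, "==") + 0
    hits[idx, idx] <- hits[idx, idx] + co
    pairs[idx, idx] <- pairs[idx, idx] + 1
  }
  consensus <- ifelse(pairs > 0, hits / pmax(pairs, 1), 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(beta), colnames(beta))

  final <- stats::cutree(stats::hclust(stats::as.dist(1 - consensus), linkage), k)
  # order clusters by mean methylation: 1 = lowest (immune-high)
  mean_beta <- vapply(seq_len(k), function(cl) {
    mean(beta[, final == cl, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  relabel <- match(seq_len(k), order(mean_beta))
  labels <- setNames(relabel[final], colnames(beta))

  structure(
    list(labels = labels, consensus = consensus, k = k,
         settings = list(n_iter = n_iter, subsample = subsample, seed = seed,
                         linkage = linkage)),
    class = "immune_consensus"
  )
}

#' Build per-cluster methylation centroids
#'
#' Screens the immune CpG set for CpGs with a significant methylation
#' difference across clusters (Kruskal-Wallis test, Benjamini-Hochberg FDR
#' strictly below `kw_fdr_threshold`), then computes each retained CpG's
#' median beta per cluster. Constant CpGs get p = 1 and drop out.
#'
#' @param beta Beta matrix (probes x samples) containing the immune CpGs.
#' @param labels Cluster labels: named vector, `immune_consensus` object, or
#'   tibble (`sample_id`, `cluster`).
#' @param cpgs Character vector of immune CpG IDs to screen (defaults to all
#'   rows of `beta`).
#' @param kw_fdr_threshold FDR gate; default 1e-4.
#' @param classify_threshold Kendall tau threshold stored for classification.
#' @return An `immune_centroids` object: list with `medians` (CpG x cluster
#'   matrix), `kw` (per-CpG test tibble), `kw_fdr_threshold`,
#'   `classify_threshold`.
#' @export
build_centroids <- function(beta, labels, cpgs = NULL,
                            kw_fdr_threshold = 1e-4,
                            classify_threshold = 0.3) {
  beta <- as_beta_matrix(beta)
  labels <- normalize_labels(labels, colnames(beta))
  cpgs <- cpgs %||% rownames(beta)
  cpgs <- intersect(cpgs, rownames(beta))
  if (!length(cpgs)) abort("none of `cpgs` are in `beta`.")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 3)) {
    abort("need >= 2 clusters with >= 3 samples each.")
  }

  grp <- factor(labels)
  kw_p <- vapply(cpgs, function(cg) {
    x <- beta[cg, ]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2 || length(unique(grp[ok])) < 2) return(1)
    kruskal.test(x[ok], grp[ok])$p.value
  }, numeric(1))
  fdr <- p.adjust(kw_p, method = "BH")
  keep <- fdr < kw_fdr_threshold
  if (!any(keep)) {
    abort(sprintf(
      "no CpG passed the Kruskal-Wallis FDR gate (< %g); smallest FDR was %.3g.",
      kw_fdr_threshold, min(fdr)))
  }
  kept <- cpgs[keep]
  medians <- vapply(sort(unique(labels)), function(cl) {
    apply(beta[kept, labels == cl, drop = FALSE], 1, median, na.rm = TRUE)
  }, numeric(length(kept)))
  if (is.null(dim(medians))) medians <- matrix(medians, nrow = length(kept))
  dimnames(medians) <- list(kept, paste0("cluster", sort(unique(labels))))

  structure(
    list(medians = medians,
         kw = tibble(probe_id = cpgs, kw_p = unname(kw_p), kw_fdr = unname(fdr),
                     retained = unname(keep)),
         kw_fdr_threshold = kw_fdr_threshold,
         classify_threshold = classify_threshold),
    class = "immune_centroids"
  )
}

#' Classify samples by correlation to methylation centroids
#'
#' Computes Kendall tau-b (tie-corrected, pairwise-complete) between each
#' sample's beta over the centroid CpGs and every cluster's median vector,
#' assigning the cluster with the highest tau when that maximum is at least
#' the threshold (default 0.3, inclusive); otherwise the sample is
#' unclassified. Samples with fewer than `min_cpgs` informative centroid CpGs
#' are unclassified with a reason code. Ties on tau go to the lowest cluster
#' index with a warning.
#'
#' @param beta Beta matrix (probes x samples), data frame, or a single named
#'   numeric vector for one sample.
#' @param centroids An `immune_centroids` object.
#' @param tau_threshold Minimum Kendall tau for assignment (inclusive).
#' @param min_cpgs Minimum non-missing overlapping centroid CpGs.
#' @return An `immune_classification` tibble: `sample_id`, one `tau_*` column
#'   per cluster, `n_cpgs`, `assigned` (`"1"`, `"2"`, ... or
#'   `"unclassified"`), `reason`.
#' @export
classify_by_centroid <- function(beta, centroids,
                                 tau_threshold = NULL, min_cpgs = 10) {
  stopifnot(inherits(centroids, "immune_centroids"))
  tau_threshold <- tau_threshold %||% centroids$classify_threshold
  if (is.numeric(beta) && is.null(dim(beta))) {
    beta <- matrix(beta, ncol = 1, dimnames = list(names(beta), "sample"))
  }
  beta <- as_beta_matrix(beta)
  med <- centroids$medians
  common <- intersect(rownames(med), rownames(beta))
  k <- ncol(med)
  cl_names <- sub("^cluster", "", colnames(med))

  rows <- purrr::map(seq_len(ncol(beta)), function(i) {
    x <- beta[common, i]
    taus <- rep(NA_real_, k)
    if (length(common)) {
      for (cl in seq_len(k)) {
        ok <- !is.na(x) & !is.na(med[common, cl])
        if (sum(ok) >= 2 && stats::sd(x[ok]) > 0 && stats::sd(med[common, cl][ok]) > 0) {
          taus[cl] <- cor(x[ok], med[common, cl][ok], method = "kendall")
        }
      }
    }
    n_inf <- if (length(common)) sum(!is.na(x)) else 0L
    if (length(common) == 0) {
      assigned <- "unclassified"; reason <- "no_overlapping_cpgs"
    } else if (n_inf < min_cpgs) {
      assigned <- "unclassified"; reason <- "too_few_cpgs"
    } else if (all(is.na(taus))) {
      assigned <- "unclassified"; reason <- "tau_not_computable"
    } else if (max(taus, na.rm = TRUE) >= tau_threshold) {
      top <- which(taus == max(taus, na.rm = TRUE))
      if (length(top) > 1) {
        warn(sprintf("sample '%s': tied tau between clusters %s; taking the lowest.",
                     colnames(beta)[i], paste(cl_names[top], collapse = ", ")))
      }
      assigned <- cl_names[min(top)]; reason <- NA_character_
    } else {
      assigned <- "unclassified"; reason <- "tau_below_threshold"
    }
    out <- tibble(sample_id = colnames(beta)[i], n_cpgs = n_inf,
                  assigned = assigned, reason = reason)
    tau_tbl <- as_tibble(as.list(setNames(taus, paste0("tau_", cl_names))))
    bind_cols(out[, "sample_id"], tau_tbl, out[, c("n_cpgs", "assigned", "reason")])
  })
  out <- list_rbind(rows)
  class(out) <- c("immune_classification", class(out))
  attr(out, "tau_threshold") <- tau_threshold
  out
}

# Accept labels as a named vector, an immune_consensus, or a tibble.
normalize_labels <- function(labels, sample_ids) {
  if (inherits(labels, "immune_consensus")) labels <- labels$labels
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "cluster") %in% names(labels))) {
      abort("label table must have columns sample_id and cluster.")
    }
    labels <- setNames(labels$cluster, labels$sample_id)
  }
  if (!is.null(names(labels))) {
    if (!all(sample_ids %in% names(labels))) {
      abort("labels are missing some samples present in the beta matrix.")
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    abort("unnamed labels must match the number of samples.")
  }
  as.integer(labels)
}
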