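#' Simulation configuration for synthetic methylation cohorts
#'
#' Bundles every knob of the synthetic-data generator: a reference panel of
#' immune cell types with cell-type-specific unmethylated promoter CpGs,
#' uniformly hypermethylated nonimmune/tumor-line profiles, and tumor cohorts
#' built as purity-weighted mixtures of tumor-line and immune methylomes with
#' three planted infiltration strata, linked expression, exponential survival
#' and PTEN lesions.
#'
#' Observed beta values are drawn from a beta distribution parameterized by
#' (mean = archetype, concentration), so values stay in \[0, 1\] without
#' clipping. Identical seeds give identical output (R's default Mersenne
#' Twister; the tumor cohort stream is derived from `seed + 1`).
#'
#' @param seed Integer seed for all randomness.
#' @param n_celltypes Number of immune cell types in the reference panel.
#' @param n_marker_cpgs_per_type Planted marker CpGs (one gene each) per type.
#' @param n_background_cpgs Non-informative promoter CpGs, methylated
#'   everywhere.
#' @param n_ref_samples_per_type Reference methylomes per immune cell type.
#' @param n_nonimmune_samples Nonimmune stromal reference samples.
#' @param n_tumor_lines Tumor cell-line reference samples.
#' @param cohort_size Number of tumor samples in a simulated cohort.
#' @param cluster_proportions Three fractions (sum 1) of samples per
#'   infiltration stratum.
#' @param infiltration_means Mean total immune infiltration per stratum
#'   (high/mid/low), strictly decreasing.
#' @param infiltration_concentration Beta-distribution concentration for
#'   per-sample infiltration draws around the stratum mean.
#' @param beta_noise_concentration Concentration for observed beta around the
#'   archetype/mixture value; larger = less noise.
#' @param hazard_ratios Per-cluster multiplicative hazards (cluster 1 = 1).
#' @param baseline_hazard Exponential baseline hazard, events per year.
#' @param censoring_max Upper bound of the uniform censoring time (years).
#' @param pten_event_rates Per-cluster probability of any PTEN alteration.
#' @param expression_slope Slope linking promoter beta to expression
#'   (negative: promoter methylation silences the gene).
#' @param expression_intercept Expression level at beta = 0.
#' @param expression_sd Gaussian noise sd on expression.
#' @param n_multi_cpg_genes Number of marker genes given extra decoy CpGs to
#'   exercise best-CpG-per-gene selection.
#' @param n_extra_cpgs_per_gene Extra CpGs per multi-CpG gene.
#' @param n_conflict_genes Genes planted with conflicting cell types in the
#'   two signature sources (must be removed by [combine_signatures()]).
#' @param cell_type_names Optional character vector of cell-type labels.
#'
#' @return A `simulation_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_celltypes = 3,
#'                          n_marker_cpgs_per_type = 4,
#'                          n_background_cpgs = 50)
simulation_config <- function(seed = 1L,
                              n_celltypes = 7,
                              n_marker_cpgs_per_type = 5,
                              n_background_cpgs = 2000,
                              n_ref_samples_per_type = 6,
                              n_nonimmune_samples = 10,
                              n_tumor_lines = 10,
                              cohort_size = 150,
                              cluster_proportions = c(1, 1, 1) / 3,
                              infiltration_means = c(0.45, 0.20, 0.05),
                              infiltration_concentration = 50,
                              beta_noise_concentration = 100,
                              hazard_ratios = c(1, 2.1, 2.2),
                              baseline_hazard = 0.14,
                              censoring_max = 15,
                              pten_event_rates = c(0.10, 0.30, 0.60),
                              expression_slope = -4,
                              expression_intercept = 10,
                              expression_sd = 0.5,
                              n_multi_cpg_genes = 2,
                              n_extra_cpgs_per_gene = 2,
                              n_conflict_genes = 2,
                              cell_type_names = NULL) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0),
    n_celltypes = check_count(n_celltypes, "n_celltypes", 2),
    n_marker_cpgs_per_type = check_count(n_marker_cpgs_per_type, "n_marker_cpgs_per_type"),
    n_background_cpgs = check_count(n_background_cpgs, "n_background_cpgs", 0),
    n_ref_samples_per_type = check_count(n_ref_samples_per_type, "n_ref_samples_per_type", 2),
    n_nonimmune_samples = check_count(n_nonimmune_samples, "n_nonimmune_samples"),
    n_tumor_lines = check_count(n_tumor_lines, "n_tumor_lines"),
    cohort_size = check_count(cohort_size, "cohort_size", 9),
    cluster_proportions = cluster_proportions,
    infiltration_means = infiltration_means,
    infiltration_concentration = infiltration_concentration,
    beta_noise_concentration = beta_noise_concentration,
    hazard_ratios = hazard_ratios,
    baseline_hazard = baseline_hazard,
    censoring_max = censoring_max,
    pten_event_rates = pten_event_rates,
    expression_slope = expression_slope,
    expression_intercept = expression_intercept,
    expression_sd = expression_sd,
    n_multi_cpg_genes = check_count(n_multi_cpg_genes, "n_multi_cpg_genes", 0),
    n_extra_cpgs_per_gene = check_count(n_extra_cpgs_per_gene, "n_extra_cpgs_per_gene", 0),
    n_conflict_genes = check_count(n_conflict_genes, "n_conflict_genes", 0),
    cell_type_names = cell_type_names
  )
  if (length(cfg$cluster_proportions) != 3 ||
      abs(sum(cfg$cluster_proportions) - 1) > 1e-9) {
    abort("`cluster_proportions` must be 3 fractions summing to 1 (tolerance 1e-9).")
  }
  check_fraction(cfg$cluster_proportions, "cluster_proportions")
  if (length(cfg$infiltration_means) != 3 ||
      any(diff(cfg$infiltration_means) >= 0)) {
    abort("`infiltration_means` must be 3 strictly decreasing fractions (high/mid/low).")
  }
  check_fraction(cfg$infiltration_means, "infiltration_means")
  for (nm in c("infiltration_concentration", "beta_noise_concentration",
               "baseline_hazard", "censoring_max", "expression_sd")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort(sprintf("`%s` must be a positive number.", nm))
    }
  }
  if (length(cfg$hazard_ratios) != 3 || any(cfg$hazard_ratios <= 0)) {
    abort("`hazard_ratios` must be 3 positive values.")
  }
  if (length(cfg$pten_event_rates) != 3) abort("`pten_event_rates` must have length 3.")
  check_fraction(cfg$pten_event_rates, "pten_event_rates")
  if (!is.numeric(cfg$expression_slope) || cfg$expression_slope >= 0) {
    abort("`expression_slope` must be negative (promoter methylation represses).")
  }
  if (is.null(cfg$cell_type_names)) {
    base <- c("B cells", "CD4 T cells", "CD8 T cells", "NK cells",
              "Monocytes", "Neutrophils", "Eosinophils")
    cfg$cell_type_names <- if (cfg$n_celltypes <= length(base)) {
      base[seq_len(cfg$n_celltypes)]
    } else {
      c(base, sprintf("Cell type %d", seq(length(base) + 1, cfg$n_celltypes)))
    }
  }
  if (length(cfg$cell_type_names) != cfg$n_celltypes ||
      anyDuplicated(cfg$cell_type_names)) {
    abort("`cell_type_names` must be unique and match `n_celltypes`.")
  }
  structure(cfg, class = "simulation_config")
}

# Cluster x cell-type infiltration weight profiles, each scaled to mean 1.
# Cluster 1 (immune-rich) is lymphoid-dominant, cluster 2 mixed, cluster 3
# (immune-poor) carries only a myeloid-skewed residual. Distinct profiles give
# the three centroids distinct rank structure, which is what a rank-correlation
# classifier keys on. Clipped so that expected marker beta in cluster 1 stays
# strictly below cluster 3 for every cell type.
infiltration_profiles <- function(n_celltypes, infiltration_means) {
  k <- n_celltypes
  lin <- function(from, to) seq(from, to, length.out = k)
  w1 <- lin(1.75, 0.55)
  w3 <- lin(0.35, 1.9)
  mid <- (k + 1) / 2
  w2 <- 0.35 + 1.55 * (1 - abs(seq_len(k) - mid) / (mid - 1))
  norm1 <- function(w) w / mean(w)
  w <- rbind(norm1(w1), norm1(w2), norm1(w3))
  # expected beta ordering: means[1] * w[1, t] > means[3] * w[3, t]
  cap <- 0.95 * infiltration_means[1] / infiltration_means[3] * w[1, ]
  w[3, ] <- pmin(w[3, ], cap)
  rownames(w) <- paste0("cluster", 1:3)
  w
}

#' Simulate a reference methylation panel
#'
#' Generates reference methylomes for `n_celltypes` immune cell types, plus
#' nonimmune stromal samples and tumor cell lines. Each cell type's marker
#' CpGs carry a low archetype beta (drawn near 0.1) in that cell type and a
#' high archetype (near 0.85) in every other immune type; background CpGs are
#' methylated everywhere; nonimmune and tumor-line profiles are hypermethylated
#' (archetype > 0.8) at all CpGs. Also emits the probe annotation and the two
#' gene signature tables (with planted conflicts and multi-CpG decoy genes)
#' that the selection pipeline consumes.
#'
#' @param config A [simulation_config()].
#' @return A `reference_panel` list with elements `beta` (probes x samples
#'   matrix), `sample_info`, `annotation`, `signature_a`, `signature_b`,
#'   `truth` (marker CpG to cell type map) and `config`.
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)

  types <- cfg$cell_type_names
  k <- cfg$n_celltypes
  n_marker <- k * cfg$n_marker_cpgs_per_type
  n_extra <- cfg$n_multi_cpg_genes * cfg$n_extra_cpgs_per_gene
  n_bg <- cfg$n_background_cpgs
  n_conf <- cfg$n_conflict_genes
  n_probes <- n_marker + n_extra + n_bg + n_conf

  probe_id <- sprintf("cg%07d", seq_len(n_probes))
  kind <- rep(c("marker", "extra", "background", "conflict"),
              times = c(n_marker, n_extra, n_bg, n_conf))

  marker_gene <- sprintf("IMM%03d", seq_len(n_marker))
  marker_type <- rep(types, each = cfg$n_marker_cpgs_per_type)
  multi_genes <- head(marker_gene, cfg$n_multi_cpg_genes)
  extra_gene <- rep(multi_genes, each = cfg$n_extra_cpgs_per_gene)
  extra_type <- marker_type[match(extra_gene, marker_gene)]
  bg_gene <- sprintf("BGD%04d", seq_len(n_bg))
  conf_gene <- sprintf("CNF%02d", seq_len(n_conf))

  gene <- c(marker_gene, extra_gene, bg_gene, conf_gene)
  cell_type <- c(marker_type, extra_type,
                 rep(types, length.out = n_bg),
                 rep(types[1], n_conf))

  # per-CpG archetypes
  low <- runif(n_probes, 0.05, 0.20)       # unmethylated state in own cell type
  high <- runif(n_probes, 0.80, 0.90)      # methylated state in other immune types
  tline <- runif(n_probes, 0.82, 0.97)     # nonimmune / tumor-line state

  # annotation: a slice of background CpGs falls outside the promoter window or
  # off the shared platform set, to exercise the mapping filters
  informative <- kind %in% c("marker", "extra")
  dist_to_tss <- sample(-1400:1400, n_probes, replace = TRUE)
  n_other <- sum(!informative)
  idx_other <- which(!informative)
  u <- runif(n_other)
  far_idx <- idx_other[u < 0.05]
  epic_idx <- idx_other[u >= 0.05 & u < 0.10]
  dist_to_tss[far_idx] <- sample(c(-1, 1), length(far_idx), TRUE) *
    sample(1500:5000, length(far_idx), replace = TRUE)
  platform_450k <- rep(TRUE, n_probes)
  platform_450k[epic_idx] <- FALSE

  annotation <- tibble(
    probe_id = probe_id, gene = gene, dist_to_tss_bp = dist_to_tss,
    platform_450k = platform_450k, platform_epic = TRUE
  )

  # two signature sources: A has everything; B repeats half of the markers with
  # the same type; conflict genes appear in both with different types
  sig_a <- tibble(gene = c(marker_gene, bg_gene[seq_len(n_bg) %% 2 == 1], conf_gene),
                  cell_type = c(marker_type, rep(types, length.out = n_bg)[seq_len(n_bg) %% 2 == 1],
                                rep(types[1], n_conf)))
  half <- marker_gene[seq_len(n_marker) %% 2 == 0]
  sig_b <- tibble(gene = c(half, bg_gene[seq_len(n_bg) %% 2 == 0], conf_gene),
                  cell_type = c(marker_type[match(half, marker_gene)],
                                rep(types, length.out = n_bg)[seq_len(n_bg) %% 2 == 0],
                                rep(types[min(2, k)], n_conf)))

  # samples
  imm_ids <- unlist(lapply(seq_len(k), function(t) {
    sprintf("ref_t%02d_%02d", t, seq_len(cfg$n_ref_samples_per_type))
  }))
  imm_type <- rep(types, each = cfg$n_ref_samples_per_type)
  stromal_ids <- sprintf("stromal_%02d", seq_len(cfg$n_nonimmune_samples))
  line_ids <- sprintf("tline_%02d", seq_len(cfg$n_tumor_lines))
  sample_info <- tibble(
    sample_id = c(imm_ids, stromal_ids, line_ids),
    sample_type = rep(c("immune", "nonimmune", "tumor_line"),
                      times = c(length(imm_ids), length(stromal_ids), length(line_ids))),
    cell_type = c(imm_type, rep(NA_character_, length(stromal_ids) + length(line_ids)))
  )

  # archetype matrix
  arch <- matrix(NA_real_, n_probes, nrow(sample_info),
                 dimnames = list(probe_id, sample_info$sample_id))
  is_immune <- sample_info$sample_type == "immune"
  marker_like <- kind %in% c("marker", "extra")
  for (j in which(marker_like)) {
    own <- is_immune & sample_info$cell_type == cell_type[j]
    arch[j, own] <- low[j]
    arch[j, is_immune & !own] <- high[j]
  }
  arch[!marker_like, is_immune] <- high[!marker_like]
  arch[, !is_immune] <- matrix(rep(tline, sum(!is_immune)), nrow = n_probes)

  beta <- matrix(rbeta_mc(length(arch), as.vector(arch), cfg$beta_noise_concentration),
                 nrow = n_probes, dimnames = dimnames(arch))

  truth <- list(
    marker_map = tibble(probe_id = probe_id[marker_like],
                        gene = gene[marker_like],
                        cell_type = cell_type[marker_like],
                        is_primary = kind[marker_like] == "marker"),
    archetypes = tibble(probe_id = probe_id, kind = kind,
                        low = low, high = high, tumorline = tline)
  )

  structure(
    list(beta = beta, sample_info = sample_info, annotation = annotation,
         signature_a = sig_a, signature_b = sig_b, truth = truth, config = cfg),
    class = "reference_panel"
  )
}

#' Simulate a tumor cohort as purity-weighted mixtures
#'
#' Tumor beta at each marker CpG is `(1 - f) * beta_tumorline + f * beta_immune`
#' where `f` is the sample's infiltration fraction for the CpG's cell type,
#' drawn around its cluster's stratum mean weighted by a cluster-specific
#' cell-type profile. Also generates exponential survival with per-cluster
#' hazard ratios and uniform censoring, promoter-linked expression, clinical
#' covariates, and PTEN promoter methylation, mutation and copy-number lesions
#' at per-cluster rates.
#'
#' @param config A [simulation_config()].
#' @param panel A `reference_panel` from [simulate_reference_panel()].
#' @return A `tumor_cohort` list with elements `beta`, `clinical`,
#'   `expression`, `pten` (annotation, mutation and CNA tables) and `truth`
#'   (cluster labels, infiltration fractions, PTEN flags, marker map).
#' @export
simulate_tumor_cohort <- function(config, panel) {
  stopifnot(inherits(config, "simulation_config"))
  if (!inherits(panel, "reference_panel")) {
    abort("`panel` must come from simulate_reference_panel().")
  }
  cfg <- config
  set.seed(cfg$seed + 1L)

  n <- cfg$cohort_size
  types <- cfg$cell_type_names
  k <- cfg$n_celltypes
  arche <- panel$truth$archetypes
  markers <- panel$truth$marker_map

  # deterministic cluster sizes from the proportions, shuffled over samples
  counts <- floor(cfg$cluster_proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  cluster <- sample(rep(1:3, times = counts))
  sample_id <- sprintf("tumor_%03d", seq_len(n))

  w <- infiltration_profiles(k, cfg$infiltration_means)
  f_mean <- pmin(w[cluster, , drop = FALSE] * cfg$infiltration_means[cluster], 0.95)
  infil <- matrix(rbeta_mc(length(f_mean), as.vector(f_mean),
                           cfg$infiltration_concentration),
                  nrow = n, dimnames = list(sample_id, types))

  # mixture means, then observed beta around them
  low <- setNames(arche$low, arche$probe_id)
  tl <- setNames(arche$tumorline, arche$probe_id)
  high <- setNames(arche$high, arche$probe_id)
  kindv <- setNames(arche$kind, arche$probe_id)
  probes <- arche$probe_id

  mix <- matrix(NA_real_, length(probes), n, dimnames = list(probes, sample_id))
  marker_like <- kindv %in% c("marker", "extra")
  type_of <- setNames(markers$cell_type, markers$probe_id)
  mj <- probes[marker_like]
  f_sel <- t(infil[, type_of[mj], drop = FALSE])          # markers x samples
  mix[mj, ] <- tl[mj] + (low[mj] - tl[mj]) * f_sel
  oth <- probes[!marker_like]
  f_bar <- rowMeans(infil)
  mix[oth, ] <- tl[oth] + (high[oth] - tl[oth]) * rep(f_bar, each = length(oth))

  # PTEN promoter block: 20 promoter CpGs, 10 at DHS
  n_pten <- 20; n_dhs <- 10
  pten_probes <- sprintf("cgPTEN%02d", seq_len(n_pten))
  is_dhs <- seq_len(n_pten) <= n_dhs
  rate <- cfg$pten_event_rates[cluster]
  any_event <- runif(n) < rate
  hyper <- mut <- cn <- logical(n)
  hyper[any_event] <- runif(sum(any_event)) < 0.60
  mut[any_event] <- runif(sum(any_event)) < 0.35
  cn[any_event] <- runif(sum(any_event)) < 0.45
  none <- any_event & !(hyper | mut | cn)
  hyper[none] <- TRUE
  hyper_arch <- ifelse(is_dhs, runif(n_pten, 0.75, 0.90), runif(n_pten, 0.55, 0.70))
  normal_arch <- runif(n_pten, 0.15, 0.35)
  pten_mix <- matrix(normal_arch, n_pten, n, dimnames = list(pten_probes, sample_id))
  pten_mix[, hyper] <- hyper_arch

  mix_all <- rbind(mix, pten_mix)
  beta <- matrix(rbeta_mc(length(mix_all), as.vector(mix_all),
                          cfg$beta_noise_concentration),
                 nrow = nrow(mix_all), dimnames = dimnames(mix_all))

  # expression linked linearly to the gene's representative promoter CpG
  gene_tab <- dplyr::bind_rows(
    tibble(gene = markers$gene[markers$is_primary],
           cpg = markers$probe_id[markers$is_primary]),
    tibble(gene = panel$annotation$gene[match(probes[kindv == "background"],
                                              panel$annotation$probe_id)],
           cpg = probes[kindv == "background"])
  )
  expr <- cfg$expression_intercept +
    cfg$expression_slope * beta[gene_tab$cpg, , drop = FALSE] +
    matrix(rnorm(nrow(gene_tab) * n, 0, cfg$expression_sd), ncol = n)
  rownames(expr) <- gene_tab$gene

  # survival: exponential with per-cluster hazards, independent uniform censoring
  lambda <- cfg$baseline_hazard * cfg$hazard_ratios[cluster]
  t_event <- rexp(n, rate = lambda)
  t_cens <- runif(n, 0, cfg$censoring_max)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  til_probs <- rbind(c(0.55, 0.35, 0.10), c(0.25, 0.45, 0.30), c(0.05, 0.30, 0.65))
  til <- vapply(cluster, function(cl) {
    sample(c("brisk", "nonbrisk", "absent"), 1, prob = til_probs[cl, ])
  }, character(1))
  mitf_neg_p <- c(0.15, 0.25, 0.40)
  clinical <- tibble(
    sample_id = sample_id,
    time = time,
    event = event,
    age = pmin(pmax(round(rnorm(n, 62, 12)), 25), 90),
    sex = sample(c("F", "M"), n, replace = TRUE),
    metastasis_type = sample(c("regional", "distant"), n, replace = TRUE,
                             prob = c(0.6, 0.4)),
    mitf_status = ifelse(runif(n) < mitf_neg_p[cluster], "negative", "positive"),
    til_category = til
  )

  pten_truth <- tibble(sample_id = sample_id, hypermethylated = hyper,
                       nonsynonymous_mutation = mut, cn_loss = cn,
                       any_event = hyper | mut | cn)
  cn_call <- character(n)
  cn_call[cn] <- sample(c("loss", "deletion"), sum(cn), replace = TRUE)
  cn_call[!cn] <- sample(c("neutral", "gain"), sum(!cn), replace = TRUE,
                         prob = c(0.92, 0.08))

  structure(
    list(
      beta = beta,
      clinical = clinical,
      expression = expr,
      pten = list(
        annotation = tibble(probe_id = pten_probes, is_dhs = is_dhs),
        mutation = tibble(sample_id = sample_id,
                          nonsynonymous_mutation = mut),
        cna = tibble(sample_id = sample_id, cn_call = cn_call)
      ),
      truth = list(
        cluster_labels = tibble(sample_id = sample_id, cluster = cluster),
        infiltration = infil,
        pten = pten_truth,
        marker_map = markers
      ),
      config = cfg
    ),
    class = "tumor_cohort"
  )
}

#' Simulate two-group exponential survival data
#'
#' Minimal generator for hazard-ratio recovery checks: exponential event times
#' with a multiplicative group hazard and independent uniform censoring.
#'
#' @param n Total sample size (split evenly).
#' @param hr True hazard ratio of group "B" vs reference group "A".
#' @param baseline_hazard Events per year in the reference group.
#' @param censoring_max Upper bound of uniform censoring (years).
#' @param seed Optional integer seed.
#' @return A tibble with `sample_id`, `group`, `time`, `event`.
#' @export
simulate_two_group_survival <- function(n = 300, hr = 2,
                                        baseline_hazard = 0.14,
                                        censoring_max = 15,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- check_count(n, "n", 4)
  group <- rep(c("A", "B"), length.out = n)
  lambda <- baseline_hazard * ifelse(group == "B", hr, 1)
  t_event <- rexp(n, lambda)
  t_cens <- runif(n, 0, censoring_max)
  tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    group = group,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
}
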