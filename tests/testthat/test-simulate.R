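test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(cluster_proportions = c(0.5, 0.4, 0.2)),
               "summing to 1")
  expect_error(simulation_config(infiltration_means = c(0.2, 0.45, 0.05)),
               "strictly decreasing")
  expect_error(simulation_config(beta_noise_concentration = 0), "positive")
  expect_error(simulation_config(n_celltypes = 1), "integer")
  expect_error(simulation_config(expression_slope = 1), "negative")
})

test_that("identical seeds give bitwise-identical output", {
  cfg <- small_config(seed = 11)
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$beta, p2$beta)
  expect_identical(p1$annotation, p2$annotation)
  c1 <- simulate_tumor_cohort(cfg, p1)
  c2 <- simulate_tumor_cohort(cfg, p2)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$clinical, c2$clinical)
  # a different seed changes the data
  p3 <- simulate_reference_panel(small_config(seed = 12))
  expect_false(identical(p1$beta, p3$beta))
})

test_that("marker bookkeeping: one CpG per gene, n_types x n_markers total", {
  cfg <- simulation_config(seed = 2, n_celltypes = 3, n_marker_cpgs_per_type = 5,
                           n_background_cpgs = 10, n_multi_cpg_genes = 0)
  panel <- simulate_reference_panel(cfg)
  mm <- panel$truth$marker_map
  expect_equal(nrow(mm), 15)
  expect_equal(as.integer(table(mm$cell_type)), rep(5L, 3))
  # every marker CpG maps to exactly one cell type
  expect_equal(anyDuplicated(mm$probe_id), 0L)
  # multi-CpG genes add decoys on existing genes only
  cfg2 <- simulation_config(seed = 2, n_celltypes = 3, n_marker_cpgs_per_type = 5,
                            n_background_cpgs = 10, n_multi_cpg_genes = 2,
                            n_extra_cpgs_per_gene = 3)
  mm2 <- simulate_reference_panel(cfg2)$truth$marker_map
  expect_equal(nrow(mm2), 15 + 6)
  expect_equal(sum(!mm2$is_primary), 6)
  expect_true(all(mm2$gene[!mm2$is_primary] %in% mm2$gene[mm2$is_primary]))
})

test_that("reference marker CpGs are unmethylated in their own type only", {
  cfg <- small_config(seed = 3, beta_noise_concentration = 50)
  panel <- simulate_reference_panel(cfg)
  mm <- panel$truth$marker_map
  si <- panel$sample_info
  for (ct in unique(mm$cell_type)) {
    cpgs <- mm$probe_id[mm$cell_type == ct]
    own <- si$sample_id[!is.na(si$cell_type) & si$cell_type == ct]
    other <- si$sample_id[si$sample_type == "immune" & !si$sample_id %in% own]
    expect_lt(mean(panel$beta[cpgs, own]), 0.3)
    expect_gt(mean(panel$beta[cpgs, other]), 0.7)
  }
  # nonimmune and tumor-line profiles hypermethylated at all marker CpGs
  nonimm <- si$sample_id[si$sample_type != "immune"]
  expect_gt(min(rowMeans(panel$beta[mm$probe_id, nonimm])), 0.7)
  expect_true(all(panel$beta >= 0 & panel$beta <= 1))
  expect_false(anyNA(panel$beta))
})

test_that("tumor beta follows the purity-weighted mixture model", {
  cfg <- small_config(seed = 4, cohort_size = 90)
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_tumor_cohort(cfg, panel)
  arche <- panel$truth$archetypes
  mm <- panel$truth$marker_map
  f <- cohort$truth$infiltration
  low <- setNames(arche$low, arche$probe_id)
  tl <- setNames(arche$tumorline, arche$probe_id)
  # observed beta deviates from the implied mixture only by beta noise
  dev <- vapply(seq_len(nrow(mm)), function(i) {
    cg <- mm$probe_id[i]
    mixture <- (1 - f[, mm$cell_type[i]]) * tl[cg] + f[, mm$cell_type[i]] * low[cg]
    mean(abs(cohort$beta[cg, rownames(f)] - mixture))
  }, numeric(1))
  expect_lt(max(dev), 0.05)
})

test_that("mixture endpoints: zero infiltration recovers the tumor-line archetype, full infiltration the immune archetype", {
  cfg <- small_config(seed = 5, cohort_size = 90,
                      infiltration_means = c(1, 0.5, 0),
                      infiltration_concentration = 5000,
                      beta_noise_concentration = 400)
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_tumor_cohort(cfg, panel)
  arche <- panel$truth$archetypes
  mm <- panel$truth$marker_map
  labels <- cohort$truth$cluster_labels
  tl <- setNames(arche$tumorline, arche$probe_id)
  low <- setNames(arche$low, arche$probe_id)
  # cluster 3 has infiltration mean 0: marker beta ~ tumor-line archetype
  s3 <- labels$sample_id[labels$cluster == 3]
  expect_lt(mean(abs(cohort$beta[mm$probe_id, s3] - tl[mm$probe_id])), 0.05)
  # samples with near-total infiltration sit at the immune-low archetype
  f <- cohort$truth$infiltration
  hits <- which(f > 0.93, arr.ind = TRUE)
  expect_gt(nrow(hits), 10)
  dev <- vapply(seq_len(nrow(hits)), function(r) {
    ct <- colnames(f)[hits[r, 2]]
    sid <- rownames(f)[hits[r, 1]]
    cgs <- mm$probe_id[mm$cell_type == ct]
    mean(abs(cohort$beta[cgs, sid] - low[cgs]))
  }, numeric(1))
  expect_lt(mean(dev), 0.08)
})

test_that("marker-CpG beta is strongly anticorrelated with planted infiltration", {
  cfg <- simulation_config(seed = 6, cohort_size = 150,
                           beta_noise_concentration = 50)
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_tumor_cohort(cfg, panel)
  mm <- panel$truth$marker_map
  f <- cohort$truth$infiltration
  sp <- vapply(which(mm$is_primary), function(i) {
    cor(f[, mm$cell_type[i]], cohort$beta[mm$probe_id[i], rownames(f)],
        method = "spearman")
  }, numeric(1))
  # per-CpG anticorrelation is strong overall; cell types with a narrow
  # cluster-weighted infiltration range correlate less tightly than the
  # broad-range types, which reach -0.9 and beyond
  expect_lte(median(sp), -0.8)
  expect_lt(max(sp), -0.5)
  by_type <- tapply(sp, mm$cell_type[mm$is_primary], mean)
  expect_lte(min(by_type), -0.9)
})

test_that("cluster 1 sits below cluster 3 in marker methylation for every cell type", {
  cfg <- small_config(seed = 7, cohort_size = 120)
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_tumor_cohort(cfg, panel)
  mm <- panel$truth$marker_map
  labels <- cohort$truth$cluster_labels
  s1 <- labels$sample_id[labels$cluster == 1]
  s3 <- labels$sample_id[labels$cluster == 3]
  for (ct in unique(mm$cell_type)) {
    cpgs <- mm$probe_id[mm$cell_type == ct]
    expect_lt(mean(cohort$beta[cpgs, s1]), mean(cohort$beta[cpgs, s3]))
  }
  expect_true(all(cohort$beta >= 0 & cohort$beta <= 1))
  expect_false(anyNA(cohort$beta))
})

test_that("two-group survival generator hits the requested censoring regime", {
  d <- simulate_two_group_survival(2000, hr = 2, seed = 8)
  expect_true(all(d$time > 0))
  expect_true(all(d$event %in% 0:1))
  cens <- 1 - mean(d$event)
  expect_gt(cens, 0.2); expect_lt(cens, 0.4)
  # group B events come faster
  expect_lt(median(d$time[d$group == "B" & d$event == 1]),
            median(d$time[d$group == "A" & d$event == 1]))
})
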