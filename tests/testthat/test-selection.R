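test_that("combining signatures unions genes and removes conflicts", {
  a <- tibble::tibble(gene = c("G", "H", "K"),
                      cell_type = c("NK cells", "Tregs", "Monocytes"))
  b <- tibble::tibble(gene = c("G", "K"),
                      cell_type = c("B cells", "Monocytes"))
  out <- combine_signatures(a, b)
  expect_false("G" %in% out$gene)              # conflicting assignment removed
  expect_equal(out$cell_type[out$gene == "H"], "Tregs")  # single-source kept
  expect_equal(sum(out$gene == "K"), 1)        # agreeing duplicate kept once
  expect_equal(attr(out, "n_conflicts"), 1)
  expect_equal(attr(out, "conflicts")$gene, "G")
  # all genes conflicting -> empty union -> error
  expect_error(
    combine_signatures(tibble::tibble(gene = "X", cell_type = "A"),
                       tibble::tibble(gene = "X", cell_type = "B")),
    "no genes left"
  )
  expect_error(combine_signatures(a[0, ], b), "non-empty")
})

test_that("promoter mapping enforces window, signature and platform filters", {
  sig <- tibble::tibble(gene = c("G1", "G2", "G3", "G4"), cell_type = "T")
  ann <- tibble::tibble(
    probe_id = c("cg1", "cg2", "cg3", "cg4", "cg5"),
    gene = c("G1", "G2", "G3", "G4", "NOT_IN_SIG"),
    dist_to_tss_bp = c(1500L, 0L, -1499L, 200L, 10L),
    platform_450k = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    platform_epic = TRUE
  )
  out <- map_promoter_cpgs(sig, ann)
  expect_false("cg1" %in% out$probe_id)   # |dist| = 1500 excluded (strict <)
  expect_true("cg2" %in% out$probe_id)    # 0 bp interior point
  expect_true("cg3" %in% out$probe_id)    # signed distance taken absolute
  expect_false("cg4" %in% out$probe_id)   # EPIC-only probe excluded
  expect_false("cg5" %in% out$probe_id)   # gene not in signature
  expect_equal(out$cell_type, rep("T", 2))
  expect_error(map_promoter_cpgs(sig, ann[, -3]), "missing column")
})

test_that("binarization uses beta < 0.3 unmethylated, >= 0.3 methylated", {
  m <- matrix(c(0.29, 0.30, 0, NA), 2, 2,
              dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  b <- binarize_beta(m)
  expect_identical(b["cg1", "s1"], 0L)
  expect_identical(b["cg2", "s1"], 1L)
  expect_identical(b["cg1", "s2"], 0L)
  expect_true(is.na(b["cg2", "s2"]))      # missing propagates
  zero <- matrix(0, 3, 3, dimnames = list(paste0("cg", 1:3), paste0("s", 1:3)))
  expect_true(all(binarize_beta(zero) == 0L))
  expect_error(binarize_beta(m, threshold = 1.2), "\\(0, 1\\)")
})

test_that("Fisher differential p-values match the enumeration oracle", {
  # [[5 meth, 1 unmeth], [0, 6]]: p = 12/792
  binary <- rbind(cg_a = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
                  cg_b = c(1, 1, 1, 0, 0, 0, 1, 1, 1, 0, 0, 0))
  types <- rep(c("A", "B"), each = 6)
  res <- fisher_differential(binary, types)
  expect_equal(res$p[res$probe_id == "cg_a"], 12 / 792, tolerance = 1e-12)
  # identical rows [[3,3],[3,3]]: all tables as or less probable -> p = 1
  expect_equal(res$p[res$probe_id == "cg_b"], 1, tolerance = 1e-12)
  # 3 types x 6 samples, one all-methylated vs others all-unmethylated,
  # among 16 candidates: p matches enumeration and survives FDR < 0.01
  b3 <- rbind(cg_sig = c(rep(1, 6), rep(0, 12)),
              matrix(1, 15, 18, dimnames = list(paste0("cg_null", 1:15), NULL)))
  t3 <- rep(c("A", "B", "C"), each = 6)
  r3 <- fisher_differential(b3, t3)
  tab <- table(factor(t3), factor(b3["cg_sig", ], levels = 0:1))
  expect_equal(r3$p[r3$probe_id == "cg_sig"], oracle_rx2_p(tab), tolerance = 1e-10)
  expect_equal(r3$p[r3$probe_id == "cg_sig"], 3 / choose(18, 6), tolerance = 1e-10)
  expect_lt(r3$fdr[r3$probe_id == "cg_sig"], 0.01)
  expect_error(fisher_differential(binary, rep("A", 12)), "2 cell types")
})

test_that("CpGs with too many missing reference values are excluded from FDR", {
  binary <- rbind(cg_ok = c(1, 1, 1, 0, 0, 0),
                  cg_na = c(NA, NA, NA, NA, 0, 1))
  res <- fisher_differential(binary, rep(c("A", "B"), each = 3))
  expect_false(res$excluded[res$probe_id == "cg_ok"])
  expect_true(res$excluded[res$probe_id == "cg_na"])
  expect_true(is.na(res$fdr[res$probe_id == "cg_na"]))
})

test_that("nonimmune hypermethylation filter uses strict boundaries", {
  mk <- function(vals) matrix(vals, nrow = 1,
                              dimnames = list("cg1", paste0("s", seq_along(vals))))
  p98 <- selection_params(mode = "melanoma")
  # 49/50 above 0.7 -> fraction 0.98, not > 0.98 -> fail
  expect_false(nonimmune_hypermethylation_filter(mk(c(rep(0.8, 49), 0.5)), p98)$pass)
  # 50/50 at 0.71 -> pass
  expect_true(nonimmune_hypermethylation_filter(mk(rep(0.71, 50)), p98)$pass)
  # beta exactly 0.7 does not count as hypermethylated (strict >)
  expect_false(nonimmune_hypermethylation_filter(mk(rep(0.70, 50)), p98)$pass)
  p90 <- selection_params(mode = "pancancer")
  expect_equal(p90$nonimmune_sample_fraction, 0.90)
  expect_false(nonimmune_hypermethylation_filter(mk(c(rep(0.8, 9), 0.5)), p90)$pass)
  expect_true(nonimmune_hypermethylation_filter(mk(rep(0.8, 10)), p90)$pass)
  # missing values drop out of numerator and denominator
  expect_true(nonimmune_hypermethylation_filter(mk(c(rep(0.8, 10), NA, NA)), p90)$pass)
})

test_that("best-CpG-per-gene selection is an argmin with deterministic ties", {
  cand <- tibble::tibble(
    gene = c("G1", "G1", "G2", "G3", "G3"),
    probe_id = c("cg002", "cg001", "cg010", "cg021", "cg020"),
    cell_type = "T",
    p = c(0.001, 0.005, 0.01, 0.002, 0.002),
    fdr = p * 2,
    beta_range = c(0.5, 0.5, 0.5, 0.3, 0.3)
  )
  out <- select_best_cpg_per_gene(cand)
  expect_equal(out$cpg[out$gene == "G1"], "cg002")   # smaller p wins
  expect_equal(out$cpg[out$gene == "G2"], "cg010")   # singleton kept
  expect_equal(out$cpg[out$gene == "G3"], "cg020")   # tie -> lexicographic probe ID
  # larger beta range breaks a p tie before the probe ID
  cand2 <- cand
  cand2$beta_range <- c(0.5, 0.5, 0.5, 0.9, 0.3)
  expect_equal(select_best_cpg_per_gene(cand2)$cpg[3], "cg021")
})

test_that("full selection recovers planted markers and rejects background", {
  cfg <- small_config(seed = 21)
  panel <- simulate_reference_panel(cfg)
  sel <- run_selection(panel)
  mm <- panel$truth$marker_map
  expect_gte(mean(mm$probe_id[mm$is_primary] %in% sel$pairs$cpg), 0.85)
  expect_equal(sum(!sel$pairs$cpg %in% mm$probe_id), 0)
  # unique genes and unique CpGs; both filters re-checkable post hoc
  expect_equal(anyDuplicated(sel$pairs$gene), 0L)
  expect_equal(anyDuplicated(sel$pairs$cpg), 0L)
  chk <- sel$candidates[sel$candidates$probe_id %in% sel$pairs$cpg, ]
  expect_true(all(chk$fisher_pass & chk$pass))
  expect_true(all(diff(match(sel$funnel$step,
                             c("signature_genes", "candidate_cpgs", "candidate_genes",
                               "fisher_pass", "nonimmune_pass", "both_filters",
                               "final_pairs"))) > 0))
  # multi-CpG genes still contribute exactly one CpG
  expect_lte(max(table(sel$pairs$gene)), 1L)
})

test_that("relaxing the nonimmune fraction never shrinks the selected set", {
  cfg <- small_config(seed = 22)
  panel <- simulate_reference_panel(cfg)
  strict <- run_selection(panel, selection_params(mode = "melanoma"))
  relaxed <- run_selection(panel, selection_params(mode = "pancancer"))
  expect_true(all(strict$pairs$cpg %in% relaxed$pairs$cpg))
  expect_gte(nrow(relaxed$pairs), nrow(strict$pairs))
})

test_that("permuting reference cell-type labels kills the signal", {
  cfg <- small_config(seed = 23)
  panel <- simulate_reference_panel(cfg)
  set.seed(99)
  si <- panel$sample_info
  imm <- si$sample_type == "immune"
  si$cell_type[imm] <- sample(si$cell_type[imm])
  sel <- run_selection(panel$beta, sample_info = si,
                       sig_a = panel$signature_a, sig_b = panel$signature_b,
                       annotation = panel$annotation)
  n_cand <- sum(!is.na(sel$candidates$fdr))
  expect_lte(sum(sel$candidates$fisher_pass) / n_cand, 0.05)
})

test_that("degenerate selection inputs raise errors", {
  cfg <- small_config(seed = 24)
  panel <- simulate_reference_panel(cfg)
  empty <- tibble::tibble(gene = character(), cell_type = character())
  expect_error(run_selection(panel, sig_a = empty, sig_b = empty), "non-empty")
  expect_error(run_selection(panel$beta, sample_info = panel$sample_info,
                             sig_a = panel$signature_a, sig_b = NULL,
                             annotation = panel$annotation),
               "supply")
})
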