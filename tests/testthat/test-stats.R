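test_that("Kruskal-Wallis and delta-beta arithmetic match the rank oracle", {
  scores <- tibble::tibble(sample_id = sprintf("s%d", 1:9),
                           T_cells = c(1, 2, 3, 4, 5, 6, 7, 8, 9) / 10)
  labels <- setNames(rep(1:3, each = 3), scores$sample_id)
  db <- delta_beta_contrasts(scores, labels)
  # H = 7.2 on {1,2,3},{4,5,6},{7,8,9}; p from chi-square with 2 df
  ora <- oracle_kruskal(scores$T_cells, rep(1:3, each = 3))
  expect_equal(ora$h, 7.2, tolerance = 1e-12)
  expect_equal(unique(db$kw_p), ora$p, tolerance = 1e-12)
  expect_equal(unique(db$kw_p), 0.02732, tolerance = 1e-3)
  # abs delta beta is the difference of cluster medians
  expect_equal(db$abs_delta_beta[db$comparison == "1 vs 3"], 0.6)
  d2 <- delta_beta_contrasts(
    tibble::tibble(sample_id = sprintf("s%d", 1:6),
                   ct = c(0.65, 0.65, 0.65, 0.26, 0.26, 0.26)),
    setNames(rep(1:2, each = 3), sprintf("s%d", 1:6))
  )
  expect_equal(d2$abs_delta_beta, 0.39)
})

test_that("Dunn z and per-comparison FDR match an independent oracle", {
  set.seed(81)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n <- sample(12:30, 1)
    g <- sample(rep(seq_len(k), length.out = n))
    x <- round(runif(n) + g * runif(1, 0, 0.5), 1)  # ties likely
    scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:n), ct1 = x,
                             ct2 = round(rev(x) + runif(n, 0, 0.1), 2))
    db <- delta_beta_contrasts(scores, setNames(g, scores$sample_id))
    ora <- oracle_dunn(x, g)
    for (cmp in ora$comparison) {
      expect_equal(db$dunn_z[db$comparison == cmp & db$cell_type == "ct1"],
                   ora$z[ora$comparison == cmp], tolerance = 1e-10)
      expect_equal(db$dunn_p[db$comparison == cmp & db$cell_type == "ct1"],
                   ora$p[ora$comparison == cmp], tolerance = 1e-10)
    }
    # FDR computed across cell types within each comparison, order-invariant
    for (cmp in unique(db$comparison)) {
      sub <- db[db$comparison == cmp, ]
      expect_equal(sub$dunn_fdr, p.adjust(sub$dunn_p, "BH"), tolerance = 1e-12)
    }
    shuffled <- scores[sample(nrow(scores)), ]
    db2 <- delta_beta_contrasts(shuffled, setNames(g, scores$sample_id))
    expect_equal(dplyr::arrange(db2, cell_type, comparison)$dunn_fdr,
                 dplyr::arrange(db, cell_type, comparison)$dunn_fdr,
                 tolerance = 1e-12)
  }
})

test_that("null scores give calibrated Dunn FDRs", {
  set.seed(82)
  frac_sig <- replicate(200, {
    scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                             a = runif(30), b = runif(30), c = runif(30),
                             d = runif(30))
    db <- suppressWarnings(
      delta_beta_contrasts(scores, setNames(rep(1:3, each = 10),
                                            scores$sample_id)))
    mean(db$dunn_fdr < 0.05)
  })
  expect_lte(mean(frac_sig), 0.10)
})

test_that("small clusters are excluded from contrasts with a warning", {
  scores <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                           ct = runif(8))
  labels <- setNames(c(rep(1, 4), rep(2, 2), rep(3, 2)), scores$sample_id)
  expect_warning(expect_error(delta_beta_contrasts(scores, labels),
                              "at least 2 clusters"),
                 "fewer than 3")
  labels2 <- setNames(c(rep(1, 3), rep(2, 3), rep(3, 2)), scores$sample_id)
  expect_warning(db <- delta_beta_contrasts(scores, labels2), "fewer than 3")
  expect_equal(unique(db$comparison), "1 vs 2")
})

test_that("categorical associations use Fisher for 2x2 and chi-square beyond", {
  # [[10,0],[0,10]]: two-sided Fisher p = 2 / C(20,10)
  x <- rep(c("c1", "c2"), each = 10)
  y <- rep(c("yes", "no"), each = 10)
  res <- categorical_association(x, y)
  expect_equal(res$test, "fisher")
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  # perfect independence -> p = 1
  res2 <- categorical_association(rep(c("c1", "c2"), 10),
                                  rep(c("yes", "yes", "no", "no"), 5))
  expect_equal(res2$p, 1)
  # 3-level factor goes through chi-square
  set.seed(83)
  x3 <- sample(c("c1", "c2", "c3"), 300, TRUE)
  y3 <- sample(c("u", "v", "w"), 300, TRUE)
  res3 <- categorical_association(x3, y3)
  expect_true(res3$test %in% c("chisq", "chisq_mc"))
  expect_error(categorical_association(rep("c1", 10), rep(c("a", "b"), 5)),
               "degenerate")
  # batched version corrects across annotations
  df <- tibble::tibble(sample_id = sprintf("s%d", 1:300), a1 = y3,
                       a2 = sample(y3))
  batch <- categorical_associations(df, setNames(x3, df$sample_id),
                                    c("a1", "a2"))
  expect_equal(batch$fdr, p.adjust(batch$p, "BH"))
})

test_that("Cox fits recover null and true effects and flag degenerate groups", {
  # identical survival in both groups -> HR 1, p ~ 1
  base <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                         event = c(1, 1, 0, 1, 1, 0, 1, 1))
  dup <- dplyr::bind_rows(base, base)
  dup$group <- rep(c("A", "B"), each = 8)
  res <- fit_survival(dup, "group", endpoint = "OS")
  expect_equal(res$hr[1], 1, tolerance = 1e-8)
  expect_gt(res$p[1], 0.95)
  expect_true(res$ci_low[1] <= res$hr[1] && res$hr[1] <= res$ci_high[1])
  # a group without events is non-estimable, not an exception
  noev <- dup
  noev$event[noev$group == "B"] <- 0
  res2 <- fit_survival(noev, "group", endpoint = "OS")
  expect_true(res2$non_estimable[1])
  expect_true(is.na(res2$hr[1]))
  # parameter recovery on exponential data with HR 2
  d <- simulate_two_group_survival(400, hr = 2, seed = 84)
  res3 <- fit_survival(d, "group", endpoint = "OS")
  expect_equal(log(res3$hr[1]), log(2), tolerance = 0.35)
  # closed-form events-ratio estimator agrees within simulation error
  rate_a <- sum(d$event[d$group == "A"]) / sum(d$time[d$group == "A"])
  rate_b <- sum(d$event[d$group == "B"]) / sum(d$time[d$group == "B"])
  expect_equal(log(res3$hr[1]), log(rate_b / rate_a), tolerance = 0.15)
  # multivariate mode reports covariate terms too
  d$age <- rnorm(400, 60, 10)
  res4 <- fit_survival(d, "group", covariates = "age", endpoint = "DMFS")
  expect_true(any(res4$term == "age"))
  expect_equal(unique(res4$model), "multivariate")
  expect_error(fit_survival(dplyr::mutate(dup, time = time - 1), "group"),
               "positive")
})

test_that("the per-cell-type survival screen corrects across cell types", {
  cfg <- small_config(seed = 85, cohort_size = 150)
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_tumor_cohort(cfg, panel)
  sel <- run_selection(panel)
  dich <- dichotomize_score(methylation_score(cohort$beta, sel))
  scr <- survival_screen(cohort$clinical, dich, endpoint = "OS")
  est <- !scr$non_estimable
  expect_equal(scr$fdr[est], p.adjust(scr$p[est], "BH"))
  expect_true(all(scr$hr_category[!is.na(scr$hr)] %in% c("large", "small")))
  # a degenerate single-level cell type is flagged, not fatal
  dich$Monocytes <- "not_hypermethylated"
  scr2 <- survival_screen(cohort$clinical, dich)
  expect_true(scr2$non_estimable[scr2$cell_type == "Monocytes"])
})

test_that("Kaplan-Meier output and log-rank behave at the edges", {
  d <- simulate_two_group_survival(200, hr = 1, seed = 86)
  one <- km_logrank(d[d$group == "A", ], rep("A", sum(d$group == "A")))
  expect_true(is.na(one$logrank_p))
  same <- km_logrank(dplyr::bind_rows(d, d) |>
                       dplyr::mutate(group = rep(c("A", "B"), each = nrow(d))),
                     "group")
  expect_gt(same$logrank_p, 0.95)
  # risk table covers the requested horizons per group
  km <- km_logrank(d, "group")
  expect_setequal(unique(km$risk_table$group), c("A", "B"))
  expect_equal(sort(unique(km$risk_table$time)), seq(0, 10, 2.5))
  # strong effects are detected
  d3 <- simulate_two_group_survival(400, hr = 3, seed = 87)
  expect_lt(km_logrank(d3, "group")$logrank_p, 0.001)
})
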