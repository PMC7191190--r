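#' Cluster contrasts of per-cell-type scores
#'
#' For every immune cell type, tests the score across clusters
#' (Kruskal-Wallis) and between each cluster pair (Dunn post hoc z-test with
#' tie correction), reporting the absolute difference of cluster median
#' scores. Benjamini-Hochberg correction is applied across cell types
#' separately within each cluster-pair comparison. Clusters with fewer than 3
#' samples are excluded with a warning.
#'
#' The Dunn statistic is
#' `z = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T)(1/n_a + 1/n_b))` with tie
#' term `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p.
#'
#' @param scores An `immune_scores` tibble (or data frame with `sample_id`
#'   and one numeric column per cell type).
#' @param labels Cluster labels (named vector, tibble, or `immune_consensus`).
#' @return A `delta_beta_table` tibble: `cell_type`, `comparison`,
#'   `abs_delta_beta`, `kw_p`, `dunn_z`, `dunn_p`, `dunn_fdr`.
#' @export
delta_beta_contrasts <- function(scores, labels) {
  scores <- as_tibble(scores)
  labels <- normalize_labels(labels, scores$sample_id)
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warn(sprintf("excluding cluster(s) %s with fewer than 3 samples.",
                 paste(small, collapse = ", ")))
    keep <- !labels %in% as.integer(small)
    scores <- scores[keep, ]
    labels <- labels[keep]
  }
  cls <- sort(unique(labels))
  if (length(cls) < 2) abort("need at least 2 clusters with >= 3 samples.")
  prs <- utils::combn(cls, 2, simplify = FALSE)
  types <- setdiff(names(scores), "sample_id")

  rows <- purrr::map(types, function(ct) {
    x <- scores[[ct]]
    ok <- !is.na(x)
    xx <- x[ok]; g <- labels[ok]
    if (length(unique(xx)) < 2) {
      kw_p <- 1
    } else {
      kw_p <- kruskal.test(xx, factor(g))$p.value
    }
    d <- dunn_test(xx, g)
    purrr::map(prs, function(pr) {
      med <- c(median(xx[g == pr[1]]), median(xx[g == pr[2]]))
      key <- paste(pr, collapse = " vs ")
      di <- d[d$comparison == key, ]
      tibble(cell_type = ct, comparison = key,
             abs_delta_beta = abs(diff(med)),
             kw_p = kw_p,
             dunn_z = if (nrow(di)) di$z else NA_real_,
             dunn_p = if (nrow(di)) di$p else NA_real_)
    }) |> list_rbind()
  }) |> list_rbind()

  out <- rows |>
    group_by(.data$comparison) |>
    mutate(dunn_fdr = p.adjust(.data$dunn_p, method = "BH")) |>
    ungroup()
  class(out) <- c("delta_beta_table", class(out))
  out
}

# Tie-corrected Dunn pairwise z-tests on ranks.
dunn_test <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  cls <- sort(unique(g))
  purrr::map(utils::combn(cls, 2, simplify = FALSE), function(pr) {
    a <- r[g == pr[1]]; b <- r[g == pr[2]]
    se <- sqrt(base_var * (1 / length(a) + 1 / length(b)))
    z <- (mean(a) - mean(b)) / se
    tibble(comparison = paste(pr, collapse = " vs "),
           z = z, p = 2 * pnorm(-abs(z)))
  }) |> list_rbind()
}

#' Association between cluster labels and a categorical annotation
#'
#' Fisher's exact test for 2x2 tables; Pearson chi-square without continuity
#' correction otherwise, replaced by a seeded Monte-Carlo exact p when any
#' expected count falls below 5.
#'
#' @param x,y Two categorical vectors (e.g. cluster labels and a staining
#'   category); NA pairs are dropped.
#' @param mc_B Monte-Carlo replicates for the small-expected-count fallback.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return One-row tibble: `test`, `statistic`, `df`, `p`, `n`.
#' @export
categorical_association <- function(x, y, mc_B = 10000, seed = 1) {
  ok <- !is.na(x) & !is.na(y)
  tab <- table(droplevels(factor(x[ok])), droplevels(factor(y[ok])))
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("degenerate contingency table: need >= 2 rows and >= 2 columns.")
  }
  n <- sum(tab)
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    p <- fisher.test(tab)$p.value
    return(tibble(test = "fisher", statistic = NA_real_, df = NA_real_,
                  p = p, n = n))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < 5)) {
    ct <- withr::with_seed(seed, suppressWarnings(
      chisq.test(tab, simulate.p.value = TRUE, B = mc_B)))
    tibble(test = "chisq_mc", statistic = unname(ct$statistic),
           df = NA_real_, p = ct$p.value, n = n)
  } else {
    ct <- chisq.test(tab, correct = FALSE)
    tibble(test = "chisq", statistic = unname(ct$statistic),
           df = unname(ct$parameter), p = ct$p.value, n = n)
  }
}

#' Batched categorical associations with FDR
#'
#' Runs [categorical_association()] of the cluster labels against each listed
#' annotation column and corrects across annotations (Benjamini-Hochberg).
#'
#' @param data Data frame of per-sample annotations.
#' @param labels Cluster labels aligned with `data` (or named / tibble form).
#' @param columns Character vector of annotation column names.
#' @param ... Passed to [categorical_association()].
#' @return Tibble with one row per annotation, plus `fdr`.
#' @export
categorical_associations <- function(data, labels, columns, ...) {
  data <- as_tibble(data)
  if (!is.null(names(labels)) && "sample_id" %in% names(data)) {
    labels <- labels[data$sample_id]
  }
  out <- purrr::map(columns, function(cl) {
    bind_cols(tibble(annotation = cl),
              categorical_association(labels, data[[cl]], ...))
  }) |> list_rbind()
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Cox proportional-hazards models for clusters or dichotomized scores
#'
#' Fits a proportional-hazards model (Efron tie handling) of survival on a
#' grouping variable, optionally adjusted for covariates, and reports the
#' hazard ratio, Wald 95% confidence interval and Wald p per non-reference
#' level. The reference is the first factor level (cluster 1 /
#' not-hypermethylated). Group levels with zero events are flagged
#' non-estimable instead of raising an error.
#'
#' @param clinical Data frame with `time` (> 0) and `event` (0/1) columns
#'   plus any covariates.
#' @param group Grouping: a column name in `clinical` or a vector aligned
#'   with its rows.
#' @param covariates Character vector of covariate column names (multivariate
#'   mode), e.g. `c("age", "sex")` for DMFS or `"metastasis_type"` for
#'   DSS/OS.
#' @param endpoint Endpoint label: `"DMFS"`, `"DSS"` or `"OS"`.
#' @param reference Reference level of the group factor.
#' @return A `cox_result` tibble: `term`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `model`, `endpoint`, `non_estimable`, `hr_category` (`"large"` when
#'   HR >= 1.5 or <= 0.66).
#' @export
fit_survival <- function(clinical, group, covariates = NULL,
                         endpoint = c("DSS", "DMFS", "OS"),
                         reference = NULL) {
  endpoint <- match.arg(endpoint)
  clinical <- as_tibble(clinical)
  if (!all(c("time", "event") %in% names(clinical))) {
    abort("`clinical` needs columns time and event.")
  }
  if (any(clinical$time <= 0, na.rm = TRUE)) abort("survival times must be positive.")
  if (!all(clinical$event %in% c(0, 1, NA))) abort("`event` must be 0/1.")
  g <- if (is.character(group) && length(group) == 1 && group %in% names(clinical)) {
    clinical[[group]]
  } else {
    group
  }
  g <- factor(g)
  if (!is.null(reference)) g <- stats::relevel(g, ref = as.character(reference))
  model <- if (is.null(covariates)) "univariate" else "multivariate"
  df <- clinical
  df$.group <- g
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ .group",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  ))

  ev <- tapply(df$event, df$.group, sum)
  bad_levels <- names(ev)[is.na(ev) | ev == 0]

  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = df, ties = "efron"),
             error = function(e) NULL),
    warning = function(w) {
      # monotone likelihood (a group without events) is reported via the
      # non-estimable flag, not as a warning
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  lv <- levels(g)[-1]
  term_names <- paste0(".group", lv)

  mk_row <- function(term, label) {
    if (is.null(fit) || !(term %in% names(stats::coef(fit)))) {
      return(tibble(term = label, hr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, non_estimable = TRUE))
    }
    co <- stats::coef(fit)[term]
    se <- sqrt(diag(fit$var))[match(term, names(stats::coef(fit)))]
    non_est <- label %in% paste0("group:", bad_levels) || !is.finite(se) || se > 50
    z <- co / se
    tibble(term = label, hr = exp(co),
           ci_low = exp(co - 1.96 * se), ci_high = exp(co + 1.96 * se),
           p = 2 * pnorm(-abs(z)), non_estimable = non_est)
  }
  rows <- purrr::map2(term_names, paste0("group:", lv), mk_row) |> list_rbind()
  if (length(covariates) && !is.null(fit)) {
    cov_terms <- setdiff(names(stats::coef(fit)), term_names)
    rows <- bind_rows(rows, purrr::map2(cov_terms, cov_terms, mk_row) |> list_rbind())
  }
  rows <- rows |>
    mutate(
      hr = ifelse(.data$non_estimable, NA_real_, .data$hr),
      ci_low = ifelse(.data$non_estimable, NA_real_, .data$ci_low),
      ci_high = ifelse(.data$non_estimable, NA_real_, .data$ci_high),
      p = ifelse(.data$non_estimable, NA_real_, .data$p),
      model = model, endpoint = endpoint,
      hr_category = dplyr::case_when(
        is.na(.data$hr) ~ NA_character_,
        .data$hr >= 1.5 | .data$hr <= 0.66 ~ "large",
        TRUE ~ "small"
      )
    )
  class(rows) <- c("cox_result", class(rows))
  rows
}

#' Per-cell-type survival screen on dichotomized methylation scores
#'
#' Fits a univariate Cox model per immune cell type with the dichotomized
#' methylation score (reference: not hypermethylated), corrects across cell
#' types (Benjamini-Hochberg; significance at adjusted p < 0.1), and flags
#' cell types where the hazard ratio is not estimable (a category absent or
#' without events) or where the score itself is missing.
#'
#' @param clinical Data frame with `time` and `event`.
#' @param dichotomized Output of [dichotomize_score()] on an `immune_scores`
#'   tibble (columns `sample_id` + one category column per cell type).
#' @param endpoint Endpoint label.
#' @param fdr_threshold Significance gate on the adjusted p; default 0.1.
#' @return Tibble: `cell_type`, `hr`, `ci_low`, `ci_high`, `p`, `fdr`,
#'   `significant`, `non_estimable`, `hr_category`, `endpoint`.
#' @export
survival_screen <- function(clinical, dichotomized, endpoint = "OS",
                            fdr_threshold = 0.1) {
  clinical <- as_tibble(clinical)
  dichotomized <- as_tibble(dichotomized)
  stopifnot("sample_id" %in% names(dichotomized))
  dat <- left_join(clinical, dichotomized, by = "sample_id")
  types <- setdiff(names(dichotomized), "sample_id")
  rows <- purrr::map(types, function(ct) {
    gv <- dat[[ct]]
    if (all(is.na(gv)) || length(unique(stats::na.omit(gv))) < 2) {
      return(tibble(cell_type = ct, hr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, non_estimable = TRUE))
    }
    sub <- dat[!is.na(gv), ]
    res <- fit_survival(sub, factor(gv[!is.na(gv)],
                                    levels = c("not_hypermethylated", "hypermethylated")),
                        endpoint = "OS")
    tibble(cell_type = ct, hr = res$hr[1], ci_low = res$ci_low[1],
           ci_high = res$ci_high[1], p = res$p[1],
           non_estimable = res$non_estimable[1])
  }) |> list_rbind()
  rows$fdr <- NA_real_
  est <- !rows$non_estimable
  rows$fdr[est] <- p.adjust(rows$p[est], method = "BH")
  rows |>
    mutate(
      significant = !is.na(.data$fdr) & .data$fdr < fdr_threshold,
      hr_category = dplyr::case_when(
        is.na(.data$hr) ~ NA_character_,
        .data$hr >= 1.5 | .data$hr <= 0.66 ~ "large",
        TRUE ~ "small"
      ),
      endpoint = endpoint
    )
}

#' Kaplan-Meier curves with numbers at risk and log-rank test
#'
#' Estimates per-group survival curves, a numbers-at-risk table at fixed
#' horizons, and the log-rank p-value across groups. The display horizon
#' (default 10 years) only truncates reporting, never the test.
#'
#' @param clinical Data frame with `time` and `event`.
#' @param group Column name in `clinical` or aligned vector; a single group
#'   yields curves only (no test).
#' @param horizon Display horizon in the time unit of `time`.
#' @param at Times for the numbers-at-risk table.
#' @return A `km_result` list: `fit` ([survival::survfit] object),
#'   `risk_table` tibble, `logrank_p` (NA for one group), `horizon`.
#' @export
km_logrank <- function(clinical, group, horizon = 10,
                       at = seq(0, horizon, length.out = 5)) {
  clinical <- as_tibble(clinical)
  g <- if (is.character(group) && length(group) == 1 && group %in% names(clinical)) {
    clinical[[group]]
  } else {
    group
  }
  df <- tibble(time = clinical$time, event = clinical$event, group = factor(g))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, times = at, extend = TRUE)
  strata <- if (is.null(sm$strata)) rep("all", length(sm$time)) else {
    sub("^group=", "", as.character(sm$strata))
  }
  risk <- tibble(group = strata, time = sm$time, n_risk = sm$n.risk,
                 surv = sm$surv)
  p <- NA_real_
  if (nlevels(df$group) > 1) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    p <- pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  }
  structure(list(fit = fit, risk_table = risk, logrank_p = p, horizon = horizon),
            class = "km_result")
}
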