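#' Pipeline configuration
#'
#' Collects simulation, selection, clustering, scoring and statistics
#' settings, either programmatically or from a YAML file. `mode` switches the
#' nonimmune hypermethylation sample-fraction default (0.98 melanoma, 0.90
#' pan-cancer).
#'
#' @param seed Master seed for the run.
#' @param mode `"melanoma"` or `"pancancer"`.
#' @param simulation A [simulation_config()]; defaults to
#'   `simulation_config(seed = seed)`.
#' @param selection A [selection_params()]; defaults follow `mode`.
#' @param k Number of immune methylation clusters.
#' @param consensus_iter,consensus_subsample Consensus-clustering settings.
#' @param kw_fdr_threshold Centroid CpG gate (Kruskal-Wallis FDR).
#' @param classify_threshold Kendall tau threshold for classification.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, mode = c("melanoma", "pancancer"),
                            simulation = NULL, selection = NULL,
                            k = 3, consensus_iter = 1000,
                            consensus_subsample = 0.8,
                            kw_fdr_threshold = 1e-4,
                            classify_threshold = 0.3) {
  mode <- match.arg(mode)
  structure(list(
    seed = check_count(seed, "seed", 0),
    mode = mode,
    simulation = simulation %||% simulation_config(seed = seed),
    selection = selection %||% selection_params(mode = mode),
    k = check_count(k, "k", 2),
    consensus_iter = check_count(consensus_iter, "consensus_iter"),
    consensus_subsample = consensus_subsample,
    kw_fdr_threshold = kw_fdr_threshold,
    classify_threshold = classify_threshold
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the arguments of
#'   [pipeline_config()], with `simulation` passed to [simulation_config()]
#'   and `selection` to [selection_params()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) {
    do.call(simulation_config, modifyList(list(seed = y$seed %||% 1L), y$simulation))
  }
  sel <- if (!is.null(y$selection)) do.call(selection_params, y$selection)
  pipeline_config(
    seed = y$seed %||% 1L,
    mode = y$mode %||% "melanoma",
    simulation = sim, selection = sel,
    k = y$k %||% 3,
    consensus_iter = y$consensus_iter %||% 1000,
    consensus_subsample = y$consensus_subsample %||% 0.8,
    kw_fdr_threshold = y$kw_fdr_threshold %||% 1e-4,
    classify_threshold = y$classify_threshold %||% 0.3
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate, select, cluster, centroids, classify, score, pten and
#' stats in order, writing every stage's tables under `outdir` plus a
#' `manifest.json` with versions, seed and parameters. Re-running with the
#' same configuration reproduces all stochastic stages bit-identically (only
#' the manifest timestamp differs).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # 1. simulate
  panel <- stage("simulate", simulate_reference_panel(config$simulation))
  cohort <- stage("simulate", simulate_tumor_cohort(config$simulation, panel))
  sim_dir <- file.path(outdir, "simulate")
  write_simulation(panel, cohort, sim_dir)
  stages <- c(stages, "simulate")

  # 2. select
  sel <- stage("select", run_selection(panel, config$selection))
  sel_dir <- file.path(outdir, "select"); dir.create(sel_dir, showWarnings = FALSE)
  write_stage_tsv(sel$pairs, sel_dir, "selected_pairs.tsv")
  jsonlite::write_json(
    list(fdr_method = sel$fdr_method,
         funnel = setNames(as.list(sel$funnel$n), sel$funnel$step)),
    file.path(sel_dir, "funnel.json"), auto_unbox = TRUE, pretty = TRUE
  )
  stages <- c(stages, "select")

  # 3. cluster
  beta_sel <- cohort$beta[intersect(sel$pairs$cpg, rownames(cohort$beta)), ,
                          drop = FALSE]
  cons <- stage("cluster", consensus_cluster(
    beta_sel, k = config$k, n_iter = config$consensus_iter,
    subsample = config$consensus_subsample, seed = config$seed
  ))
  cl_dir <- file.path(outdir, "cluster"); dir.create(cl_dir, showWarnings = FALSE)
  write_stage_tsv(tibble(sample_id = names(cons$labels), cluster = cons$labels),
                  cl_dir, "labels.tsv")
  cons_df <- bind_cols(tibble(sample_id = rownames(cons$consensus)),
                       as_tibble(cons$consensus))
  readr::write_tsv(cons_df, file.path(cl_dir, "consensus_matrix.tsv"),
                   progress = FALSE)
  stages <- c(stages, "cluster")

  # 4. centroids
  cents <- stage("centroids", build_centroids(
    beta_sel, cons, kw_fdr_threshold = config$kw_fdr_threshold,
    classify_threshold = config$classify_threshold
  ))
  ce_dir <- file.path(outdir, "centroids"); dir.create(ce_dir, showWarnings = FALSE)
  write_stage_tsv(bind_cols(tibble(probe_id = rownames(cents$medians)),
                            as_tibble(cents$medians)),
                  ce_dir, "centroids.tsv")
  write_stage_tsv(cents$kw, ce_dir, "kruskal_wallis.tsv")
  stages <- c(stages, "centroids")

  # 5. classify (the training cohort back through the centroids)
  assign <- stage("classify", classify_by_centroid(cohort$beta, cents))
  as_dir <- file.path(outdir, "classify"); dir.create(as_dir, showWarnings = FALSE)
  write_stage_tsv(assign, as_dir, "assignments.tsv")
  stages <- c(stages, "classify")

  # 6. score
  mscores <- stage("score", methylation_score(cohort$beta, sel))
  escores <- stage("score", expression_score(cohort$expression, sel$signature,
                                             center = TRUE))
  dich <- dichotomize_score(mscores)
  sc_dir <- file.path(outdir, "score"); dir.create(sc_dir, showWarnings = FALSE)
  write_stage_tsv(mscores, sc_dir, "methylation_scores.tsv")
  write_stage_tsv(escores, sc_dir, "expression_scores.tsv")
  write_stage_tsv(dich, sc_dir, "dichotomized_scores.tsv")
  stages <- c(stages, "score")

  # 7. pten
  pt_set <- pten_cpg_set(cohort$pten$annotation)
  hyper <- stage("pten", call_pten_hypermethylation(cohort$beta, pt_set))
  status <- stage("pten", integrate_pten_events(hyper, cohort$pten$mutation,
                                                cohort$pten$cna))
  pt_dir <- file.path(outdir, "pten"); dir.create(pt_dir, showWarnings = FALSE)
  write_stage_tsv(status, pt_dir, "pten_status.tsv")
  write_stage_tsv(pten_event_summary(status, cons), pt_dir, "pten_by_cluster.tsv")
  stages <- c(stages, "pten")

  # 8. stats
  st_dir <- file.path(outdir, "stats"); dir.create(st_dir, showWarnings = FALSE)
  db <- stage("stats", delta_beta_contrasts(mscores, cons))
  write_stage_tsv(db, st_dir, "delta_beta.tsv")
  clin <- cohort$clinical
  clin$cluster <- factor(cons$labels[clin$sample_id])
  assoc <- stage("stats", categorical_associations(
    clin, cons$labels[clin$sample_id],
    c("mitf_status", "til_category", "metastasis_type"), seed = config$seed
  ))
  write_stage_tsv(assoc, st_dir, "associations.tsv")
  cox_uni <- stage("stats", fit_survival(clin, "cluster", endpoint = "DSS"))
  cox_multi <- stage("stats", fit_survival(clin, "cluster",
                                           covariates = "metastasis_type",
                                           endpoint = "DSS"))
  write_stage_tsv(cox_uni, st_dir, "cox_univariate.tsv")
  write_stage_tsv(cox_multi, st_dir, "cox_multivariate.tsv")
  km <- stage("stats", km_logrank(clin, "cluster"))
  write_stage_tsv(km$risk_table, st_dir, "km_risk_table.tsv")
  screen <- stage("stats", survival_screen(clin, dich, endpoint = "OS"))
  write_stage_tsv(screen, st_dir, "survival_screen.tsv")
  stages <- c(stages, "stats")

  manifest <- list(
    package = "immunometh",
    version = as.character(packageVersion("immunometh")),
    r_version = as.character(getRversion()),
    rng_kind = RNGkind()[1],
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    mode = config$mode,
    k = config$k,
    consensus = list(iterations = config$consensus_iter,
                     subsample = config$consensus_subsample),
    kw_fdr_threshold = config$kw_fdr_threshold,
    classify_threshold = config$classify_threshold,
    selection = unclass(config$selection),
    simulation = unclass(config$simulation)[setdiff(names(config$simulation),
                                                    "cell_type_names")],
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(panel = panel, cohort = cohort, selection = sel,
                 consensus = cons, centroids = cents, assignments = assign,
                 methylation_scores = mscores, expression_scores = escores,
                 pten_status = status, delta_beta = db, associations = assoc,
                 cox_univariate = cox_uni, cox_multivariate = cox_multi,
                 km = km, survival_screen = screen))
}
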