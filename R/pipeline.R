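# rolling polynomial hash for run manifests (config fingerprinting only,
# not cryptographic)
config_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_seed <- function(global_seed, stage) {
  # deterministic per-stage seed below 2^31
  (as.numeric(global_seed) * 131 + sum(utf8ToInt(stage))) %% 2147483647
}

#' Run the full analysis pipeline
#'
#' Orchestrates score computation, SOC merging and triage, job-years
#' tabulation, the exposure and SOC model batteries, and the joint
#' profile clustering, writing every result table to `out_dir`:
#' \itemize{
#'   \item `score_summary.csv` -- per-type, per-status score summaries
#'   \item `score_correlations.csv` -- Spearman correlations between types
#'   \item `exposure_models.csv` -- univariate (with permutation p),
#'     multivariable and adaptive-elastic-net columns per exposure
#'   \item `soc_tabulation.csv` -- job-years/counts and enrichment tests
#'   \item `soc_models.csv` -- per-group logistic models with BH columns
#'     and lasso selection
#'   \item `metal_linear_models.csv` -- per-group linear slopes of the
#'     metals score on job-years
#'   \item `metals_by_soc.csv` -- metals score summary per group
#'   \item `metal_subcomponents.csv` -- subcomponent intersection counts
#'   \item `dendrogram_plain.nwk`, `dendrogram_duration.nwk`
#'   \item `manifest.json` -- seeds, config hash, package version, row
#'     counts
#' }
#' Every stochastic stage consumes a seed derived deterministically from
#' the global seed and the stage name. Any stage failure aborts with the
#' stage name in the message.
#'
#' @param participants,jobs,responses Cohort tables (paths or data frames).
#' @param candidates_a,candidates_b Coder candidate tables.
#' @param schema An `occx_schema` (default [default_schema()]).
#' @param aggregation_map data.frame (default: packaged map).
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param B Permutation count (default 10000).
#' @param soc_config See [default_soc_config()].
#' @return Invisible list with all in-memory results.
#' @export
run_all <- function(participants, jobs, responses, candidates_a,
                    candidates_b, schema = default_schema(),
                    aggregation_map = read_aggregation_map(),
                    out_dir, seed = 1L, B = 10000L,
                    soc_config = default_soc_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE, na = "")

  cohort <- stage("load", {
    co <- load_cohort(participants, jobs, responses, schema)
    impute_military(filter_eligible_jobs(co))
  })
  scores <- stage("score", compute_scores(cohort))
  stage("score_outputs", {
    w(summarize_scores(scores, cohort), "score_summary.csv")
    cm <- score_correlations(scores)
    w(data.frame(type = rownames(cm), cm, check.names = FALSE),
      "score_correlations.csv")
    sub <- metal_subcomponents(cohort)
    w(sub$intersections, "metal_subcomponents.csv")
  })

  exp_models <- stage("exposure_models",
    exposure_model_battery(cohort, scores, B = B,
                           seed = stage_seed(seed, "exposure_models")))
  stage("exposure_models_out", {
    uni <- exp_models$univariate
    multi <- exp_models$multivariable
    aen <- exp_models$aen
    tab <- data.frame(
      type = uni$term, n = uni$n,
      or_uni = uni$or, ci_low_uni = uni$ci_low, ci_high_uni = uni$ci_high,
      p_uni = uni$p, perm_p = uni$perm_p,
      or_multi = multi$or[match(uni$term, multi$term)],
      ci_low_multi = multi$ci_low[match(uni$term, multi$term)],
      ci_high_multi = multi$ci_high[match(uni$term, multi$term)],
      p_multi = multi$p[match(uni$term, multi$term)],
      or_aen = aen$or[match(uni$term, aen$term)],
      stringsAsFactors = FALSE)
    w(tab, "exposure_models.csv")
  })

  socres <- stage("soc", {
    merged <- merge_coders(candidates_a, candidates_b,
                           soc_config$agreement_digits)
    assignments <- build_assignments(cohort$jobs, merged, soc_config)
    jym <- job_years_matrix(cohort, assignments)
    w(tabulate_group(cohort, jym), "soc_tabulation.csv")
    models <- soc_model_battery(cohort, jym,
                                seed = stage_seed(seed, "soc_models"))
    tab <- models$per_group
    tab$lasso_selected <- models$lasso$selected[match(tab$major_group,
                                                     models$lasso$term)]
    tab$lasso_or <- models$lasso$or[match(tab$major_group,
                                          models$lasso$term)]
    w(tab, "soc_models.csv")
    list(merged = merged, assignments = assignments, jym = jym,
         models = models)
  })

  stage("metal_linear", {
    m <- score_matrix(scores)
    z <- standardize_scores(m[, "metals"])
    cov <- covariate_matrix(make_covariates(cohort), rownames(m))
    jym <- socres$jym[rownames(m), , drop = FALSE]
    rows <- do.call(rbind, lapply(colnames(jym), function(g)
      linear_score_on_socyears(z, jym[, g], cov, term = g)))
    w(rows, "metal_linear_models.csv")
  })

  stage("joint", {
    w(metals_by_soc(scores, socres$assignments), "metals_by_soc.csv")
    for (v in c("plain", "duration_adjusted")) {
      pm <- build_profile_matrix(scores, socres$assignments,
                                 aggregation_map, v)
      tree <- cluster_profiles(pm)
      export_newick(tree, file.path(out_dir,
        if (v == "plain") "dendrogram_plain.nwk"
        else "dendrogram_duration.nwk"))
    }
  })

  stage("manifest", {
    cfg_json <- jsonlite::toJSON(list(seed = seed, B = B,
                                      soc_config = soc_config),
                                 auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package_version = as.character(utils::packageVersion("occupex")),
      global_seed = seed, config_hash = config_hash(as.character(cfg_json)),
      n_participants = nrow(cohort$participants),
      n_jobs = nrow(cohort$jobs),
      stage_seeds = list(
        exposure_models = stage_seed(seed, "exposure_models"),
        soc_models = stage_seed(seed, "soc_models")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(cohort = cohort, scores = scores,
                 exposure_models = exp_models, soc = socres))
}
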