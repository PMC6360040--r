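# End-to-end orchestration: simulate or load a cohort, preprocess, score,
# associate, build forest data and run the multivariate stage, with
# provenance-stamped tabular outputs.

#' Assemble a pipeline configuration
#'
#' @param simulation A [simulation_config()] (used when `input` is `NULL`).
#' @param input Optional path to a cohort CSV/TSV, or a data frame; takes
#'   precedence over `simulation`.
#' @param stages Character vector of stages to run, in pipeline order; any
#'   subset of `c("preprocess", "scoring", "association", "risk", "multivariate")`.
#' @param outcome_score Score name grouping the downstream stages.
#' @param association_sets,forest_predictors,multivariate_sets Stage inputs;
#'   sensible defaults target the morphology/metabolic/oxidative panels.
#' @param alpha Gate and test level.
#' @param bootstrap_b Resampling iterations for associations.
#' @param seed Master seed; every stochastic stage derives its own from it.
#' @param out_dir Optional directory for provenance-stamped CSV artifacts.
#' @return List of class `ps_pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input = NULL,
                            stages = c("preprocess", "scoring",
                                       "association", "risk",
                                       "multivariate"),
                            outcome_score = "reactivity_aggregation",
                            association_sets = c("morphology", "metabolic",
                                                 "oxidative"),
                            forest_predictors = c("plt", "pct", "p_lcr",
                                                  "uric_acid"),
                            multivariate_sets = c("morphology", "metabolic"),
                            alpha = 0.05,
                            bootstrap_b = 2000L,
                            seed = 1L,
                            out_dir = NULL) {
  known <- c("preprocess", "scoring", "association", "risk", "multivariate")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    ps_abort(paste0("unknown stages: ", paste(bad, collapse = ", ")),
             "ps_bad_argument")
  }
  structure(list(simulation = simulation, input = input,
                 stages = intersect(known, stages),
                 outcome_score = outcome_score,
                 association_sets = association_sets,
                 forest_predictors = forest_predictors,
                 multivariate_sets = multivariate_sets,
                 alpha = alpha, bootstrap_b = as.integer(bootstrap_b),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "ps_pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Scalar fields of [pipeline_config()] may be overridden from file;
#' simulation settings under a `simulation` block (`n_subjects`,
#' `female_fraction`, `seed`, `missing_rate`).
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return A `ps_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim_args <- raw$simulation %||% list()
  sim <- do.call(simulation_config, sim_args)
  args <- raw[setdiff(names(raw), "simulation")]
  do.call(pipeline_config, c(list(simulation = sim), args))
}

write_artifact <- function(df, path, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# plateletscore %s",
            as.character(utils::packageVersion("plateletscore"))),
    sprintf("# seed: %d", seed),
    sprintf("# config: %s", config_hash)), con)
  for (v in names(df)[vapply(df, is.list, logical(1))]) {
    df[[v]] <- vapply(df[[v]], function(x)
      paste(format(unlist(x)), collapse = ";"), character(1))
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — preprocessing (outlier flags,
#' kNN imputation), scoring (cumulative normal scores and classes),
#' association (score-against-set rank correlations), risk models
#' (median-split forest with pooled OR, adjusted logistic model) and the
#' multivariate stage (discriminant ranking, canonical summary, classifier
#' panel with consensus) — on a simulated or supplied cohort.  All outputs
#' are returned in a named list; when `out_dir` is set, tabular artifacts
#' are also written as CSV with a provenance header (package version,
#' seed, config hash).  A rerun with the same config reproduces every
#' output.
#'
#' @param config A `ps_pipeline_config`.
#' @return Named list of stage artifacts, with the config hash under
#'   `$provenance`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "ps_pipeline_config")) {
    ps_abort("`config` must come from pipeline_config().", "ps_bad_argument")
  }
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  t0 <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[plateletscore] %-12s %+.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out <- list(provenance = list(config_hash = hash, seed = config$seed))

  cohort <- if (!is.null(config$input)) {
    if (is.character(config$input)) {
      sep <- if (grepl("\\.tsv$", config$input)) "\t" else ","
      tibble::as_tibble(utils::read.csv(config$input, sep = sep,
                                        comment.char = "#"))
    } else tibble::as_tibble(config$input)
  } else {
    generate_cohort(config$simulation)
  }
  needed <- unique(unlist(score_sets()[config$outcome_score]))
  absent <- setdiff(needed, names(cohort))
  if (length(absent)) {
    ps_abort(paste0("stage 'scoring' requires missing reactivity columns: ",
                    paste(absent, collapse = ", ")), "ps_missing_column")
  }
  out$cohort <- cohort
  log_stage("input")

  if ("preprocess" %in% config$stages) {
    pp <- preprocess_cohort(cohort)
    out$preprocess <- pp[c("outliers", "imputation")]
    cohort <- pp$data
    log_stage("preprocess")
  }

  scored <- if ("scoring" %in% config$stages) {
    sc <- add_reactivity_scores(cohort)
    out$scored <- sc
    log_stage("scoring")
    sc
  } else cohort

  if ("association" %in% config$stages) {
    out$associations <- associate_sets(
      scored, against = paste0("cum_", config$outcome_score),
      sets = config$association_sets, B = config$bootstrap_b,
      seed = derive_seed(config$seed, 11L))
    log_stage("association")
  }

  if ("risk" %in% config$stages) {
    cls <- paste0("class_", config$outcome_score)
    out$forest <- build_forest(scored, cls, config$forest_predictors)
    out$forest_by_sex <- if ("sex" %in% names(scored))
      build_forest(scored, cls, config$forest_predictors,
                   stratify_by_sex = TRUE) else NULL
    adj <- intersect(c("age", "sex"), names(scored))
    out$logistic <- fit_logistic(scored, cls, config$forest_predictors,
                                 adjust = adj)
    log_stage("risk")
  }

  if ("multivariate" %in% config$stages) {
    cls <- paste0("class_", config$outcome_score)
    vs <- variable_sets(scored)
    feats <- unlist(vs[config$multivariate_sets], use.names = FALSE)
    out$lda <- lda_rank(scored, scored[[cls]], features = feats)
    out$canonical <- canonical(
      scored[score_sets()[[config$outcome_score]]],
      scored[vs[[config$multivariate_sets[1]]]])
    panel_feats <- if (nrow(out$lda$ranking) >= 2)
      out$lda$ranking$term else feats[1:2]
    out$panel <- run_panel(scored, scored[[cls]], features = panel_feats,
                           seed = derive_seed(config$seed, 13L))
    out$consensus <- vote_judges(out$panel)
    log_stage("multivariate")
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df) && is.data.frame(df)) {
        write_artifact(df, file.path(config$out_dir,
                                     paste0(name, ".csv")),
                       hash, config$seed)
      }
    }
    wr(out$scored %||% out$cohort, "cohort_scored")
    wr(out$associations, "associations")
    wr(out$forest, "forest")
    if (!is.null(out$logistic)) wr(tidy(out$logistic), "logistic")
    if (!is.null(out$lda)) wr(tidy(out$lda), "lda_ranking")
    if (!is.null(out$canonical)) wr(tidy(out$canonical), "canonical")
    if (!is.null(out$panel)) wr(out$panel$accuracy, "panel_accuracy")
  }
  out
}
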