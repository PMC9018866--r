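# End-to-end orchestration: maze -> synthetic cohort -> model fitting and
# model selection -> behavioral report -> filter traces -> synthetic patterns
# -> decoding (plain, conditional, permutation) -> one report bundle.

#' Pipeline configuration
#'
#' A nested list validated by [validate_config()]; every stage derives its
#' own seed from the single global seed so stages can be re-run in isolation
#' with identical results. Defaults are desk-scale (a small cohort with
#' reduced undersampling/permutation counts).
#'
#' @param seed global seed.
#' @param maze_file optional path to a maze JSON (otherwise a maze is
#'   generated from the seed).
#' @param n_rows,n_cols maze dimensions when generating.
#' @param n_subjects cohort size.
#' @param params generative `model_params` shared by the cohort.
#' @param n_games,n_sessions task protocol scale.
#' @param fit a `fit_settings`.
#' @param patterns a `pattern_spec`.
#' @param decoding a `decoding_config` for the main scene analysis.
#' @param conditions conditional decoders to run.
#' @param n_sbj,n_group permutation-test scale.
#' @param out_dir output directory (`NULL` keeps the bundle in memory only).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, maze_file = NULL,
                            n_rows = 5L, n_cols = 5L,
                            n_subjects = 5L,
                            params = model_params(),
                            n_games = 12L, n_sessions = 4L,
                            fit = fit_settings(),
                            patterns = pattern_spec(),
                            decoding = decoding_config(
                              target = "scene", periods = 6L,
                              n_undersample_repeats = 5L),
                            conditions = c("conf_high", "conf_low"),
                            n_sbj = 10L, n_group = 50L,
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), maze_file = maze_file,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_subjects = as.integer(n_subjects), params = params,
                 n_games = as.integer(n_games),
                 n_sessions = as.integer(n_sessions),
                 fit = fit, patterns = patterns, decoding = decoding,
                 conditions = conditions, n_sbj = as.integer(n_sbj),
                 n_group = as.integer(n_group), out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema and invariant checks; returns diagnostics instead of raising, so a
#' configuration can be fully linted in one pass.
#'
#' @param config a `pipeline_config` (or plain list).
#' @return character vector of diagnostics (empty when valid).
#' @export
validate_config <- function(config) {
  d <- character(0)
  say <- function(...) d <<- c(d, sprintf(...))
  if (is.null(config$seed) || !is.finite(config$seed))
    say("seed: missing or non-finite")
  if (!is.null(config$maze_file) && !file.exists(config$maze_file))
    say("maze_file: path '%s' not resolvable", config$maze_file)
  if (!is.null(config$n_rows) && !is.null(config$n_cols) &&
      config$n_rows * config$n_cols > 30L)
    say("maze: more than 30 cells is unsupported by the filter")
  if (isTRUE(config$n_subjects < 1L)) say("n_subjects: must be >= 1")
  if (!is.null(config$params) && !inherits(config$params, "model_params"))
    say("params: not a model_params object")
  ps <- config$patterns
  if (!is.null(ps)) {
    if (ps$sigma_low_conf < ps$sigma_high_conf)
      say("patterns: sigma_low_conf < sigma_high_conf violates the PatternSpec invariant")
    if (length(ps$envelope) != 9L) say("patterns: envelope must have 9 entries")
  }
  dc <- config$decoding
  if (!is.null(dc) && !all(dc$periods %in% 0:8))
    say("decoding: periods must lie in 0..8")
  d
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort on a (loaded or generated) maze, fits and compares the
#' model variants per subject, computes the behavioral report, filters every
#' log for model state confidence, generates synthetic patterns, and runs the
#' main, conditional and permutation decoding analyses. The returned bundle
#' is fully reproducible from the configuration and its single seed; when
#' `out_dir` is set, every table is also written as CSV/JSON.
#'
#' @param config a `pipeline_config`.
#' @param fit_variants model variants to compare (set to `NULL` to skip the
#'   fitting stage).
#' @return list bundle with one element per stage; on a stage failure the
#'   bundle is returned with `partial = TRUE` and the stage error recorded.
#' @export
run_end_to_end <- function(config = pipeline_config(),
                           fit_variants = c("switching", "forward_only",
                                            "efficient_only")) {
  diags <- validate_config(config)
  if (length(diags)) stop("invalid config:\n  ", paste(diags, collapse = "\n  "))
  bundle <- list(config = config, partial = FALSE, errors = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      bundle$partial <<- TRUE
      bundle$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    bundle[[name]] <<- res
    res
  }

  m <- stage("maze", {
    if (!is.null(config$maze_file)) read_maze(config$maze_file)
    else generate_maze(config$n_rows, config$n_cols,
                       seed = derive_seed(config$seed, "maze"))
  })
  logs <- stage("cohort", {
    specs <- lapply(seq_len(config$n_subjects), function(i)
      agent_spec(params = config$params,
                 rng_seed = derive_seed(config$seed, paste0("subject", i))))
    simulate_cohort(m, specs, game_config(
      n_games = config$n_games, n_sessions = config$n_sessions,
      rng_seed = derive_seed(config$seed, "task")))
  })
  if (is.null(logs)) return(bundle)

  stage("exclusion", exclude_subjects(logs))

  if (!is.null(fit_variants)) stage("model_selection", {
    tabs <- lapply(logs, function(log)
      compare_models(log, m, fit_variants, config$fit))
    do.call(rbind, Map(function(tb, id) cbind(subject_id = id, tb),
                       tabs, names(logs)))
  })

  traces <- stage("traces", lapply(logs, function(log)
    filter_log(log, m, config$params)))

  stage("behavior", list(
    accuracy_by_confidence = accuracy_by_confidence(logs),
    trend_accuracy = trend_vs_trial_index(logs, "accuracy"),
    trend_confidence = trend_vs_trial_index(logs, "confidence"),
    trend_state_conf = trend_vs_trial_index(logs, "high_state_conf_fraction",
                                            traces = traces),
    streaks = streak_analysis(logs),
    rt = rt_zscore_and_summarize(logs),
    agreement = vapply(seq_along(logs), function(i)
      confidence_agreement(logs[[i]], traces[[i]]), numeric(1))))

  datasets <- stage("patterns", lapply(seq_along(logs), function(i) {
    ps <- config$patterns
    ps$rng_seed <- derive_seed(config$seed, paste0("patterns", i))
    generate_patterns(logs[[i]], ps)
  }))
  if (is.null(datasets)) return(bundle)
  datasets6 <- lapply(datasets, function(ds) exclude_rare_label(ds)$dataset)

  stage("decoding", {
    main <- lapply(datasets6, cross_validate, config = config$decoding)
    conds <- lapply(config$conditions, function(cond)
      lapply(datasets6, conditional_decode, condition = cond,
             config = config$decoding))
    names(conds) <- config$conditions
    comparisons <- NULL
    if (all(c("conf_high", "conf_low") %in% config$conditions))
      comparisons <- lapply(config$decoding$periods, function(t)
        c(period = t, compare_conditions(conds$conf_high, conds$conf_low, t)))
    list(main = main, conditional = conds, comparisons = comparisons)
  })

  stage("permutation", permutation_test_two_step(
    datasets6, config$decoding, n_sbj = config$n_sbj,
    n_group = config$n_group,
    rng_seed = derive_seed(config$seed, "permutation")))

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' `params`, `fit`, `patterns` and `decoding` blocks mirror the arguments of
#' their constructors. Missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, ctor) {
    if (is.null(y[[block]])) return(ctor())
    do.call(ctor, y[[block]])
  }
  args <- y[setdiff(names(y), c("params", "fit", "patterns", "decoding"))]
  args$params <- take("params", model_params)
  args$fit <- take("fit", fit_settings)
  args$patterns <- take("patterns", pattern_spec)
  args$decoding <- take("decoding", decoding_config)
  cfg <- do.call(pipeline_config, args)
  diags <- validate_config(cfg)
  if (length(diags)) stop("invalid config ", path, ":\n  ",
                          paste(diags, collapse = "\n  "))
  cfg
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  w(bundle$exclusion, "exclusion")
  w(bundle$model_selection, "model_selection")
  if (!is.null(bundle$behavior)) {
    w(bundle$behavior$accuracy_by_confidence$per_subject, "accuracy_by_confidence")
    w(bundle$behavior$rt$medians, "rt_medians")
    summary <- list(
      p_acc_by_conf = bundle$behavior$accuracy_by_confidence$p,
      trend_accuracy = bundle$behavior$trend_accuracy[c("r", "p")],
      trend_confidence = bundle$behavior$trend_confidence[c("r", "p")],
      trend_state_conf = bundle$behavior$trend_state_conf[c("r", "p")],
      streak_r_correct = bundle$behavior$streaks$r_correct,
      rt_p_conf = bundle$behavior$rt$p_conf,
      rt_p_correct = bundle$behavior$rt$p_correct,
      agreement_pct = bundle$behavior$agreement)
    jsonlite::write_json(summary, file.path(out_dir, "behavior_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$decoding)) {
    acc <- do.call(rbind, lapply(bundle$decoding$main, function(r)
      if (!r$excluded) cbind(subject_id = r$subject_id, r$period_accuracy)))
    w(acc, "decoding_main")
  }
  if (!is.null(bundle$permutation))
    jsonlite::write_json(list(p = bundle$permutation$p,
                              original = bundle$permutation$original),
                         file.path(out_dir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
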