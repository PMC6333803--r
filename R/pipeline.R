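#' Configure a full pipeline run
#'
#' Bundles every stage's settings and seeds. Validation happens here, before
#' any stage runs: every stochastic stage must have an explicit integer seed.
#'
#' @param generator A [generator_config()].
#' @param n_spaces Arbitrage feature spaces (default 320).
#' @param n_trees Trees per arbitrage model (default 80).
#' @param n_sets Feature sets to select (default 3).
#' @param split A [split_spec()].
#' @param arch An [arch_config()].
#' @param epsilon Epsilon-accuracy half-width in years (default 10).
#' @param bins Age bins as from [default_age_bins()].
#' @param seeds Named list of integer seeds for the stochastic stages:
#'   `spaces`, `arbitrage`, `split`, `age`, `smoking`, `importance`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(generator, n_spaces = 320, n_trees = 80,
                            n_sets = 3, split = split_spec(),
                            arch = arch_config(), epsilon = 10,
                            bins = default_age_bins(),
                            seeds = list(spaces = 11L, arbitrage = 12L,
                                         split = 13L, age = 14L,
                                         smoking = 15L, importance = 16L)) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(split, "split_spec"), inherits(arch, "arch_config"))
  needed <- c("spaces", "arbitrage", "split", "age", "smoking", "importance")
  missing_seeds <- setdiff(needed, names(seeds))
  ok <- vapply(seeds[intersect(needed, names(seeds))],
               function(s) is.numeric(s) && length(s) == 1L && !is.na(s),
               logical(1))
  if (length(missing_seeds) || !all(ok))
    stop("pipeline_config: every stochastic stage needs an explicit integer ",
         "seed; missing or invalid: ",
         paste(c(missing_seeds, names(ok)[!ok]), collapse = ", "),
         call. = FALSE)
  structure(list(generator = generator, n_spaces = n_spaces,
                 n_trees = n_trees, n_sets = n_sets, split = split,
                 arch = arch, epsilon = epsilon, bins = bins,
                 seeds = lapply(seeds, as.integer)),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> arbitrage feature selection -> reconstruction ->
#' age clock on nonsmokers -> predictions and aging-ratio analysis ->
#' age clock with smoking feature -> smoking classifier -> permutation
#' importance and partial dependence, writing every intermediate artifact,
#' a JSON manifest (seeds, settings, file hashes) and a human-readable
#' report into `out_dir`. Reruns with the same config reproduce the tabular
#' outputs bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return `out_dir`, invisibly; artifacts are listed in
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("stage simulate: n = %d", config$generator$n_subjects)
  cohort <- stage("simulate", generate_cohort(config$generator))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  say("stage select-features: %d spaces, %d trees",
      config$n_spaces, config$n_trees)
  records <- stage("select-features", {
    spaces <- enumerate_feature_spaces(cohort, n_spaces = config$n_spaces,
                                       seed = config$seeds$spaces)
    withCallingHandlers(
      fit_arbitrage_ensemble(cohort, spaces, n_trees = config$n_trees,
                             seed = config$seeds$arbitrage),
      warning = function(w) {
        say("  %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  say("  fitted %d arbitrage models (%d skipped)", length(records),
      length(attr(records, "skipped")))
  scores <- stage("select-features", arbitrage_fi(records))
  write_tsv(scores, file.path(out_dir, "feature_rank.tsv"))
  sets <- stage("select-features",
                select_feature_sets(scores, cohort, n_sets = config$n_sets))
  jsonlite::write_json(
    lapply(sets, function(s) list(markers = s$markers,
                                  eligible_n = s$eligible_n)),
    file.path(out_dir, "feature_sets.json"), auto_unbox = TRUE, pretty = TRUE)

  largest <- sets[[length(sets)]]
  say("stage reconstruct: %d markers in the largest set",
      length(largest$markers))
  recon <- stage("reconstruct", reconstruct_feature_set(cohort, largest))
  write_cohort(recon, file.path(out_dir, "cohort_reconstructed.csv"))
  models <- attr(recon, "models")
  jsonlite::write_json(
    list(unfilled = as.list(attr(recon, "unfilled")),
         fits = lapply(models, function(m)
           list(target = m$target, fit_n = m$fit_n,
                fit_fraction = m$fit_fraction))),
    file.path(out_dir, "reconstruction.json"), auto_unbox = TRUE,
    pretty = TRUE)
  usable <- largest$markers[vapply(largest$markers,
                                   function(m) !anyNA(recon[[m]]),
                                   logical(1))]
  features <- c(usable, "sex")

  say("stage train-age (nonsmokers): %d features", length(features))
  nonsmokers <- recon[recon$smoking == 0, , drop = FALSE]
  spl <- split_spec(train_fraction = config$split$train_fraction,
                    cv_folds = config$split$cv_folds,
                    seed = config$seeds$split,
                    train_population = "nonsmokers_only")
  parts <- stage("train-age", split_train_test(nonsmokers, spl))
  clock_spec <- spl; clock_spec$seed <- config$seeds$age
  clock <- stage("train-age",
                 train_age_model(parts$train, features, clock_spec,
                                 config$arch))
  heldout <- rbind(parts$test, recon[recon$smoking == 1, , drop = FALSE])
  pred <- stage("predict", predict_age(clock, heldout))
  rep_ns <- regression_metrics(pred[pred$smoking == 0, ], config$epsilon)
  say("  held-out nonsmokers: MAE %.2f y, R^2 %.3f", rep_ns$mae,
      rep_ns$r_squared)

  say("stage aging-ratio")
  ratio_tab <- stage("aging-ratio", group_aging_summary(pred, config$bins))
  say("  %d samples excluded for nonpositive predicted age",
      attr(ratio_tab, "n_excluded"))
  write_tsv(ratio_tab, file.path(out_dir, "aging_ratio.tsv"))
  risk_path <- NULL
  risk_cols <- c("total_cholesterol", "hdl", "fasting_glucose")
  if (all(risk_cols %in% names(heldout)) &&
      !anyNA(heldout[, risk_cols])) {
    risk <- stage("aging-ratio", assign_risk_groups(heldout[, risk_cols]))
    risk_tab <- stage("aging-ratio",
                      risk_group_aging_summary(pred, risk, config$bins))
    risk_path <- write_tsv(risk_tab, file.path(out_dir, "risk_ratio.tsv"))
  }

  say("stage train-age (with smoking feature)")
  spl_all <- split_spec(train_fraction = config$split$train_fraction,
                        cv_folds = config$split$cv_folds,
                        seed = config$seeds$split,
                        train_population = "all_with_smoking_feature")
  parts_all <- stage("train-age", split_train_test(recon, spl_all))
  clock_all_spec <- spl_all; clock_all_spec$seed <- config$seeds$age
  clock_all <- stage("train-age",
                     train_age_model(parts_all$train,
                                     c(features, "smoking"),
                                     clock_all_spec, config$arch))
  pred_all <- stage("predict", predict_age(clock_all, parts_all$test))
  rep_all <- regression_metrics(pred_all, config$epsilon)
  say("  held-out: MAE %.2f y, R^2 %.3f", rep_all$mae, rep_all$r_squared)

  say("stage train-smoking")
  clf_spec <- spl_all; clf_spec$seed <- config$seeds$smoking
  clf <- stage("train-smoking",
               train_smoking_model(parts_all$train, features, clf_spec,
                                   config$arch))
  clf_pred <- predict(clf, parts_all$test, type = "class")
  clf_rep <- classification_metrics(parts_all$test$smoking, clf_pred)
  say("  held-out: accuracy %.3f, F1 %s", clf_rep$accuracy,
      format(clf_rep$f1, digits = 3))
  conf <- confusion_by_age_group(parts_all$test$smoking, clf_pred,
                                 parts_all$test$age, config$bins)
  write_tsv(conf, file.path(out_dir, "confusion_by_age.tsv"))

  say("stage importance")
  pfi <- stage("importance",
               permutation_importance(clock_all, parts_all$test,
                                      metric = "mae",
                                      seed = config$seeds$importance))
  write_tsv(as.data.frame(pfi), file.path(out_dir, "importance.tsv"))
  pd <- stage("importance",
              partial_dependence(clock_all, "smoking",
                                 background = parts_all$test))
  write_tsv(as.data.frame(pd), file.path(out_dir, "pd_smoking.tsv"))

  metrics <- list(
    age_clock_nonsmokers = unclass(rep_ns),
    age_clock_with_smoking = unclass(rep_all),
    smoking_classifier = unclass(clf_rep),
    n_arbitrage_models = length(records),
    n_arbitrage_skipped = length(attr(records, "skipped")),
    feature_set_sizes = vapply(sets, function(s) length(s$markers),
                               integer(1)),
    reconstruction_unfilled = as.list(attr(recon, "unfilled")))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  files <- c("cohort.csv", "feature_rank.tsv", "feature_sets.json",
             "cohort_reconstructed.csv", "reconstruction.json",
             "aging_ratio.tsv", if (!is.null(risk_path)) "risk_ratio.tsv",
             "confusion_by_age.tsv", "importance.tsv", "pd_smoking.tsv",
             "metrics.json")
  manifest <- list(
    package = "bloodclock",
    version = as.character(utils::packageVersion("bloodclock")),
    settings = list(n_subjects = config$generator$n_subjects,
                    n_spaces = config$n_spaces, n_trees = config$n_trees,
                    train_fraction = config$split$train_fraction,
                    cv_folds = config$split$cv_folds,
                    epsilon = config$epsilon,
                    estimator = config$arch$estimator),
    seeds = config$seeds,
    hashes = as.list(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(c("# Pipeline run report", "", log_lines),
             file.path(out_dir, "report.md"))
  invisible(out_dir)
}
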