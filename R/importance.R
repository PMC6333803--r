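model_features <- function(model) {
  if (!inherits(model, c("age_clock", "smoking_clf")))
    stop("expected an age_clock or smoking_clf model", call. = FALSE)
  model$features
}

model_predictions <- function(model, data) {
  if (inherits(model, "age_clock")) predict_age(model, data)$y_hat
  else predict(model, data, type = "prob")
}

score_model <- function(model, data, metric) {
  pred <- model_predictions(model, data)
  switch(metric,
         mae = mean(abs(pred - data$age)),
         f1 = classification_metrics(data$smoking,
                                     as.integer(pred > model$threshold))$f1,
         accuracy = classification_metrics(
           data$smoking, as.integer(pred > model$threshold))$accuracy)
}

#' Permutation feature importance
#'
#' For each input feature, the model's performance metric is recomputed after
#' permuting that feature's column (seeded), `n_repeats` times. The drop is
#' signed so that larger means more important: `permuted - baseline` for MAE,
#' `baseline - permuted` for F1 and accuracy. Other columns are never
#' touched.
#'
#' @param model An `age_clock` or `smoking_clf`.
#' @param data Evaluation set, complete on the model features (>= 2 rows)
#'   with the target column (`age` or `smoking`).
#' @param metric `"mae"` (regression), `"f1"` or `"accuracy"`
#'   (classification).
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed.
#' @return A `pfi_result` data frame with per-feature `mean_drop`, `sd_drop`
#'   and `rank` (1 = most important); the unpermuted baseline metric is
#'   attached as attribute `"baseline"`.
#' @export
permutation_importance <- function(model, data,
                                   metric = c("mae", "f1", "accuracy"),
                                   n_repeats = 10, seed = 1L) {
  metric <- match.arg(metric)
  if (nrow(data) < 2)
    stop("permutation_importance: need >= 2 rows (permutation is ",
         "meaningless on a single row)", call. = FALSE)
  feats <- model_features(model)
  check_complete(data, feats, "permutation_importance")
  baseline <- score_model(model, data, metric)
  higher_better <- metric %in% c("f1", "accuracy")
  set.seed(seed)
  drops <- vapply(feats, function(f) {
    vapply(seq_len(n_repeats), function(r) {
      perm <- data
      perm[[f]] <- perm[[f]][sample.int(nrow(perm))]
      s <- score_model(model, perm, metric)
      if (higher_better) baseline - s else s - baseline
    }, numeric(1))
  }, numeric(n_repeats))
  drops <- matrix(drops, nrow = n_repeats)
  mean_drop <- colMeans(drops)
  out <- data.frame(feature = feats, mean_drop = mean_drop,
                    sd_drop = apply(drops, 2, stats::sd),
                    stringsAsFactors = FALSE)
  out$rank <- as.integer(rank(-out$mean_drop, ties.method = "first"))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "metric") <- metric
  class(out) <- c("pfi_result", "data.frame")
  out
}

#' Partial dependence of a fitted model on one feature
#'
#' For each grid value `v`, the mean model prediction over the background
#' rows with the feature forced to `v` (predicted age for an age clock,
#' smoking probability for the classifier). Binary features are evaluated at
#' exactly `{0, 1}`.
#'
#' @param model An `age_clock` or `smoking_clf`.
#' @param feature Feature name.
#' @param grid Grid values; defaults to `{0, 1}` for binary features and a
#'   20-point quantile grid otherwise. Must stay within the observed range.
#' @param background Background cohort rows, complete on the model features.
#' @return A `partial_dependence` data frame with columns `grid` (sorted)
#'   and `mean_prediction`.
#' @export
partial_dependence <- function(model, feature, grid = NULL, background) {
  if (!nrow(background))
    stop("partial_dependence: empty background", call. = FALSE)
  feats <- model_features(model)
  if (!feature %in% feats)
    stop("partial_dependence: '", feature, "' is not a model feature",
         call. = FALSE)
  check_complete(background, feats, "partial_dependence")
  obs <- background[[feature]]
  binary <- all(obs %in% c(0, 1))
  if (is.null(grid)) {
    grid <- if (binary) c(0, 1)
            else unique(stats::quantile(obs, probs = seq(0, 1, length.out = 20),
                                        names = FALSE))
  } else if (!binary && (min(grid) < min(obs) || max(grid) > max(obs))) {
    stop("partial_dependence: grid outside the observed feature range",
         call. = FALSE)
  }
  grid <- sort(unique(grid))
  mp <- vapply(grid, function(v) {
    forced <- background
    forced[[feature]] <- v
    mean(model_predictions(model, forced))
  }, numeric(1))
  out <- data.frame(grid = grid, mean_prediction = mp)
  attr(out, "feature") <- feature
  class(out) <- c("partial_dependence", "data.frame")
  out
}
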