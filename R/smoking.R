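#' Train a smoking-status classifier
#'
#' Fits a probabilistic classifier of smoking status on blood markers and sex
#' (binary cross-entropy loss for the MLP; probability forest otherwise). The
#' smoking column itself is refused among the input features (label-leakage
#' guard). Smoker is the positive class; the default decision threshold is
#' 0.5. Deterministic given the spec seed.
#'
#' @param train Training cohort, complete on the features.
#' @param features A [feature_space()] or character vector of feature columns
#'   (markers, optionally `"sex"`; never `"smoking"`).
#' @param spec A [split_spec()].
#' @param arch An [arch_config()].
#' @param threshold Decision threshold on the smoking probability
#'   (default 0.5).
#' @return A `smoking_clf` model object.
#' @export
train_smoking_model <- function(train, features, spec = split_spec(),
                                arch = arch_config(), threshold = 0.5) {
  cols <- feature_columns(features)
  if ("smoking" %in% cols)
    stop("train_smoking_model: smoking status among the input features ",
         "would leak the label", call. = FALSE)
  check_complete(train, cols, "train_smoking_model")
  scaler <- make_scaler(train, cols)
  x <- apply_scaler(scaler, train)
  y <- as.numeric(train$smoking)
  fit <- fit_estimator(x, y, "classification", arch, spec$cv_folds,
                       spec$seed)
  structure(list(fit = fit, features = cols, scaler = scaler,
                 threshold = threshold, spec = spec, arch = arch,
                 loss = "binary_cross_entropy"),
            class = "smoking_clf")
}

#' Predict smoking probabilities and labels
#'
#' @param object A `smoking_clf`.
#' @param newdata Cohort complete on the model's features.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels at the
#'   model threshold.
#' @param ... Unused.
#' @return Numeric probabilities or integer labels.
#' @export
predict.smoking_clf <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  check_complete(newdata, object$features, "predict.smoking_clf")
  x <- apply_scaler(object$scaler, newdata)
  p <- predict_estimator(object$fit, x)
  if (object$fit$kind == "linear" && is.null(object$fit$task))
    p <- sigmoid(p)
  if (type == "prob") p else as.integer(p > object$threshold)
}

#' Classification metrics for the smoking classifier
#'
#' Confusion counts with smoker (1) as the positive class, and the standard
#' derived metrics: accuracy `(tp + tn) / n`, precision `tp / (tp + fp)`,
#' recall `tp / (tp + fn)`, and F1 (the harmonic mean of precision and
#' recall). Metrics with a zero denominator are reported as `NA`.
#'
#' @param truth True 0/1 smoking labels.
#' @param predicted Predicted 0/1 labels.
#' @return A `classification_report` list with counts `tp`, `fp`, `fn`,
#'   `tn` and metrics `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(truth, predicted) {
  if (!length(truth)) stop("classification_metrics: empty input",
                           call. = FALSE)
  if (length(truth) != length(predicted))
    stop("classification_metrics: length mismatch", call. = FALSE)
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("classification_metrics: labels must be binary 0/1", call. = FALSE)
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  tn <- sum(truth == 0 & predicted == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / length(truth),
                 precision = precision, recall = recall, f1 = f1,
                 n = length(truth)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Smoking-status report (n = %d)\n", x$n))
  cat(sprintf("  counts    : tp %d  fp %d  fn %d  tn %d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  accuracy  : %.3f\n", x$accuracy))
  cat(sprintf("  precision : %s  recall : %s  F1 : %s\n",
              format(x$precision, digits = 3), format(x$recall, digits = 3),
              format(x$f1, digits = 3)))
  invisible(x)
}

#' Default age bins for stratified reporting
#'
#' Integer-age bins `<31, 31-40, 41-50, 51-60, 61-70, >70`.
#'
#' @return A list with `breaks` (for [cut()], right-closed) and `labels`.
#' @export
default_age_bins <- function() {
  list(breaks = c(-Inf, 30, 40, 50, 60, 70, Inf),
       labels = c("<31", "31-40", "41-50", "51-60", "61-70", ">70"))
}

age_bin <- function(age, bins = default_age_bins()) {
  cut(age, breaks = bins$breaks, labels = bins$labels, right = TRUE)
}

#' Age-stratified confusion matrices
#'
#' Per age-bin 2x2 confusion counts for the smoking classifier, with
#' row-normalized percentages (within true class) and the per-bin error
#' rate. Empty bins are reported with zero counts, not dropped.
#'
#' @param truth True 0/1 smoking labels.
#' @param predicted Predicted 0/1 labels.
#' @param age Ages (years), same length.
#' @param bins Age bins as from [default_age_bins()].
#' @return A data frame with one row per bin: counts `tp`, `fp`, `fn`, `tn`,
#'   `n`, `error_rate`, and percentage columns `pct_*` normalized within the
#'   true class.
#' @export
confusion_by_age_group <- function(truth, predicted, age,
                                   bins = default_age_bins()) {
  if (anyNA(age)) stop("confusion_by_age_group: ages must be present",
                       call. = FALSE)
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(age))
  bin <- age_bin(age, bins)
  out <- do.call(rbind, lapply(bins$labels, function(lb) {
    idx <- which(bin == lb)
    tp <- sum(truth[idx] == 1 & predicted[idx] == 1)
    fp <- sum(truth[idx] == 0 & predicted[idx] == 1)
    fn <- sum(truth[idx] == 1 & predicted[idx] == 0)
    tn <- sum(truth[idx] == 0 & predicted[idx] == 0)
    n <- length(idx)
    n_smoker <- tp + fn; n_nonsmoker <- tn + fp
    data.frame(age_group = lb, tp = tp, fp = fp, fn = fn, tn = tn, n = n,
               error_rate = if (n > 0) (fp + fn) / n else NA_real_,
               pct_tp = if (n_smoker > 0) 100 * tp / n_smoker else NA_real_,
               pct_fn = if (n_smoker > 0) 100 * fn / n_smoker else NA_real_,
               pct_tn = if (n_nonsmoker > 0) 100 * tn / n_nonsmoker else NA_real_,
               pct_fp = if (n_nonsmoker > 0) 100 * fp / n_nonsmoker else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
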