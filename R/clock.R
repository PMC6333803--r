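#' Train/test split specification
#'
#' @param train_fraction Fraction of subjects in the training set, in (0, 1);
#'   default 0.80 (the study's 80/20 design).
#' @param cv_folds Cross-validation folds for model selection (default 5).
#' @param seed Integer seed.
#' @param train_population `"nonsmokers_only"` (the clock is fitted on
#'   nonsmokers and applied to everyone) or `"all_with_smoking_feature"`
#'   (smokers included and smoking status allowed as an input feature).
#' @return A validated `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.80, cv_folds = 5, seed = 1L,
                       train_population = c("nonsmokers_only",
                                            "all_with_smoking_feature")) {
  train_population <- match.arg(train_population)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("split_spec: train_fraction must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(cv_folds) || cv_folds < 2)
    stop("split_spec: cv_folds must be >= 2", call. = FALSE)
  structure(list(train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 train_population = train_population),
            class = "split_spec")
}

#' Split a cohort into train and test sets
#'
#' Disjoint, exhaustive, stratified by 10-year age group; the train size is
#' exactly `round(train_fraction * n)` (largest-remainder apportionment over
#' strata) and membership is reproducible from the seed.
#'
#' @param cohort Cohort data frame (n >= 10).
#' @param spec A [split_spec()].
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(cohort, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(cohort)
  if (n < 10) stop("split_train_test: need n >= 10", call. = FALSE)
  set.seed(spec$seed)
  decade <- cohort$age %/% 10L
  strata <- split(seq_len(n), decade)
  sizes <- lengths(strata)
  quota <- apportion(round(spec$train_fraction * n), sizes, cap = sizes)
  train_idx <- unlist(lapply(seq_along(strata), function(k)
    sample(strata[[k]], quota[k])), use.names = FALSE)
  list(train = cohort[sort(train_idx), , drop = FALSE],
       test = cohort[sort(setdiff(seq_len(n), train_idx)), , drop = FALSE])
}

#' Center and scale markers by training-set statistics
#'
#' Normalization parameters (mean, SD) are fitted only on `train` and applied
#' to `apply_to`, so no information leaks from held-out data.
#'
#' @param train Cohort providing the normalization statistics (complete on
#'   `features`).
#' @param apply_to Cohort to transform.
#' @param features Marker columns to scale; defaults to the shared marker
#'   columns.
#' @return `apply_to` with scaled feature columns; the per-marker means and
#'   SDs are attached as attribute `"scaler"`.
#' @export
normalize_markers <- function(train, apply_to,
                              features = intersect(marker_names(train),
                                                   marker_names(apply_to))) {
  means <- vapply(features, function(f) mean(train[[f]]), numeric(1))
  sds <- vapply(features, function(f) stats::sd(train[[f]]), numeric(1))
  if (anyNA(means) || anyNA(sds))
    stop("normalize_markers: train is not complete on the feature set",
         call. = FALSE)
  zero <- features[sds == 0]
  if (length(zero))
    stop("normalize_markers: zero-SD marker(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  out <- apply_to
  for (f in features) out[[f]] <- (out[[f]] - means[f]) / sds[f]
  attr(out, "scaler") <- list(means = means, sds = sds)
  out
}

#' Estimator configuration for the age and smoking models
#'
#' @param estimator `"mlp"` (default: two hidden ReLU layers with dropout,
#'   width chosen by cross-validation, minibatch Adam, MAE /
#'   binary-cross-entropy loss, early stopping), `"forest"` (bagged
#'   regression trees) or `"linear"`.
#' @param hidden_widths Candidate hidden-layer widths for the MLP grid.
#' @param dropout Dropout probability after each hidden layer. Default 0.05:
#'   at desk scale heavy dropout (e.g. the 35% used for study-scale networks)
#'   measurably compresses predictions toward the cohort mean and biases the
#'   age tails; early stopping supplies the regularization instead.
#' @param epochs,learning_rate,patience,batch_size MLP optimizer controls
#'   (minibatch Adam with early stopping on a validation slice).
#' @param n_ensemble Number of seed-varied networks averaged in the final
#'   MLP fit (default 3; averaging stabilizes the age tails).
#' @param n_trees,max_depth Forest controls.
#' @return An `arch_config` list.
#' @export
arch_config <- function(estimator = c("mlp", "forest", "linear"),
                        hidden_widths = c(16, 32, 64), dropout = 0.05,
                        epochs = 400, learning_rate = 0.01, patience = 40,
                        batch_size = 256, n_ensemble = 3,
                        n_trees = 200, max_depth = 14) {
  estimator <- match.arg(estimator)
  structure(list(estimator = estimator, hidden_widths = hidden_widths,
                 dropout = dropout, epochs = epochs,
                 learning_rate = learning_rate, patience = patience,
                 batch_size = batch_size, n_ensemble = n_ensemble,
                 n_trees = n_trees, max_depth = max_depth),
            class = "arch_config")
}

feature_columns <- function(features) {
  if (inherits(features, "feature_space")) features$markers
  else as.character(features)
}

check_complete <- function(cohort, cols, where) {
  absent <- setdiff(cols, names(cohort))
  if (length(absent))
    stop(where, ": missing feature column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  bad <- cols[vapply(cols, function(c) anyNA(cohort[[c]]), logical(1))]
  if (length(bad))
    stop(where, ": incomplete feature column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

make_scaler <- function(train, cols) {
  cont <- setdiff(cols, c("sex", "smoking"))
  means <- vapply(cont, function(f) mean(train[[f]]), numeric(1))
  sds <- vapply(cont, function(f) stats::sd(train[[f]]), numeric(1))
  zero <- cont[sds == 0]
  if (length(zero))
    stop("zero-SD feature(s) in the training set: ",
         paste(zero, collapse = ", "), call. = FALSE)
  list(cols = cols, cont = cont, means = means, sds = sds)
}

apply_scaler <- function(scaler, cohort) {
  x <- cohort[, scaler$cols, drop = FALSE]
  for (f in scaler$cont) x[[f]] <- (x[[f]] - scaler$means[f]) / scaler$sds[f]
  as.matrix(x)
}

# Shared estimator fit with CV width selection for the MLP.
fit_estimator <- function(x, y, task, arch, cv_folds, seed) {
  if (arch$estimator == "linear") {
    xm <- cbind(1, x)
    fit <- if (task == "regression") stats::lm.fit(xm, y)
           else stats::glm.fit(xm, y, family = stats::binomial())
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0
    return(list(kind = "linear", coef = coef, task = task))
  }
  if (arch$estimator == "forest") {
    f <- fit_forest(x, y, n_trees = arch$n_trees, max_depth = arch$max_depth,
                    seed = seed)
    return(list(kind = "forest", forest = f))
  }
  widths <- arch$hidden_widths
  fit_one <- function(xx, yy, w, s)
    mlp_fit(xx, yy, task = task, hidden = c(w, w), dropout = arch$dropout,
            epochs = arch$epochs, lr = arch$learning_rate,
            patience = arch$patience, batch_size = arch$batch_size, seed = s)
  cv_table <- NULL
  best_width <- widths[1]
  if (length(widths) > 1) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(cv_folds), length(y)))
    cv_loss <- vapply(widths, function(w) {
      mean(vapply(seq_len(cv_folds), function(k) {
        tr <- fold != k
        m <- fit_one(x[tr, , drop = FALSE], y[tr], w, seed + k)
        pred <- predict_mlp(m, x[!tr, , drop = FALSE])
        if (task == "regression") mean(abs(pred - y[!tr]))
        else {
          p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
          -mean(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
        }
      }, numeric(1)))
    }, numeric(1))
    cv_table <- data.frame(width = widths, cv_loss = cv_loss)
    best_width <- widths[which.min(cv_loss)]
  }
  nets <- lapply(seq_len(max(1L, arch$n_ensemble)), function(j)
    fit_one(x, y, best_width, seed + 1000L * (j - 1L)))
  list(kind = "mlp", nets = nets, width = best_width, cv_table = cv_table)
}

predict_estimator <- function(fit, x) {
  switch(fit$kind,
         linear = {
           eta <- as.numeric(cbind(1, x) %*% fit$coef)
           if (!is.null(fit$task) && fit$task == "classification")
             sigmoid(eta) else eta
         },
         forest = predict(fit$forest, x),
         mlp = rowMeans(vapply(fit$nets, function(m) predict_mlp(m, x),
                               numeric(nrow(x)))))
}

#' Train an age-prediction model
#'
#' Fits an MAE-minimizing regressor of chronological age on the feature set.
#' Under the default `"nonsmokers_only"` design the training cohort must
#' contain only nonsmokers and the smoking column may not appear among the
#' features (contamination guard); the
#' `"all_with_smoking_feature"` design lifts both restrictions. Marker
#' features are z-scored with training-set statistics; the MLP width is
#' chosen by `cv_folds`-fold cross-validation; everything is deterministic
#' given the spec seed.
#'
#' @param train Training cohort, complete on the features.
#' @param features A [feature_space()] or character vector of feature
#'   columns (markers, optionally `"sex"` / `"smoking"`).
#' @param spec A [split_spec()].
#' @param arch An [arch_config()].
#' @return An `age_clock` model object.
#' @export
train_age_model <- function(train, features, spec = split_spec(),
                            arch = arch_config()) {
  cols <- feature_columns(features)
  if (spec$train_population == "nonsmokers_only") {
    if ("smoking" %in% cols)
      stop(paste0("train_age_model: smoking status among the input features ",
                  "is not allowed when train_population = 'nonsmokers_only' ",
                  "(use 'all_with_smoking_feature' for the extended variants)"),
           call. = FALSE)
    if (any(train$smoking != 0))
      stop("train_age_model: training cohort contains smokers but ",
           "train_population = 'nonsmokers_only'", call. = FALSE)
  }
  check_complete(train, cols, "train_age_model")
  scaler <- make_scaler(train, cols)
  x <- apply_scaler(scaler, train)
  y_centre <- mean(train$age)
  y_scale <- stats::sd(train$age)
  y <- (train$age - y_centre) / y_scale
  fit <- fit_estimator(x, if (arch$estimator == "mlp") y else train$age,
                       "regression", arch, spec$cv_folds, spec$seed)
  structure(list(fit = fit, features = cols, scaler = scaler,
                 y_centre = if (arch$estimator == "mlp") y_centre else 0,
                 y_scale = if (arch$estimator == "mlp") y_scale else 1,
                 spec = spec, arch = arch, loss = "mae"),
            class = "age_clock")
}

#' Predict ages and assemble a prediction set
#'
#' @param model An `age_clock` from [train_age_model()].
#' @param cohort Cohort complete on the model's features.
#' @return A `prediction_set` data frame with columns `y` (chronological
#'   age), `y_hat` (predicted age), and `age`, `sex`, `smoking` carried
#'   through for stratified analysis.
#' @export
predict_age <- function(model, cohort) {
  stopifnot(inherits(model, "age_clock"))
  check_complete(cohort, model$features, "predict_age")
  x <- apply_scaler(model$scaler, cohort)
  y_hat <- predict_estimator(model$fit, x) * model$y_scale + model$y_centre
  out <- data.frame(y = cohort$age, y_hat = y_hat, age = cohort$age,
                    sex = cohort$sex, smoking = cohort$smoking)
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Regression metrics for an age predictor
#'
#' Pearson correlation between true and predicted age, coefficient of
#' determination `1 - SS_res / SS_tot`, mean absolute error in years, and
#' epsilon-accuracy: the fraction of predictions inside the closed interval
#' `[y - epsilon, y + epsilon]` (a prediction exactly epsilon years off
#' counts as correct).
#'
#' @param pred A `prediction_set` (or data frame with columns `y`, `y_hat`).
#' @param epsilon Half-width of the accuracy interval in years (default 10).
#' @return A `regression_report` list with `r`, `r_squared`, `mae`,
#'   `epsilon_accuracy`, `epsilon`, `n`. With zero variance in `y`, `r` and
#'   `r_squared` are `NA`.
#' @export
regression_metrics <- function(pred, epsilon = 10) {
  y <- pred$y; y_hat <- pred$y_hat
  n <- length(y)
  if (n < 2) stop("regression_metrics: need >= 2 samples", call. = FALSE)
  if (anyNA(y) || anyNA(y_hat))
    stop("regression_metrics: missing values in predictions", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r <- NA_real_; r2 <- NA_real_
  } else {
    num <- sum((y - mean(y)) * (y_hat - mean(y_hat)))
    den <- sqrt(sum((y - mean(y))^2)) * sqrt(sum((y_hat - mean(y_hat))^2))
    r <- if (den == 0) NA_real_ else num / den
    r2 <- 1 - sum((y_hat - y)^2) / sst
  }
  structure(list(r = r, r_squared = r2, mae = mean(abs(y_hat - y)),
                 epsilon_accuracy = mean(abs(y_hat - y) <= epsilon),
                 epsilon = epsilon, n = n),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Age-prediction report (n = %d)\n", x$n))
  cat(sprintf("  MAE       : %.3f years\n", x$mae))
  cat(sprintf("  r         : %s\n", format(x$r, digits = 4)))
  cat(sprintf("  R^2       : %s\n", format(x$r_squared, digits = 4)))
  cat(sprintf("  eps-acc   : %.3f (eps = %g years)\n",
              x$epsilon_accuracy, x$epsilon))
  invisible(x)
}
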