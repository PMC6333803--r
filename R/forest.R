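#' Bagged regression-tree ensemble
#'
#' A compact random-forest-style regressor: `n_trees` depth-limited CART
#' trees, each grown on a bootstrap resample with `mtry` candidate features
#' per split, aggregated by the mean. Used as the tree-ensemble engine behind
#' the arbitrage feature-ranking stage and as the fallback estimator for the
#' age and smoking models.
#'
#' @param x Numeric matrix or data frame of features (complete cases only).
#' @param y Numeric response (age in years, or 0/1 for a probability forest).
#' @param n_trees Number of trees (default 80, the arbitrage-stage setting).
#' @param mtry Features tried per split; default `max(1, floor(p / 3))`.
#' @param max_depth,min_split,min_bucket Tree size controls.
#' @param seed Integer seed; fits are deterministic given the seed.
#'
#' @return An object of class `bagged_forest` with a `predict` method.
#' @export
fit_forest <- function(x, y, n_trees = 80, mtry = NULL, max_depth = 12,
                       min_split = 10, min_bucket = 5, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || anyNA(y)) stop("fit_forest: x and y must be complete",
                                 call. = FALSE)
  if (nrow(x) != length(y)) stop("fit_forest: nrow(x) != length(y)",
                                 call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, ncol(x) %/% 3L)
  trees <- cpp_forest_fit(x, as.numeric(y), as.integer(n_trees),
                          as.integer(mtry), as.integer(max_depth),
                          as.integer(min_split), as.integer(min_bucket),
                          as.integer(seed))
  structure(list(trees = trees, features = colnames(x),
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 seed = as.integer(seed)),
            class = "bagged_forest")
}

#' @param object A `bagged_forest`.
#' @param newdata Matrix or data frame containing the model's feature columns.
#' @param ... Unused.
#' @rdname fit_forest
#' @export
predict.bagged_forest <- function(object, newdata, ...) {
  if (!is.null(object$features)) {
    missing_cols <- setdiff(object$features, colnames(newdata))
    if (length(missing_cols))
      stop("predict.bagged_forest: missing feature column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    newdata <- newdata[, object$features, drop = FALSE]
  }
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  as.numeric(cpp_forest_predict(object$trees, newdata))
}

# Mean-decrease-accuracy importance of a fitted forest on a held-out set:
# the MAE increase when one feature column is permuted (seeded), averaged
# over n_repeats permutations.
forest_mda <- function(forest, x, y, n_repeats = 3, seed = 1L) {
  x <- as.data.frame(x)
  base_mae <- mean(abs(predict(forest, x) - y))
  feats <- forest$features
  set.seed(seed)
  q <- vapply(feats, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
      mean(abs(predict(forest, xp) - y)) - base_mae
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  q
}
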