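#' Fit a per-marker reconstruction regression
#'
#' Ordinary least squares of one target marker on a set of predictor markers
#' plus age and sex, fitted on the subjects where target and predictors are
#' all observed. The fitted model is later used to predict the target where
#' it is missing, expanding the usable feature space.
#'
#' @param cohort Cohort data frame.
#' @param target Target marker name.
#' @param predictors Predictor marker names (age and sex are always added).
#' @param min_rows Minimum complete fitting rows (default 100).
#' @return An `imputation_model` with elements `target`, `predictors`,
#'   `coefficients` (intercept first), `fit_n`, `fit_fraction`.
#' @export
fit_marker_regression <- function(cohort, target, predictors,
                                  min_rows = 100) {
  if (!target %in% names(cohort))
    stop("fit_marker_regression: unknown target '", target, "'",
         call. = FALSE)
  predictors <- setdiff(as.character(predictors), target)
  vars <- c(predictors, "age", "sex")
  rows <- stats::complete.cases(cohort[, c(target, vars), drop = FALSE])
  if (sum(rows) < min_rows)
    stop(sprintf(paste0("fit_marker_regression: only %d complete rows for ",
                        "target '%s' (need >= %d)"),
                 sum(rows), target, min_rows), call. = FALSE)
  dat <- cohort[rows, c(target, vars), drop = FALSE]
  x <- as.matrix(cbind(`(Intercept)` = 1, dat[, vars, drop = FALSE]))
  fit <- stats::lm.fit(x, dat[[target]])
  if (fit$rank < ncol(x)) {
    aliased <- colnames(x)[is.na(fit$coefficients)]
    stop("fit_marker_regression: rank-deficient design; collinear predictor(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(list(target = target, predictors = vars,
                 coefficients = fit$coefficients,
                 fit_n = as.integer(sum(rows)),
                 fit_fraction = sum(rows) / nrow(cohort)),
            class = "imputation_model")
}

predict_imputation <- function(model, cohort, rows) {
  x <- as.matrix(cbind(1, cohort[rows, model$predictors, drop = FALSE]))
  as.numeric(x %*% model$coefficients)
}

#' Reconstruct missing marker values
#'
#' Fills missing cells of each modeled marker with its regression prediction,
#' in the order the models are given (fit them in ascending-missingness order
#' so earlier reconstructions can serve later ones). Observed values are
#' never overwritten. Rows whose predictors are still missing are left
#' missing and counted.
#'
#' @param cohort Cohort data frame.
#' @param models List of [fit_marker_regression()] models.
#' @return The cohort with modeled markers filled; attribute `"provenance"`
#'   is a logical matrix (subjects x modeled markers, `TRUE` =
#'   reconstructed) and attribute `"unfilled"` a named count of cells that
#'   could not be filled.
#' @export
reconstruct_missing <- function(cohort, models) {
  out <- cohort
  targets <- vapply(models, function(m) m$target, character(1))
  prov <- matrix(FALSE, nrow(cohort), length(targets),
                 dimnames = list(NULL, targets))
  unfilled <- stats::setNames(integer(length(targets)), targets)
  for (m in models) {
    need <- is.na(out[[m$target]])
    if (!any(need)) next
    havepred <- stats::complete.cases(out[, m$predictors, drop = FALSE])
    fill <- which(need & havepred)
    if (length(fill)) {
      out[fill, m$target] <- predict_imputation(m, out, fill)
      prov[fill, m$target] <- TRUE
    }
    unfilled[m$target] <- sum(need & !havepred)
  }
  attr(out, "provenance") <- prov
  attr(out, "unfilled") <- unfilled
  out
}

#' Reconstruct the markers of a feature set
#'
#' Convenience wrapper for the reconstruction stage: for each marker of
#' `space` with missing values, fits a regression on the fully observed
#' markers of the space (plus age and sex) and fills the gaps, processing
#' targets in ascending order of missingness.
#'
#' @param cohort Cohort data frame.
#' @param space A [feature_space()] whose markers should become complete.
#' @param min_rows Passed to [fit_marker_regression()].
#' @return As [reconstruct_missing()], with attribute `"models"` carrying the
#'   fitted per-marker regressions.
#' @export
reconstruct_feature_set <- function(cohort, space, min_rows = 100) {
  mk <- space$markers
  n_miss <- vapply(mk, function(m) sum(is.na(cohort[[m]])), integer(1))
  complete <- mk[n_miss == 0]
  targets <- mk[n_miss > 0][order(n_miss[n_miss > 0],
                                  mk[n_miss > 0])]
  if (!length(targets)) {
    attr(cohort, "provenance") <- matrix(FALSE, nrow(cohort), 0)
    attr(cohort, "unfilled") <- integer(0)
    attr(cohort, "models") <- list()
    return(cohort)
  }
  models <- lapply(targets, function(tg)
    fit_marker_regression(cohort, tg, complete, min_rows = min_rows))
  out <- reconstruct_missing(cohort, models)
  attr(out, "models") <- models
  out
}
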