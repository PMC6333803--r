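#' Construct a feature space
#'
#' A feature space is a marker subset together with the number of subjects
#' observed for all its markers (complete cases), the quantity the selection
#' stage trades off against set size.
#'
#' @param markers Character vector of marker names (non-empty, unique).
#' @param cohort Cohort data frame used to count eligible subjects.
#' @return A `feature_space` list with elements `markers` and `eligible_n`.
#' @export
feature_space <- function(markers, cohort) {
  markers <- as.character(markers)
  if (!length(markers)) stop("feature_space: 'markers' must be non-empty",
                             call. = FALSE)
  if (anyDuplicated(markers))
    stop("feature_space: duplicated marker names", call. = FALSE)
  absent <- setdiff(markers, names(cohort))
  if (length(absent))
    stop("feature_space: marker(s) not in cohort: ",
         paste(absent, collapse = ", "), call. = FALSE)
  eligible <- sum(stats::complete.cases(cohort[, markers, drop = FALSE]))
  structure(list(markers = markers, eligible_n = as.integer(eligible)),
            class = "feature_space")
}

space_key <- function(markers) paste(sort(markers), collapse = "|")

#' Enumerate candidate feature spaces
#'
#' Builds `n_spaces` distinct marker subsets for the arbitrage ranking stage:
#' first the nested prefix sets of the candidates ordered by ascending
#' missingness (these maximize eligible samples at each size), then seeded
#' random subsets until the quota is reached. Subsets whose complete-case
#' count falls below `min_eligible` are not emitted, so every returned space
#' is trainable downstream.
#'
#' @param cohort Cohort data frame.
#' @param candidates Candidate marker names (>= 2); defaults to all markers.
#' @param n_spaces Number of distinct spaces required (default 320).
#' @param min_eligible Minimum complete-case count per space (default 50).
#' @param seed Integer seed for the random subsets.
#' @return A list of [feature_space()] objects of length `n_spaces`.
#' @export
enumerate_feature_spaces <- function(cohort, candidates = marker_names(cohort),
                                     n_spaces = 320, min_eligible = 50,
                                     seed = 1L) {
  candidates <- as.character(candidates)
  if (length(candidates) < 2)
    stop("enumerate_feature_spaces: need >= 2 candidate markers",
         call. = FALSE)
  if (n_spaces < 1)
    stop("enumerate_feature_spaces: n_spaces must be >= 1", call. = FALSE)
  p <- length(candidates)
  max_subsets <- if (p < 31) 2^p - 1 else Inf
  if (n_spaces > max_subsets)
    stop(sprintf(paste0("enumerate_feature_spaces: %d spaces requested but ",
                        "only %d distinct non-empty subsets exist"),
                 n_spaces, max_subsets), call. = FALSE)

  spaces <- list()
  seen <- character(0)
  add <- function(markers) {
    key <- space_key(markers)
    if (key %in% seen) return(FALSE)
    sp <- feature_space(markers, cohort)
    if (sp$eligible_n < min_eligible) return(FALSE)
    seen <<- c(seen, key)
    spaces[[length(spaces) + 1L]] <<- sp
    TRUE
  }

  # (a) nested prefixes by ascending missingness
  n_miss <- vapply(candidates, function(m) sum(is.na(cohort[[m]])), integer(1))
  ord <- candidates[order(n_miss, candidates)]
  for (k in 2:p) {
    if (length(spaces) >= n_spaces) break
    add(ord[seq_len(k)])
  }

  # (b) seeded random subsets
  set.seed(seed)
  size_lo <- if (p <= 5) 1L else 5L
  attempts <- 0L
  max_attempts <- max(2000L, 200L * n_spaces)
  while (length(spaces) < n_spaces && attempts < max_attempts) {
    attempts <- attempts + 1L
    k <- sample(size_lo:p, 1L)
    add(sample(candidates, k))
  }
  if (length(spaces) < n_spaces)
    stop(sprintf(paste0("enumerate_feature_spaces: only %d distinct spaces ",
                        "with >= %d eligible subjects attainable ",
                        "(requested %d)"),
                 length(spaces), min_eligible, n_spaces), call. = FALSE)
  spaces[seq_len(n_spaces)]
}

#' Fit the arbitrage model ensemble
#'
#' Trains one bagged regression-tree ensemble per feature space on the
#' complete cases of that space, with chronological age as the target. Each
#' model's record carries its held-out mean absolute error `MAE_i` (20% split,
#' seeded per record index) and its per-marker mean-decrease-accuracy
#' importance `q_i` (permutation importance on the held-out split).
#'
#' @param cohort Cohort data frame.
#' @param spaces List of [feature_space()] objects.
#' @param n_trees Trees per ensemble (default 80).
#' @param seed Integer base seed; record `i` uses `seed + i`.
#' @param min_eligible Spaces with fewer complete cases are skipped with a
#'   warning (default 50).
#' @param holdout_fraction Held-out fraction for `MAE_i` (default 0.2).
#' @param max_depth Tree depth limit for the ranking forests (default 8;
#'   shallow trees keep the 320-model stage fast without changing the
#'   ranking).
#' @return A list of `arbitrage_record` objects (`space`, `mae`,
#'   `importance`), with skipped spaces recorded in attribute `"skipped"`.
#' @export
fit_arbitrage_ensemble <- function(cohort, spaces, n_trees = 80, seed = 1L,
                                   min_eligible = 50, holdout_fraction = 0.2,
                                   max_depth = 8) {
  records <- list()
  skipped <- character(0)
  for (i in seq_along(spaces)) {
    sp <- spaces[[i]]
    rows <- stats::complete.cases(cohort[, sp$markers, drop = FALSE])
    dat <- cohort[rows, , drop = FALSE]
    if (nrow(dat) < min_eligible) {
      msg <- sprintf("space %d skipped: eligible n = %d < %d",
                     i, nrow(dat), min_eligible)
      warning(msg, call. = FALSE)
      skipped <- c(skipped, msg)
      next
    }
    set.seed(seed + i)
    n <- nrow(dat)
    test_idx <- sample.int(n, max(1L, round(holdout_fraction * n)))
    train <- dat[-test_idx, , drop = FALSE]
    test <- dat[test_idx, , drop = FALSE]
    forest <- fit_forest(train[, sp$markers, drop = FALSE], train$age,
                         n_trees = n_trees, max_depth = max_depth,
                         seed = seed + i)
    mae <- mean(abs(predict(forest, test) - test$age))
    q <- forest_mda(forest, test[, sp$markers, drop = FALSE], test$age,
                    n_repeats = 3, seed = seed + i)
    records[[length(records) + 1L]] <- structure(
      list(space = sp, mae = mae, importance = q, n_trees = n_trees),
      class = "arbitrage_record")
  }
  attr(records, "skipped") <- skipped
  records
}

#' Aggregate arbitrage feature importance
#'
#' For each marker, the arbitrage importance is the sum over models containing
#' it of `q_i(marker) / MAE_i`: a marker scores highly when it is important in
#' accurate models. Ranking is by descending FI with ties broken by ascending
#' marker name.
#'
#' @param records List of records from [fit_arbitrage_ensemble()].
#' @return A data frame with columns `marker`, `fi`, `n_models`, sorted by
#'   descending `fi`.
#' @export
arbitrage_fi <- function(records) {
  if (!length(records))
    stop("arbitrage_fi: need >= 1 record", call. = FALSE)
  fi <- numeric(0)
  n_models <- integer(0)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (!is.numeric(rec$mae) || rec$mae == 0)
      stop(sprintf("arbitrage_fi: record %d has MAE = 0 (division undefined)",
                   i), call. = FALSE)
    lacking <- setdiff(rec$space$markers, names(rec$importance))
    if (length(lacking))
      stop(sprintf("arbitrage_fi: record %d lacks importance for marker(s): %s",
                   i, paste(lacking, collapse = ", ")), call. = FALSE)
    for (m in rec$space$markers) {
      if (!m %in% names(fi)) { fi[m] <- 0; n_models[m] <- 0L }
      fi[m] <- fi[m] + rec$importance[[m]] / rec$mae
      n_models[m] <- n_models[m] + 1L
    }
  }
  out <- data.frame(marker = names(fi), fi = as.numeric(fi),
                    n_models = as.integer(n_models), stringsAsFactors = FALSE)
  out[order(-out$fi, out$marker), , drop = FALSE]
}

#' Select nested feature sets from an arbitrage ranking
#'
#' Markers are added greedily in descending arbitrage FI, tracking the number
#' of subjects with complete data at each prefix size. A "knee" is a size at
#' which adding the next marker costs more than `knee_fraction` of the
#' currently eligible subjects; the first `n_sets` knees (the ones with the
#' largest eligible counts) define the selected sets. If fewer knees exist the
#' selection is padded with the largest sizes. Sets are nested prefixes,
#' returned sorted by size.
#'
#' @param scores Data frame from [arbitrage_fi()] (columns `marker`, `fi`).
#' @param cohort Cohort data frame.
#' @param n_sets Number of sets (default 3).
#' @param knee_fraction Relative eligible-n drop defining a knee
#'   (default 0.10).
#' @return A list of `n_sets` [feature_space()] objects.
#' @export
select_feature_sets <- function(scores, cohort, n_sets = 3,
                                knee_fraction = 0.10) {
  if (is.null(scores) || !nrow(scores))
    stop("select_feature_sets: empty scores", call. = FALSE)
  ord <- scores[order(-scores$fi, scores$marker), , drop = FALSE]
  markers <- ord$marker
  p <- length(markers)
  obs <- !is.na(as.matrix(cohort[, markers, drop = FALSE]))
  all_obs <- rep(TRUE, nrow(cohort))
  eligible <- integer(p)
  for (k in seq_len(p)) {
    all_obs <- all_obs & obs[, k]
    eligible[k] <- sum(all_obs)
  }
  drop_frac <- c((eligible[-p] - eligible[-1]) / pmax(eligible[-p], 1L), 0)
  knees <- which(drop_frac > knee_fraction)
  sizes <- utils::head(knees, n_sets)
  if (length(sizes) < n_sets) {
    pad <- setdiff(rev(seq_len(p)), sizes)
    sizes <- c(sizes, utils::head(pad, n_sets - length(sizes)))
  }
  sizes <- sort(sizes)
  lapply(sizes, function(k) feature_space(markers[seq_len(k)], cohort))
}
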