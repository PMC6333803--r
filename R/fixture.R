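#' Packaged nested-feature-space fixture
#'
#' A synthetic cohort built for the reconstruction-expansion check: 18 fully
#' observed markers (`m01`-`m18`, descending age-informativeness) plus five
#' partially missing markers (`m19`-`m23`, 35-55% missing completely at
#' random). Three nested feature spaces are packaged with it, containing 14,
#' 15 and 18 fully observed markers plus 4, 5 and 5 partial markers, so that
#' reconstructing the partial markers expands their complete-marker counts
#' from 14/15/18 to 18/20/23.
#'
#' @param n Number of subjects (default 2000).
#' @param seed Integer seed (default 1).
#' @return A list with elements `cohort`, `spaces` (list of three nested
#'   [feature_space()] objects, ascending size) and `panel`.
#' @export
fixture_nested_spaces <- function(n = 2000, seed = 1L) {
  nm <- sprintf("m%02d", 1:23)
  slopes <- seq(0.09, 0.02, length.out = 23)
  miss <- c(rep(0, 18), 0.35, 0.40, 0.45, 0.50, 0.55)
  panel <- do.call(rbind, lapply(1:23, function(i)
    marker_spec(nm[i], "au", mean_female = 10, mean_male = 10.5, sd = 1,
                age_slope = slopes[i], missing_rate = miss[i])))
  cfg <- generator_config(n_subjects = n, panel = panel, seed = seed)
  cohort <- generate_cohort(cfg)
  spaces <- list(
    feature_space(c(nm[1:14], nm[19:22]), cohort),
    feature_space(c(nm[1:15], nm[19:23]), cohort),
    feature_space(c(nm[1:18], nm[19:23]), cohort))
  list(cohort = cohort, spaces = spaces, panel = panel)
}

#' Count fully observed markers of a feature space
#'
#' @param cohort Cohort data frame.
#' @param space A [feature_space()].
#' @return The number of the space's markers with no missing values.
#' @export
n_complete_markers <- function(cohort, space) {
  sum(vapply(space$markers, function(m) !anyNA(cohort[[m]]), logical(1)))
}
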