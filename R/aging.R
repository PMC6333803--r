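#' Per-sample log2 aging ratio
#'
#' `log2(y_hat / y)`: 0 means on-clock, 1 means predicted twice as old as the
#' chronological age, -1 half as old. Samples with a nonpositive predicted
#' age (possible for an unconstrained regressor) are excluded (`NA`) and
#' counted.
#'
#' @param pred A `prediction_set` (or data frame with columns `y`, `y_hat`);
#'   chronological ages must be positive.
#' @return Numeric vector of per-sample ratios aligned with `pred` rows
#'   (`NA` for excluded samples); the exclusion count is attached as
#'   attribute `"n_excluded"`.
#' @export
log2_aging_ratio <- function(pred) {
  y <- pred$y; y_hat <- pred$y_hat
  if (any(y <= 0)) stop("log2_aging_ratio: chronological ages must be > 0",
                        call. = FALSE)
  bad <- y_hat <= 0
  ratio <- rep(NA_real_, length(y))
  ratio[!bad] <- log2(y_hat[!bad] / y[!bad])
  attr(ratio, "n_excluded") <- sum(bad)
  ratio
}

# Two-tailed Mann-Whitney through the paper's own tool (stats::wilcox.test):
# exact when both groups are small (<= 50) and tie-free, otherwise normal
# approximation with tie correction.
mann_whitney_p <- function(a, b) {
  if (!length(a) || !length(b)) return(NA_real_)
  exact <- max(length(a), length(b)) <= 50 && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Aging-ratio summaries by age group, sex and smoking status
#'
#' Per (age group x sex x smoking) cell: n, mean and SD of the per-sample
#' log2 aging ratio, plus a two-tailed Mann-Whitney p-value comparing smoker
#' and nonsmoker ratios within the (age group x sex) stratum (the same p is
#' reported on both rows of a stratum) and a significance flag at p < 0.05.
#' Empty cells are emitted with `n = 0` and `NA` statistics.
#'
#' @param pred A `prediction_set` carrying `age`, `sex`, `smoking`.
#' @param bins Age bins as from [default_age_bins()].
#' @return An `aging_ratio_table` data frame.
#' @export
group_aging_summary <- function(pred, bins = default_age_bins()) {
  ratio <- log2_aging_ratio(pred)
  bin <- age_bin(pred$age, bins)
  grid <- expand.grid(age_group = bins$labels, sex = c(0L, 1L),
                      smoking = c(0L, 1L), stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$age_group, bins$labels), grid$sex,
                     grid$smoking), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    in_stratum <- bin == g$age_group & pred$sex == g$sex
    rs <- ratio[in_stratum & pred$smoking == 1]
    rn <- ratio[in_stratum & pred$smoking == 0]
    rs <- rs[!is.na(rs)]; rn <- rn[!is.na(rn)]
    own <- if (g$smoking == 1) rs else rn
    p <- if (length(rs) && length(rn)) mann_whitney_p(rs, rn) else NA_real_
    data.frame(age_group = g$age_group, sex = g$sex, smoking = g$smoking,
               n = length(own),
               mean_ratio = if (length(own)) mean(own) else NA_real_,
               sd_ratio = if (length(own) > 1) stats::sd(own) else NA_real_,
               p_value = p,
               significant = if (is.na(p)) NA else p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- attr(ratio, "n_excluded")
  class(out) <- c("aging_ratio_table", "data.frame")
  out
}

#' Cardiovascular risk quadrants from cholesterol ratio and fasting glucose
#'
#' The cholesterol ratio is total cholesterol divided by HDL cholesterol.
#' Subjects are assigned to the 2x2 of (ratio > 4 vs <= 4) and (fasting
#' glucose > 5 vs <= 5 mmol/L); inequalities are strict on the "high" side
#' exactly as thresholds are stated. Rows with nonpositive HDL are excluded
#' (`NA`) and counted.
#'
#' @param cohort Data frame with observed (or reconstructed) columns
#'   `total_cholesterol`, `hdl` and `fasting_glucose`.
#' @return A factor of quadrant labels aligned with `cohort` rows, with the
#'   numeric `cholesterol_ratio` as attribute `"cholesterol_ratio"` and the
#'   exclusion count as attribute `"n_excluded"`.
#' @export
assign_risk_groups <- function(cohort) {
  needed <- c("total_cholesterol", "hdl", "fasting_glucose")
  absent <- setdiff(needed, names(cohort))
  if (length(absent))
    stop("assign_risk_groups: missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (anyNA(cohort[, needed]))
    stop("assign_risk_groups: the three risk markers must be observed or ",
         "reconstructed for all rows", call. = FALSE)
  bad <- cohort$hdl <= 0
  if (any(bad))
    warning(sum(bad), " row(s) excluded: HDL <= 0", call. = FALSE)
  ratio <- ifelse(bad, NA_real_, cohort$total_cholesterol / cohort$hdl)
  hi_r <- ratio > 4
  hi_g <- cohort$fasting_glucose > 5
  labels <- c("ratio<=4_glucose<=5", "ratio<=4_glucose>5",
              "ratio>4_glucose<=5", "ratio>4_glucose>5")
  idx <- 1L + hi_g + 2L * hi_r
  out <- factor(labels[ifelse(is.na(ratio), NA_integer_, idx)],
                levels = labels)
  attr(out, "cholesterol_ratio") <- ratio
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Aging-ratio summaries by risk quadrant
#'
#' As [group_aging_summary()] with the cardiovascular risk quadrant as an
#' extra stratification key: mean +/- SD of the log2 aging ratio per
#' (quadrant x age group x sex x smoking) cell. Cells with no samples are
#' emitted with `n = 0`.
#'
#' @param pred A `prediction_set`.
#' @param risk Quadrant factor from [assign_risk_groups()], aligned with
#'   `pred` rows.
#' @param bins Age bins as from [default_age_bins()].
#' @return A data frame keyed by (quadrant, age_group, sex, smoking) with
#'   `n`, `mean_ratio`, `sd_ratio`.
#' @export
risk_group_aging_summary <- function(pred, risk, bins = default_age_bins()) {
  stopifnot(length(risk) == nrow(pred))
  ratio <- log2_aging_ratio(pred)
  bin <- age_bin(pred$age, bins)
  grid <- expand.grid(quadrant = levels(risk), age_group = bins$labels,
                      sex = c(0L, 1L), smoking = c(0L, 1L),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    r <- ratio[!is.na(risk) & risk == g$quadrant & bin == g$age_group &
                 pred$sex == g$sex & pred$smoking == g$smoking]
    r <- r[!is.na(r)]
    data.frame(quadrant = g$quadrant, age_group = g$age_group, sex = g$sex,
               smoking = g$smoking, n = length(r),
               mean_ratio = if (length(r)) mean(r) else NA_real_,
               sd_ratio = if (length(r) > 1) stats::sd(r) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Biweight midcorrelation
#'
#' Robust correlation: both vectors are median-centred, observations are
#' weighted by Tukey biweights with the 9-MAD cutoff, and the weighted
#' cross-product is normalized by the weighted norms. Less sensitive to
#' outliers than Pearson's r.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A correlation in \[-1, 1\].
#' @export
biweight_midcorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("biweight_midcorrelation: length mismatch",
                                   call. = FALSE)
  if (length(x) < 3) stop("biweight_midcorrelation: need length >= 3",
                          call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("biweight_midcorrelation: missing values", call. = FALSE)
  bw <- function(v) {
    med <- stats::median(v)
    mad <- stats::median(abs(v - med))
    if (mad == 0)
      stop("biweight_midcorrelation: zero median absolute deviation ",
           "(degenerate dispersion)", call. = FALSE)
    u <- (v - med) / (9 * mad)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  a <- bw(x); b <- bw(y)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}
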