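#' Configure the synthetic cohort generator
#'
#' The generator stands in for the (private) administrative dataset the
#' analysis was designed for: ~1/3 smokers, median age 55, sex and smoking
#' balanced within each 10-year age group, up to 66 markers with per-marker
#' missingness, and a planted smoking effect that multiplies biological age
#' below a plateau age.
#'
#' @param n_subjects Number of subjects (>= 20).
#' @param smoker_fraction Fraction of smokers, in (0, 1); realized count is
#'   quota-exact: `round(smoker_fraction * n_subjects)`.
#' @param age_range Integer age interval, default `c(18, 92)`; ages are
#'   assigned on a deterministic symmetric grid so the median equals the
#'   midpoint (55 by default) exactly.
#' @param acceleration_factor Named pair `c(female = , male = )` of
#'   multipliers (>= 1) mapping chronological to biological age in smokers
#'   below `plateau_age`. Defaults plant the study's headline analogue:
#'   female smokers age twice as fast, males one and a half times.
#' @param plateau_age Age at/above which the smoking acceleration vanishes
#'   (default 55).
#' @param plateau_shape `"hard"` (effect drops to zero at `plateau_age`) or
#'   `"taper"` (excess factor shrinks linearly to zero at `plateau_age`).
#' @param panel Marker panel data frame (see [default_marker_panel()]).
#' @param seed Integer seed; identical configs produce identical cohorts.
#'
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_subjects,
                             smoker_fraction = 0.33,
                             age_range = c(18L, 92L),
                             acceleration_factor = c(female = 2.0, male = 1.5),
                             plateau_age = 55,
                             plateau_shape = c("hard", "taper"),
                             panel = default_marker_panel(),
                             seed = 1L) {
  plateau_shape <- match.arg(plateau_shape)
  bad <- function(field, why)
    stop(sprintf("generator_config: invalid '%s': %s", field, why),
         call. = FALSE)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 20)
    bad("n_subjects", "must be a single number >= 20")
  if (!is.numeric(smoker_fraction) || smoker_fraction <= 0 || smoker_fraction >= 1)
    bad("smoker_fraction", "must lie in (0, 1)")
  if (length(age_range) != 2L || age_range[1] >= age_range[2] || age_range[1] < 0)
    bad("age_range", "must be an increasing non-negative pair")
  if (length(acceleration_factor) != 2L || any(acceleration_factor < 1))
    bad("acceleration_factor", "must be a pair of factors >= 1")
  if (is.null(names(acceleration_factor)))
    names(acceleration_factor) <- c("female", "male")
  if (!is.numeric(plateau_age) || plateau_age <= age_range[1])
    bad("plateau_age", "must exceed the lower age bound")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    bad("seed", "must be a single integer")
  validate_panel(panel)
  structure(list(n_subjects = as.integer(n_subjects),
                 smoker_fraction = smoker_fraction,
                 age_range = as.integer(age_range),
                 acceleration_factor = acceleration_factor,
                 plateau_age = plateau_age,
                 plateau_shape = plateau_shape,
                 panel = panel,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Largest-remainder apportionment of `total` integer units over `weights`,
# capped elementwise at `cap`; quota-exact by construction.
apportion <- function(total, weights, cap = NULL) {
  if (total == 0) return(integer(length(weights)))
  q <- total * weights / sum(weights)
  out <- floor(q)
  rem <- q - out
  left <- total - sum(out)
  if (left > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    out[take] <- out[take] + 1
  }
  if (!is.null(cap)) {
    over <- out > cap
    while (any(over)) {
      excess <- sum(out[over] - cap[over])
      out[over] <- cap[over]
      room <- which(out < cap)
      if (!length(room) || excess == 0) break
      give <- room[order(rem[room], decreasing = TRUE)]
      give <- rep_len(give, excess)
      for (g in give) out[g] <- out[g] + 1
      over <- out > cap
    }
  }
  as.integer(out)
}

# Biological age under the planted smoking acceleration.
biological_age <- function(age, sex, smoking, config) {
  accel <- config$acceleration_factor[ifelse(sex == 1, 2L, 1L)]
  if (config$plateau_shape == "hard") {
    eff <- ifelse(smoking == 1 & age < config$plateau_age, accel, 1)
  } else {
    span <- config$plateau_age - config$age_range[1]
    frac <- pmax(0, (config$plateau_age - age) / span)
    eff <- 1 + (accel - 1) * frac * smoking
  }
  age * eff
}

#' Generate a synthetic blood-biochemistry cohort
#'
#' Ages are placed on a deterministic symmetric grid over `age_range` (median
#' = midpoint exactly) and shuffled with the seed. Sex and smoking are
#' assigned by largest-remainder quotas within 10-year age groups, so the
#' smoker count equals `round(smoker_fraction * n)` exactly and groups are
#' balanced. Each marker value is drawn as
#' `baseline_mean[sex] + age_response(B - age_centre) + smoking_offset * smoking
#'  + N(0, sd)` where the biological age `B` equals chronological age times
#' the sex-specific acceleration factor for smokers below the plateau age.
#' Missingness is MCAR and quota-exact per marker.
#'
#' @param config A [generator_config()].
#' @return A data frame with columns `id`, `age`, `sex` (0 = female,
#'   1 = male), `smoking` (0/1), then one column per panel marker (`NA` =
#'   missing).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  lo <- config$age_range[1]; hi <- config$age_range[2]

  ages <- round(seq(lo, hi, length.out = n))
  ages <- ages[sample.int(n)]

  group <- pmin((ages - lo) %/% 10L, (hi - lo) %/% 10L)
  glev <- sort(unique(group))
  gsize <- as.integer(table(factor(group, levels = glev)))

  sex <- integer(n)
  smoking <- integer(n)
  males_per_group <- apportion(round(n / 2), gsize, cap = gsize)
  smokers_per_group <- apportion(round(config$smoker_fraction * n), gsize,
                                 cap = gsize)
  for (k in seq_along(glev)) {
    rows <- which(group == glev[k])
    male_rows <- sample(rows, males_per_group[k])
    sex[male_rows] <- 1L
    female_rows <- setdiff(rows, male_rows)
    by_sex <- apportion(smokers_per_group[k],
                        c(length(female_rows), length(male_rows)),
                        cap = c(length(female_rows), length(male_rows)))
    if (by_sex[1] > 0) smoking[sample(female_rows, by_sex[1])] <- 1L
    if (by_sex[2] > 0) smoking[sample(male_rows, by_sex[2])] <- 1L
  }

  bio <- biological_age(ages, sex, smoking, config)
  centre <- mean(config$age_range)

  cohort <- data.frame(id = sprintf("S%06d", seq_len(n)),
                       age = as.integer(ages), sex = sex, smoking = smoking,
                       stringsAsFactors = FALSE)
  panel <- config$panel
  for (i in seq_len(nrow(panel))) {
    p <- panel[i, ]
    dev <- bio - centre
    resp <- if (p$shape == "saturating") p$age_slope * 20 * tanh(dev / 20)
            else p$age_slope * dev
    mu <- ifelse(sex == 1, p$mean_male, p$mean_female) + resp +
      p$smoking_offset * smoking
    val <- mu + rnorm(n, 0, p$sd)
    n_miss <- round(p$missing_rate * n)
    if (n_miss > 0) val[sample.int(n, n_miss)] <- NA_real_
    cohort[[p$name]] <- val
  }
  attr(cohort, "generator_config") <- config
  cohort
}

#' Expected per-stratum log2 aging ratio planted by a generator config
#'
#' Ground truth for parameter-recovery tests: for smokers below the plateau
#' age the generator multiplies biological age by the sex-specific
#' acceleration factor, so a well-calibrated clock should recover a mean log2
#' aging ratio of `log2(factor)` there and 0 everywhere else.
#'
#' @param config A [generator_config()].
#' @return A data frame over (sex, smoking, age band) with the expected mean
#'   log2 aging ratio.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  g <- expand.grid(sex = c(0L, 1L), smoking = c(0L, 1L),
                   age_band = c("below_plateau", "at_or_above_plateau"),
                   stringsAsFactors = FALSE)
  fac <- config$acceleration_factor[ifelse(g$sex == 1, 2L, 1L)]
  g$expected_log2_ratio <- ifelse(
    g$smoking == 1 & g$age_band == "below_plateau", log2(fac), 0)
  g
}

#' Marker columns of a cohort
#' @param cohort A cohort data frame.
#' @return Character vector of marker column names.
#' @export
marker_names <- function(cohort) {
  setdiff(names(cohort), c("id", "age", "sex", "smoking"))
}

#' Write / read a cohort as CSV
#'
#' One header row; columns `id, age, sex, smoking`, then markers; missing
#' values as empty cells; UTF-8, LF newlines. Round-trips exactly up to
#' numeric printing precision, and identical cohorts produce byte-identical
#' files.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(cohort, con, row.names = FALSE, na = "", quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}
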