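test_that("log2 aging ratio hits its closed forms and excludes bad predictions", {
  pred <- make_prediction_set(y = c(40, 50, 60), y_hat = c(80, 50, 30))
  r <- log2_aging_ratio(pred)
  expect_equal(as.numeric(r), c(1, 0, -1))
  expect_equal(attr(r, "n_excluded"), 0L)
  set.seed(61)
  y <- runif(100, 20, 90)
  y_hat <- y * 2^runif(100, -1, 1)
  expect_equal(as.numeric(log2_aging_ratio(make_prediction_set(y, y_hat))),
               oracle_log2_ratio(y, y_hat), tolerance = 1e-10)
  bad <- make_prediction_set(c(40, 50), c(-3, 60))
  rb <- log2_aging_ratio(bad)
  expect_true(is.na(rb[1]))
  expect_equal(attr(rb, "n_excluded"), 1L)
  expect_error(log2_aging_ratio(make_prediction_set(c(0, 50), c(10, 20))),
               "> 0")
})

test_that("swapping a k-fold prediction for its reciprocal flips the sign", {
  set.seed(67)
  y <- runif(50, 20, 90)
  for (k in c(1.3, 2, 3)) {
    up <- log2_aging_ratio(make_prediction_set(y, k * y))
    down <- log2_aging_ratio(make_prediction_set(y, y / k))
    expect_equal(as.numeric(up), -as.numeric(down), tolerance = 1e-12)
  }
})

test_that("identical smoker and nonsmoker ratios give p = 1 on tiny cells", {
  vals <- c(0.1, 0.2, 0.3)
  pred <- make_prediction_set(y = rep(40, 6),
                              y_hat = rep(40 * 2^vals, 2),
                              age = rep(40, 6), sex = 0L,
                              smoking = rep(c(1L, 0L), each = 3))
  tab <- group_aging_summary(pred)
  row <- tab[tab$age_group == "31-40" & tab$sex == 0 & tab$smoking == 1, ]
  expect_equal(row$n, 3L)
  expect_equal(row$p_value, 1)
  expect_false(row$significant)
})

test_that("group summaries recover the planted acceleration structure", {
  co <- generate_cohort(generator_config(n_subjects = 4000, seed = 71))
  core <- marker_names(co)[colSums(is.na(co[marker_names(co)])) == 0]
  ns <- co[co$smoking == 0, ]
  spec <- split_spec(seed = 10)
  parts <- split_train_test(ns, spec)
  clock <- train_age_model(parts$train, c(core, "sex"), spec,
                           arch_config("linear"))
  pred <- predict_age(clock, rbind(parts$test, co[co$smoking == 1, ]))
  tab <- group_aging_summary(pred)
  young_f <- tab[tab$age_group %in% c("<31", "31-40") & tab$sex == 0, ]
  expect_true(all(young_f$mean_ratio[young_f$smoking == 1] > 0.7))
  expect_true(all(young_f$p_value < 0.05))
  old <- tab[tab$age_group %in% c("61-70", ">70") & tab$n > 0, ]
  expect_true(all(abs(old$mean_ratio) < 0.1))
  # empty cells are emitted with n = 0, not dropped
  few <- make_prediction_set(c(25, 26), c(25, 27), age = c(25, 26),
                             sex = 0L, smoking = 0L)
  tab2 <- group_aging_summary(few)
  expect_equal(nrow(tab2), 24L)
  expect_true(all(is.na(tab2$mean_ratio[tab2$n == 0])))
})

test_that("risk quadrants follow the stated strict/weak threshold sides", {
  co <- data.frame(total_cholesterol = c(5.0, 4.0, 3.0, 4.4),
                   hdl = c(1.0, 1.0, 1.0, 1.0),
                   fasting_glucose = c(5.5, 5.0, 6.0, 4.9))
  q <- assign_risk_groups(co)
  expect_equal(as.character(q),
               c("ratio>4_glucose>5", "ratio<=4_glucose<=5",
                 "ratio<=4_glucose>5", "ratio>4_glucose<=5"))
  expect_equal(attr(q, "cholesterol_ratio"), c(5, 4, 3, 4.4))
  co$hdl[2] <- -1
  expect_warning(q2 <- assign_risk_groups(co), "HDL")
  expect_true(is.na(q2[2]))
  expect_equal(attr(q2, "n_excluded"), 1L)
  expect_error(assign_risk_groups(co[, 1:2]), "fasting_glucose")
})

test_that("risk-stratified summaries restrict to the plain group summary", {
  set.seed(73)
  n <- 200
  pred <- make_prediction_set(y = sample(20:80, n, TRUE),
                              y_hat = sample(20:80, n, TRUE) + rnorm(n),
                              age = sample(20:80, n, TRUE),
                              sex = rep_len(0:1, n),
                              smoking = rep_len(c(0L, 1L), n))
  pred$age <- pred$y
  risk <- factor(rep("ratio>4_glucose>5", n),
                 levels = c("ratio>4_glucose>5", "ratio<=4_glucose<=5"))
  rtab <- risk_group_aging_summary(pred, risk)
  gtab <- group_aging_summary(pred)
  filled <- rtab[rtab$quadrant == "ratio>4_glucose>5", ]
  merged <- merge(filled, gtab, by = c("age_group", "sex", "smoking"))
  expect_equal(merged$mean_ratio.x, merged$mean_ratio.y, tolerance = 1e-12)
  expect_equal(merged$n.x, merged$n.y)
  empty <- rtab[rtab$quadrant == "ratio<=4_glucose<=5", ]
  expect_true(all(empty$n == 0))
})

test_that("smokers read older in every populated risk quadrant below the plateau", {
  co <- generate_cohort(generator_config(n_subjects = 4000, seed = 79))
  core <- marker_names(co)[colSums(is.na(co[marker_names(co)])) == 0]
  ns <- co[co$smoking == 0, ]
  spec <- split_spec(seed = 11)
  parts <- split_train_test(ns, spec)
  clock <- train_age_model(parts$train, c(core, "sex"), spec,
                           arch_config("linear"))
  held <- rbind(parts$test, co[co$smoking == 1, ])
  pred <- predict_age(clock, held)
  # a -4 SD draw can push a synthetic HDL below zero; the counted-exclusion
  # path is what we want here
  risk <- suppressWarnings(assign_risk_groups(held))
  rtab <- risk_group_aging_summary(pred, risk)
  young <- rtab[rtab$age_group %in% c("<31", "31-40", "41-50"), ]
  for (qd in levels(risk)) for (sx in 0:1) for (ag in unique(young$age_group)) {
    cell <- young[young$quadrant == qd & young$sex == sx &
                    young$age_group == ag, ]
    if (all(cell$n[cell$smoking == 1] >= 10) &&
        all(cell$n[cell$smoking == 0] >= 10))
      expect_gt(cell$mean_ratio[cell$smoking == 1],
                cell$mean_ratio[cell$smoking == 0])
  }
})

test_that("biweight midcorrelation matches the textbook oracle and resists outliers", {
  x <- c(2.1, 3.4, 1.2, 5.6, 4.4, 3.3, 2.8, 6.1, 0.9, 4.0)
  y <- c(1.9, 3.1, 1.5, 5.2, 4.9, 3.0, 2.5, 6.4, 1.2, 3.6)
  expect_equal(biweight_midcorrelation(x, y), oracle_bicor(x, y),
               tolerance = 1e-10)
  expect_equal(biweight_midcorrelation(x, x), 1, tolerance = 1e-12)
  expect_equal(biweight_midcorrelation(x, -x), -1, tolerance = 1e-12)
  set.seed(83)
  for (rep in 1:30) {
    a <- rnorm(25); b <- 0.6 * a + rnorm(25, 0, 0.5)
    expect_equal(biweight_midcorrelation(a, b), oracle_bicor(a, b),
                 tolerance = 1e-10)
    expect_lte(abs(biweight_midcorrelation(a, b)), 1)
  }
  # one gross outlier: bicor moves < 0.05 where Pearson moves > 0.2
  set.seed(89)
  a <- rnorm(40); b <- 0.9 * a + rnorm(40, 0, 0.3)
  a2 <- c(a, 20); b2 <- c(b, -20)
  expect_lt(abs(biweight_midcorrelation(a2, b2) -
                  biweight_midcorrelation(a, b)), 0.05)
  expect_gt(abs(stats::cor(a2, b2) - stats::cor(a, b)), 0.2)
  expect_error(biweight_midcorrelation(c(1, 1, 1, 2), c(1, 2, 3, 4)),
               "dispersion")
  expect_error(biweight_midcorrelation(1:2, 1:2), ">= 3")
})
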