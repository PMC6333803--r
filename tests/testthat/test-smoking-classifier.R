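test_that("classification metrics match hand arithmetic and the loop oracle", {
  # tp=3, fp=1, fn=1, tn=5
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  got <- classification_metrics(truth, pred)
  expect_equal(got$tp, 3); expect_equal(got$fp, 1)
  expect_equal(got$fn, 1); expect_equal(got$tn, 5)
  expect_equal(got$precision, 0.75)
  expect_equal(got$recall, 0.75)
  expect_equal(got$f1, 0.75)
  expect_equal(got$accuracy, 0.8)
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    t <- stats::rbinom(n, 1, 0.4); p <- stats::rbinom(n, 1, 0.5)
    g <- classification_metrics(t, p)
    o <- oracle_classification(t, p)
    for (k in names(o)) expect_equal(g[[k]], o[[k]], tolerance = 1e-10)
  }
})

test_that("degenerate label patterns give exact or undefined values as specified", {
  perfect <- classification_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  none_pred <- classification_metrics(c(1, 1, 0), c(0, 0, 0))
  expect_equal(none_pred$recall, 0)
  expect_true(is.na(none_pred$precision))
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
  expect_error(classification_metrics(c(1, 2), c(0, 1)), "binary")
})

test_that("F1 is the harmonic mean of reported precision and recall", {
  set.seed(43)
  for (rep in 1:50) {
    n <- sample(4:60, 1)
    g <- classification_metrics(stats::rbinom(n, 1, 0.5),
                                stats::rbinom(n, 1, 0.5))
    if (!is.na(g$precision) && !is.na(g$recall) && g$precision + g$recall > 0)
      expect_equal(g$f1,
                   2 * g$precision * g$recall / (g$precision + g$recall),
                   tolerance = 1e-12)
  }
})

test_that("age-binned confusion counts sum to the global confusion", {
  set.seed(47)
  n <- 500
  truth <- stats::rbinom(n, 1, 0.33)
  pred <- stats::rbinom(n, 1, 0.4)
  age <- sample(18:92, n, TRUE)
  conf <- confusion_by_age_group(truth, pred, age)
  glob <- classification_metrics(truth, pred)
  expect_equal(sum(conf$tp), glob$tp)
  expect_equal(sum(conf$fp), glob$fp)
  expect_equal(sum(conf$fn), glob$fn)
  expect_equal(sum(conf$tn), glob$tn)
  expect_equal(sum(conf$n), n)
  # a single bin covering all ages equals the global confusion matrix
  one <- confusion_by_age_group(truth, pred, age,
                                bins = list(breaks = c(-Inf, Inf),
                                            labels = "all"))
  expect_equal(one$tp, glob$tp)
  expect_equal(one$error_rate, (glob$fp + glob$fn) / n)
  # perfect classifier: zero off-diagonals everywhere
  pconf <- confusion_by_age_group(truth, truth, age)
  expect_true(all(pconf$fp == 0) && all(pconf$fn == 0))
  # empty bins are reported, not dropped
  young_only <- confusion_by_age_group(truth[age < 31], pred[age < 31],
                                       age[age < 31])
  expect_equal(nrow(young_only), 6L)
  expect_equal(young_only$n[young_only$age_group == ">70"], 0L)
  # row percentages sum to 100 within rounding where defined
  ok <- conf$n > 0 & (conf$tp + conf$fn) > 0
  expect_equal(conf$pct_tp[ok] + conf$pct_fn[ok], rep(100, sum(ok)))
  expect_error(confusion_by_age_group(truth, pred, replace(age, 1, NA)),
               "ages")
})

test_that("the smoking column is refused as an input feature", {
  co <- toy_cohort(200, seed = 51)
  expect_error(train_smoking_model(co, c("signal", "smoking"), split_spec()),
               "leak")
})

test_that("same seed gives identical predictions; thresholds trade recall", {
  co <- generate_cohort(generator_config(
    n_subjects = 1200, seed = 53,
    panel = default_marker_panel(smoking_offset_sd = 1)))
  feats <- c("hdl", "hemoglobin", "rdw", "mcv", "sex")
  spec <- split_spec(seed = 8, train_population = "all_with_smoking_feature")
  parts <- split_train_test(co, spec)
  arch <- arch_config(hidden_widths = 16, n_ensemble = 1)
  m1 <- train_smoking_model(parts$train, feats, spec, arch)
  m2 <- train_smoking_model(parts$train, feats, spec, arch)
  p1 <- predict(m1, parts$test, type = "prob")
  expect_identical(p1, predict(m2, parts$test, type = "prob"))
  # raising the decision threshold never increases recall
  recalls <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    classification_metrics(parts$test$smoking,
                           as.integer(p1 > th))$recall, numeric(1))
  expect_true(all(diff(recalls) <= 0))
})

test_that("without planted smoking signal, accuracy sits at the majority rate", {
  cfg <- generator_config(
    n_subjects = 2000, seed = 59,
    acceleration_factor = c(female = 1, male = 1),
    panel = default_marker_panel(smoking_offset_sd = 0))
  co <- generate_cohort(cfg)
  core <- marker_names(co)[colSums(is.na(co[marker_names(co)])) == 0]
  spec <- split_spec(seed = 9, train_population = "all_with_smoking_feature")
  parts <- split_train_test(co, spec)
  clf <- train_smoking_model(parts$train, c(core, "sex"), spec,
                             arch_config(hidden_widths = 16, n_ensemble = 1))
  rep <- classification_metrics(parts$test$smoking,
                                predict(clf, parts$test, type = "class"))
  majority <- max(mean(parts$test$smoking), 1 - mean(parts$test$smoking))
  expect_lt(abs(rep$accuracy - majority), 0.03)
})
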