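test_that("train/test split is disjoint, exhaustive, 80/20 and seed-stable", {
  co <- toy_cohort(1000, seed = 5)
  spec <- split_spec(seed = 3)
  parts <- split_train_test(co, spec)
  expect_equal(nrow(parts$train), 800L)
  expect_equal(nrow(parts$test), 200L)
  expect_length(intersect(parts$train$id, parts$test$id), 0)
  expect_setequal(c(parts$train$id, parts$test$id), co$id)
  again <- split_train_test(co, spec)
  expect_identical(parts$train$id, again$train$id)
  # stratification: every decade appears in both sides close to 80/20
  dec <- co$age %/% 10L
  for (d in unique(dec)) {
    in_train <- sum(parts$train$age %/% 10L == d)
    expect_lte(abs(in_train - 0.8 * sum(dec == d)), 1)
  }
  expect_error(split_spec(train_fraction = 1), "train_fraction")
  expect_error(split_spec(train_fraction = 0), "train_fraction")
  expect_error(split_train_test(co[1:5, ], spec), "n >= 10")
})

test_that("marker normalization is train-anchored and leak-free", {
  train <- data.frame(id = as.character(1:4), age = 30:33, sex = 0L,
                      smoking = 0L, m = c(8, 9, 11, 12))
  apply_to <- train
  apply_to$m <- 14
  out <- normalize_markers(train, apply_to, "m")
  expect_equal(out$m, rep((14 - 10) / stats::sd(c(8, 9, 11, 12)), 4))
  self <- normalize_markers(train, train, "m")
  expect_equal(mean(self$m), 0)
  expect_equal(stats::sd(self$m), 1)
  train$m <- 5
  expect_error(normalize_markers(train, train, "m"), "zero-SD")
})

test_that("regression metrics match loop-based oracles on random instances", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(3:40, 1)
    y <- rnorm(n, 50, 15)
    y_hat <- y + rnorm(n, 0, sample(1:10, 1))
    eps <- runif(1, 1, 15)
    got <- regression_metrics(make_prediction_set(y, y_hat), epsilon = eps)
    expect_equal(got$r, oracle_pearson(y, y_hat), tolerance = 1e-10)
    expect_equal(got$r_squared, oracle_r2(y, y_hat), tolerance = 1e-10)
    expect_equal(got$mae, oracle_mae(y, y_hat), tolerance = 1e-10)
    expect_equal(got$epsilon_accuracy, oracle_eps_accuracy(y, y_hat, eps),
                 tolerance = 1e-10)
  }
})

test_that("metric identities and edge cases behave as specified", {
  y <- c(40, 50, 60)
  ident <- regression_metrics(make_prediction_set(y, y))
  expect_equal(ident$r, 1)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$mae, 0)
  expect_equal(ident$epsilon_accuracy, 1)
  # boundary-inclusive epsilon window: 55 vs 50 at eps = 5 counts as correct
  b <- regression_metrics(make_prediction_set(c(50, 50), c(55, 45)),
                          epsilon = 5)
  expect_equal(b$epsilon_accuracy, 1)
  # hand-computed pair
  h <- regression_metrics(make_prediction_set(c(50, 60), c(55, 55)),
                          epsilon = 5)
  expect_equal(h$mae, 5)
  expect_equal(h$epsilon_accuracy, 1)
  # zero variance in y: r and R2 undefined, not numbers
  z <- regression_metrics(make_prediction_set(c(50, 50), c(48, 52)))
  expect_true(is.na(z$r) && is.na(z$r_squared))
  expect_error(regression_metrics(make_prediction_set(1, 1)), ">= 2")
})

test_that("epsilon-accuracy never decreases as epsilon grows; R2 bounded by one", {
  set.seed(23)
  pred <- make_prediction_set(rnorm(60, 50, 10), rnorm(60, 50, 12))
  accs <- vapply(c(1, 2, 5, 10, 20, 40), function(e)
    regression_metrics(pred, e)$epsilon_accuracy, numeric(1))
  expect_true(all(diff(accs) >= 0))
  for (rep in 1:20) {
    y <- rnorm(20, 50, 10)
    expect_lte(regression_metrics(make_prediction_set(y, rnorm(20, 50, 10)))$r_squared, 1)
  }
})

test_that("the contamination guard separates the two training designs", {
  co <- toy_cohort(300, seed = 9)
  ns <- co[co$smoking == 0, ]
  spec_ns <- split_spec(seed = 1, train_population = "nonsmokers_only")
  expect_error(train_age_model(ns, c("signal", "smoking"), spec_ns),
               "nonsmokers_only")
  expect_error(train_age_model(co, "signal", spec_ns), "contains smokers")
  spec_all <- split_spec(seed = 1,
                         train_population = "all_with_smoking_feature")
  m <- train_age_model(co, c("signal", "smoking"), spec_all,
                       arch_config("linear"))
  expect_s3_class(m, "age_clock")
  co_na <- ns; co_na$signal[3] <- NA
  expect_error(train_age_model(co_na, "signal", spec_ns), "incomplete")
})

test_that("a noiseless linear age signal is learned to under a year of MAE", {
  set.seed(31)
  n <- 2000
  co <- data.frame(id = as.character(1:n), age = sample(20:80, n, TRUE),
                   sex = rep_len(0:1, n), smoking = 0L)
  co$m1 <- 2 * co$age + 5
  spec <- split_spec(seed = 2)
  parts <- split_train_test(co, spec)
  clock <- train_age_model(parts$train, "m1", spec,
                           arch_config(hidden_widths = 32))
  rep <- regression_metrics(predict_age(clock, parts$test))
  expect_lt(rep$mae, 1)
})

test_that("pure-noise features do no better than predicting the mean age", {
  set.seed(37)
  n <- 2000
  co <- data.frame(id = as.character(1:n), age = sample(20:80, n, TRUE),
                   sex = rep_len(0:1, n), smoking = 0L, m1 = rnorm(n))
  spec <- split_spec(seed = 3)
  parts <- split_train_test(co, spec)
  clock <- train_age_model(parts$train, "m1", spec,
                           arch_config(hidden_widths = 16))
  rep <- regression_metrics(predict_age(clock, parts$test))
  const_mae <- mean(abs(mean(parts$train$age) - parts$test$age))
  expect_lt(abs(rep$mae - const_mae) / const_mae, 0.10)
})

test_that("predictions carry metadata, permute with rows, and need all features", {
  co <- toy_cohort(300, seed = 13)
  ns <- co[co$smoking == 0, ]
  spec <- split_spec(seed = 4)
  clock <- train_age_model(ns, c("signal", "noise1"), spec,
                           arch_config("linear"))
  pred <- predict_age(clock, co)
  expect_named(pred, c("y", "y_hat", "age", "sex", "smoking"))
  expect_equal(pred$y, co$age)
  perm <- sample(nrow(co))
  pred2 <- predict_age(clock, co[perm, ])
  expect_equal(pred2$y_hat, pred$y_hat[perm], tolerance = 1e-12)
  expect_error(predict_age(clock, co[, setdiff(names(co), "noise1")]),
               "noise1")
})

test_that("training never touches held-out labels", {
  co <- toy_cohort(400, seed = 19)
  ns <- co[co$smoking == 0, ]
  spec <- split_spec(seed = 6)
  parts <- split_train_test(ns, spec)
  clock <- train_age_model(parts$train, "signal", spec, arch_config("linear"))
  shuffled <- parts$test
  shuffled$age <- sample(shuffled$age)
  p1 <- predict_age(clock, parts$test)$y_hat
  clock2 <- train_age_model(parts$train, "signal", spec,
                            arch_config("linear"))
  p2 <- predict_age(clock2, shuffled)$y_hat
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("smokers read older than their years below the plateau", {
  co <- generate_cohort(generator_config(n_subjects = 3000, seed = 25))
  core <- marker_names(co)[colSums(is.na(co[marker_names(co)])) == 0]
  ns <- co[co$smoking == 0, ]
  spec <- split_spec(seed = 7)
  parts <- split_train_test(ns, spec)
  clock <- train_age_model(parts$train, c(core, "sex"), spec,
                           arch_config("linear"))
  pred <- predict_age(clock, co[co$smoking == 1, ])
  young <- pred$age < 55
  expect_gt(mean(pred$y_hat[young] - pred$y[young]), 5)
  # and the default synthetic cohort supports a strong clock
  rep <- regression_metrics(predict_age(clock, parts$test))
  expect_gt(rep$r_squared, 0.5)
})
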