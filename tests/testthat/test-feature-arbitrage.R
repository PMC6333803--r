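fake_record <- function(markers, mae, q) {
  structure(list(space = structure(list(markers = markers,
                                        eligible_n = 100L),
                                   class = "feature_space"),
                 mae = mae, importance = q, n_trees = 80),
            class = "arbitrage_record")
}

test_that("arbitrage FI equals the per-model importance over MAE, summed", {
  r1 <- fake_record("a", mae = 2, q = c(a = 0.5))
  expect_equal(arbitrage_fi(list(r1))$fi, 0.25)
  r2 <- fake_record("a", mae = 3, q = c(a = 0.3))
  r3 <- fake_record("a", mae = 4, q = c(a = 0.2))
  expect_equal(arbitrage_fi(list(r2, r3))$fi, 0.3 / 3 + 0.2 / 4)
  r0 <- fake_record(c("a", "b"), mae = 5, q = c(a = 0, b = 0))
  expect_equal(arbitrage_fi(list(r0))$fi, c(0, 0))
})

test_that("arbitrage FI matches the brute-force oracle on random record sets", {
  set.seed(42)
  for (rep in 1:100) {
    n_rec <- sample(1:3, 1)
    markers <- letters[1:sample(2:5, 1)]
    recs <- lapply(seq_len(n_rec), function(i) {
      mk <- sample(markers, sample(seq_along(markers), 1))
      fake_record(mk, mae = runif(1, 0.5, 10),
                  q = stats::setNames(rnorm(length(mk)), mk))
    })
    got <- arbitrage_fi(recs)
    want <- oracle_arbitrage_fi(recs)
    expect_equal(stats::setNames(got$fi, got$marker)[names(want)], want,
                 tolerance = 1e-10)
  }
})

test_that("FI is additive over record lists and scales inversely with MAE", {
  set.seed(7)
  mk <- c("a", "b", "c")
  recs <- lapply(1:6, function(i)
    fake_record(mk, mae = runif(1, 1, 5),
                q = stats::setNames(rnorm(3), mk)))
  whole <- arbitrage_fi(recs)
  p1 <- arbitrage_fi(recs[1:2]); p2 <- arbitrage_fi(recs[3:6])
  joined <- stats::setNames(p1$fi, p1$marker)[whole$marker] +
    stats::setNames(p2$fi, p2$marker)[whole$marker]
  expect_equal(whole$fi, unname(joined), tolerance = 1e-12)
  scaled <- lapply(recs, function(r) { r$mae <- r$mae * 2.5; r })
  expect_equal(arbitrage_fi(scaled)$fi, whole$fi / 2.5, tolerance = 1e-12)
})

test_that("FI errors on zero MAE and on missing importance entries", {
  expect_error(arbitrage_fi(list(fake_record("a", 0, c(a = 1)))), "MAE = 0")
  expect_error(arbitrage_fi(list(fake_record(c("a", "b"), 2, c(a = 1)))),
               "lacks importance")
  expect_error(arbitrage_fi(list()), "1 record")
})

test_that("feature spaces count eligible complete cases", {
  co <- toy_cohort(100)
  expect_equal(feature_space(c("signal", "noise1"), co)$eligible_n, 100L)
  co$noise1[1:30] <- NA
  expect_equal(feature_space(c("signal", "noise1"), co)$eligible_n, 70L)
  expect_error(feature_space(character(0), co), "non-empty")
  expect_error(feature_space(c("signal", "absent"), co), "absent")
})

test_that("enumeration is exhaustive for tiny candidate sets and errors beyond", {
  co <- toy_cohort(100)
  sp <- enumerate_feature_spaces(co, c("noise1", "noise2"), n_spaces = 3,
                                 min_eligible = 1, seed = 1)
  keys <- sort(vapply(sp, function(s) paste(sort(s$markers), collapse = "+"),
                      character(1)))
  expect_equal(keys, c("noise1", "noise1+noise2", "noise2"))
  expect_error(enumerate_feature_spaces(co, c("noise1", "noise2"),
                                        n_spaces = 4, min_eligible = 1),
               "3 distinct")
})

test_that("enumeration yields the requested number of distinct trainable spaces", {
  co <- generate_cohort(generator_config(n_subjects = 300, seed = 2))
  sp <- enumerate_feature_spaces(co, n_spaces = 40, min_eligible = 50,
                                 seed = 4)
  expect_length(sp, 40)
  keys <- vapply(sp, function(s) paste(sort(s$markers), collapse = "+"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(vapply(sp, function(s) s$eligible_n, integer(1)) >= 50))
  # no missingness: every space covers all subjects
  co2 <- toy_cohort(120)
  sp2 <- enumerate_feature_spaces(co2, c("signal", "noise1", "noise2"),
                                  n_spaces = 7, min_eligible = 1, seed = 1)
  expect_true(all(vapply(sp2, function(s) s$eligible_n, integer(1)) == 120L))
})

test_that("ensemble records per space hold a held-out MAE and per-marker importance", {
  co <- toy_cohort(300, seed = 3)
  sp <- list(feature_space(c("signal", "noise1"), co),
             feature_space(c("signal", "noise2"), co))
  recs <- fit_arbitrage_ensemble(co, sp, n_trees = 25, seed = 6)
  expect_length(recs, 2)
  for (r in recs) {
    expect_gt(r$mae, 0)
    expect_setequal(names(r$importance), r$space$markers)
    # the age-linked marker is important in every model containing it
    expect_gt(r$importance[["signal"]], 0)
  }
  # undersized space is skipped with a warning, not silently
  tiny <- co[1:30, ]
  expect_warning(
    recs2 <- fit_arbitrage_ensemble(tiny, list(feature_space("signal", tiny)),
                                    n_trees = 10, seed = 1),
    "skipped")
  expect_length(recs2, 0)
  expect_length(attr(recs2, "skipped"), 1)
})

test_that("a pure-noise marker gets near-zero mean-decrease-accuracy", {
  co <- toy_cohort(2000, seed = 8)
  sp <- list(feature_space(c("signal", "noise1"), co))
  recs <- fit_arbitrage_ensemble(co, sp, n_trees = 40, seed = 2)
  expect_lt(abs(recs[[1]]$importance[["noise1"]]), 0.05 * recs[[1]]$mae + 0.3)
  expect_gt(recs[[1]]$importance[["signal"]], 1)
})

test_that("the planted age-linked marker ranks first by FI", {
  co <- toy_cohort(2000, seed = 10)
  sp <- enumerate_feature_spaces(co, c("signal", "noise1", "noise2"),
                                 n_spaces = 7, min_eligible = 50, seed = 3)
  recs <- fit_arbitrage_ensemble(co, sp, n_trees = 30, seed = 5)
  fi <- arbitrage_fi(recs)
  expect_equal(fi$marker[1], "signal")
})

test_that("feature-set selection finds knees and breaks ties by name", {
  # structured missingness: complete prefix, then two drops, then a cliff
  set.seed(12)
  n <- 1000
  co <- data.frame(id = as.character(1:n), age = sample(20:80, n, TRUE),
                   sex = rep_len(0:1, n), smoking = 0L)
  for (i in 1:8) co[[paste0("f", i)]] <- rnorm(n)
  blockA <- sample(n, 120)                       # 12%
  blockB <- sample(setdiff(1:n, blockA), 130)    # 13%, disjoint
  co$f5[blockA] <- NA
  co$f6[blockB] <- NA
  co$f7[blockB] <- NA                            # co-missing with f6
  co$f8[sample(n, 400)] <- NA                    # 40% cliff
  scores <- data.frame(marker = paste0("f", 1:8), fi = seq(8, 1))
  sets <- select_feature_sets(scores, co, n_sets = 3)
  expect_equal(vapply(sets, function(s) length(s$markers), integer(1)),
               c(4L, 5L, 7L))
  # nested prefixes
  expect_true(all(sets[[1]]$markers %in% sets[[2]]$markers))
  expect_true(all(sets[[2]]$markers %in% sets[[3]]$markers))
  # equal FI resolves by ascending marker name, independent of input order
  s2 <- data.frame(marker = c("b", "a"), fi = c(1, 1))
  co2 <- toy_cohort(50)
  co2$a <- rnorm(50); co2$b <- rnorm(50)
  sel <- select_feature_sets(s2, co2, n_sets = 1)
  expect_equal(sel[[1]]$markers[1], "a")
  # fully observed markers: one maximal set dominates, prefixes nested
  s3 <- data.frame(marker = c("signal", "noise1", "noise2"), fi = c(3, 2, 1))
  sets3 <- select_feature_sets(s3, co2, n_sets = 2)
  expect_equal(length(sets3[[length(sets3)]]$markers), 3L)
  expect_error(select_feature_sets(data.frame(), co2), "empty")
})
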