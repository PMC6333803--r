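# Independent brute-force oracles, written as explicit loops so they share no
# code path with the package implementations they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / (sqrt(dx) * sqrt(dy))
}

oracle_r2 <- function(y, y_hat) {
  n <- length(y)
  my <- sum(y) / n
  ss_res <- 0; ss_tot <- 0
  for (i in seq_len(n)) {
    ss_res <- ss_res + (y_hat[i] - y[i])^2
    ss_tot <- ss_tot + (y[i] - my)^2
  }
  1 - ss_res / ss_tot
}

oracle_mae <- function(y, y_hat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y_hat[i] - y[i])
  s / length(y)
}

oracle_eps_accuracy <- function(y, y_hat, eps) {
  hits <- 0
  for (i in seq_along(y))
    if (y_hat[i] >= y[i] - eps && y_hat[i] <= y[i] + eps) hits <- hits + 1
  hits / length(y)
}

oracle_classification <- function(truth, pred) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(accuracy = (tp + tn) / length(truth), precision = prec, recall = rec,
       f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
         2 * prec * rec / (prec + rec) else NA_real_)
}

oracle_log2_ratio <- function(y, y_hat) {
  out <- numeric(length(y))
  for (i in seq_along(y)) out[i] <- log(y_hat[i] / y[i], base = 2)
  out
}

oracle_arbitrage_fi <- function(records) {
  fi <- list()
  for (rec in records) {
    for (m in rec$space$markers) {
      cur <- if (is.null(fi[[m]])) 0 else fi[[m]]
      fi[[m]] <- cur + rec$importance[[m]] / rec$mae
    }
  }
  unlist(fi)
}

# Textbook biweight midcorrelation, per-element loops.
oracle_bicor <- function(x, y) {
  one <- function(v) {
    n <- length(v)
    sv <- sort(v)
    med <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
    ad <- sort(abs(v - med))
    mad <- if (n %% 2 == 1) ad[(n + 1) / 2] else (ad[n / 2] + ad[n / 2 + 1]) / 2
    out <- numeric(n)
    for (i in seq_len(n)) {
      u <- (v[i] - med) / (9 * mad)
      w <- if (abs(u) < 1) (1 - u^2)^2 else 0
      out[i] <- (v[i] - med) * w
    }
    out
  }
  a <- one(x); b <- one(y)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    da <- da + a[i]^2
    db <- db + b[i]^2
  }
  num / (sqrt(da) * sqrt(db))
}

# A minimal complete cohort with a single strong age-linked marker plus noise
# markers; used across module tests.
toy_cohort <- function(n = 400, seed = 1, age_sd_noise = 3) {
  set.seed(seed)
  age <- sample(20:80, n, replace = TRUE)
  data.frame(id = sprintf("T%04d", seq_len(n)), age = age,
             sex = rep_len(c(0L, 1L), n), smoking = rep_len(c(0L, 0L, 1L), n),
             signal = age + rnorm(n, 0, age_sd_noise),
             noise1 = rnorm(n), noise2 = rnorm(n),
             stringsAsFactors = FALSE)
}

make_prediction_set <- function(y, y_hat, age = y, sex = 0L, smoking = 0L) {
  out <- data.frame(y = y, y_hat = y_hat, age = age,
                    sex = rep_len(sex, length(y)),
                    smoking = rep_len(smoking, length(y)))
  class(out) <- c("prediction_set", "data.frame")
  out
}
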