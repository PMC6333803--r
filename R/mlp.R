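# Small fully connected network: two hidden ReLU layers, inverted dropout,
# Adam on the full batch, MAE loss for regression / binary cross-entropy for
# classification, early stopping on a held-back validation slice. Inputs are
# expected pre-standardized by the caller. Deterministic given `seed`.

relu <- function(z) (z > 0) * z
sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(p, hidden, seed) {
  set.seed(seed)
  dims <- c(p, hidden, 1L)
  lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = matrix(stats::rnorm(dims[i] * dims[i + 1L],
                                 sd = sqrt(2 / dims[i])),
                    dims[i], dims[i + 1L]),
         b = rep(0, dims[i + 1L]))
  })
}

mlp_forward <- function(params, x, dropout = 0, train = FALSE) {
  a <- x
  L <- length(params)
  acts <- vector("list", L)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    z <- a %*% params[[l]]$W
    z <- sweep(z, 2, params[[l]]$b, "+")
    if (l < L) {
      a <- relu(z)
      if (train && dropout > 0) {
        m <- matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                    nrow(a), ncol(a))
        a <- a * m
        masks[[l]] <- m
      }
    } else a <- z
    acts[[l]] <- a
  }
  list(out = as.numeric(a), acts = acts, masks = masks)
}

mlp_loss <- function(params, x, y, task) {
  out <- mlp_forward(params, x)$out
  if (task == "regression") mean(abs(out - y))
  else {
    p <- pmin(pmax(sigmoid(out), 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

mlp_fit <- function(x, y, task = c("regression", "classification"),
                    hidden = c(32, 32), dropout = 0.05, epochs = 400,
                    lr = 0.01, patience = 40, val_fraction = 0.15,
                    batch_size = 256, seed = 1L) {
  task <- match.arg(task)
  x <- as.matrix(x)
  n <- nrow(x)
  set.seed(seed)
  n_val <- if (val_fraction > 0 && n >= 40) round(val_fraction * n) else 0L
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  xt <- if (n_val) x[-val_idx, , drop = FALSE] else x
  yt <- if (n_val) y[-val_idx] else y
  xv <- if (n_val) x[val_idx, , drop = FALSE] else NULL
  yv <- if (n_val) y[val_idx] else NULL

  params <- mlp_init(ncol(x), hidden, seed)
  L <- length(params)
  adam_m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, params = params, epoch = 0L)
  stale <- 0L
  nt <- nrow(xt)
  step <- 0L

  for (ep in seq_len(epochs)) {
    perm <- sample.int(nt)
    starts <- seq(1L, nt, by = batch_size)
    for (s in starts) {
      rows <- perm[s:min(s + batch_size - 1L, nt)]
      xb <- xt[rows, , drop = FALSE]
      yb <- yt[rows]
      nb <- length(rows)
      fw <- mlp_forward(params, xb, dropout = dropout, train = TRUE)
      out <- fw$out
      delta <- if (task == "regression") matrix(sign(out - yb) / nb, ncol = 1)
               else matrix((sigmoid(out) - yb) / nb, ncol = 1)
      grads <- vector("list", L)
      for (l in rev(seq_len(L))) {
        a_prev <- if (l == 1) xb else fw$acts[[l - 1]]
        grads[[l]] <- list(W = crossprod(a_prev, delta),
                           b = colSums(delta))
        if (l > 1) {
          delta <- delta %*% t(params[[l]]$W)
          delta <- delta * (fw$acts[[l - 1]] > 0)
          if (!is.null(fw$masks[[l - 1]])) delta <- delta * fw$masks[[l - 1]]
        }
      }
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (l in seq_len(L)) {
        for (nm in c("W", "b")) {
          adam_m[[l]][[nm]] <- b1 * adam_m[[l]][[nm]] +
            (1 - b1) * grads[[l]][[nm]]
          adam_v[[l]][[nm]] <- b2 * adam_v[[l]][[nm]] +
            (1 - b2) * grads[[l]][[nm]]^2
          params[[l]][[nm]] <- params[[l]][[nm]] -
            lr * corr * adam_m[[l]][[nm]] / (sqrt(adam_v[[l]][[nm]]) + eps)
        }
      }
    }
    if (n_val > 0) {
      vloss <- mlp_loss(params, xv, yv, task)
      if (vloss < best$loss - 1e-5) {
        best <- list(loss = vloss, params = params, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  final <- if (n_val > 0) best$params else params
  structure(list(params = final, task = task, hidden = hidden,
                 dropout = dropout, seed = seed,
                 val_loss = if (n_val > 0) best$loss else NA_real_,
                 stopped_epoch = if (n_val > 0) best$epoch else epochs),
            class = "bloodclock_mlp")
}

predict_mlp <- function(model, x) {
  out <- mlp_forward(model$params, as.matrix(x))$out
  if (model$task == "classification") sigmoid(out) else out
}
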