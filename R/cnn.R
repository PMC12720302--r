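# Lightweight 1-D CNN for 21-component PCA score vectors, implemented with
# plain matrix algebra (BLAS-backed). Layer stack, in order:
#   Conv1D(64, k=3) -> BatchNorm -> MaxPool(2) ->
#   Conv1D(128, k=3) -> BatchNorm -> MaxPool(2) ->
#   Flatten -> Dense(128, ReLU) -> Dropout(0.5) -> Dense(1, sigmoid)
# Valid padding and floor pooling give the length chain 21->19->9->7->3 and
# a flattened width of 384; learnable parameters total 74,753 (conv 256 +
# BN 128 + conv 24,704 + BN 256 + dense 49,280 + dense 129). The conv
# stages are linear (no activation is specified for them); nonlinearity
# enters through max-pooling, the ReLU dense layer and the sigmoid output.

BN_EPS <- 1e-3
# Running-statistics momentum. With a 162-subject training split there are
# only ~3 batches per epoch, so a slow schedule would leave the inference
# statistics far from the activation distribution for most of training;
# 0.9 converges within the first few epochs.
BN_MOMENTUM <- 0.9

#' The fixed CNN architecture specification
#'
#' @param input_len Input sequence length (default 21 principal components).
#' @return A tibble describing the layer stack with parameter counts.
#' @export
#' @examples
#' sum(architecture_spec()$params)  # 74753
architecture_spec <- function(input_len = 21) {
  l1 <- input_len - 2          # conv k=3, valid
  p1 <- l1 %/% 2               # pool 2, floor
  l2 <- p1 - 2
  p2 <- l2 %/% 2
  tibble(
    layer = c("conv1d_1", "batchnorm_1", "maxpool_1", "conv1d_2",
              "batchnorm_2", "maxpool_2", "flatten", "dense_1",
              "dropout", "dense_2"),
    spec = c("64 filters, kernel=3", "-", "pool size=2",
             "128 filters, kernel=3", "-", "pool size=2", "-",
             "128 neurons, ReLU", "rate=0.5", "1 neuron, sigmoid"),
    output_len = c(l1, l1, p1, l2, l2, p2, p2 * 128, 128, 128, 1),
    params = c(3 * 1 * 64 + 64, 2 * 64, 0, 3 * 64 * 128 + 128, 2 * 128, 0,
               0, p2 * 128 * 128 + 128, 0, 128 + 1)
  )
}

#' Build an untrained CNN
#'
#' Glorot-uniform weight initialization (seeded), zero biases, unit
#' batch-norm scales.
#'
#' @param input_len Input length; must support two conv(k=3)/pool(2) stages
#'   (>= 11).
#' @param seed Integer seed for the initialization.
#' @return An `eeg_cnn` model object.
#' @export
#' @examples
#' m <- build_cnn(21, seed = 1)
#' cnn_n_params(m)
build_cnn <- function(input_len = 21, seed = 1) {
  if (((input_len - 2) %/% 2 - 2) %/% 2 < 1 || input_len < 11)
    abort(sprintf(
      "input_len = %d cannot pass two conv(k=3)/pool(2) stages; need >= 11",
      input_len))
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  l1 <- input_len - 2; p1 <- l1 %/% 2; l2 <- p1 - 2; p2 <- l2 %/% 2
  params <- with_local_seed(seed, list(
    W1 = glorot(3, 64, 3, 3 * 64), b1 = numeric(64),
    g1 = rep(1, 64), be1 = numeric(64),
    W2 = glorot(192, 128, 3 * 64, 3 * 128), b2 = numeric(128),
    g2 = rep(1, 128), be2 = numeric(128),
    W3 = glorot(p2 * 128, 128, p2 * 128, 128), b3 = numeric(128),
    # zero-initialized output head: the untrained network is the constant
    # p = 0.5, so every dependence on the input is learned, not inherited
    # from random initialization (this is what makes the attribution stage
    # reflect the fitted discriminant rather than initialization noise)
    W4 = matrix(0, 128, 1), b4 = numeric(1)
  ))
  structure(list(
    params = params,
    buffers = list(rm1 = numeric(64), rv1 = rep(1, 64),
                   rm2 = numeric(128), rv2 = rep(1, 128)),
    input_len = input_len,
    dims = list(l1 = l1, p1 = p1, l2 = l2, p2 = p2),
    arch = architecture_spec(input_len),
    history = NULL, config = NULL
  ), class = "eeg_cnn")
}

#' Learnable parameter count
#' @param model An `eeg_cnn`.
#' @return Integer number of learnable parameters (batch-norm running
#'   statistics are buffers, not counted).
#' @export
cnn_n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- forward / backward -------------------------------------------------

bn_forward <- function(a, g, be, rm, rv, training) {
  if (training) {
    mu <- colMeans(a)
    v <- colMeans(a^2) - mu^2
  } else {
    mu <- rm; v <- rv
  }
  std <- sqrt(v + BN_EPS)
  xhat <- sweep(sweep(a, 2, mu, `-`), 2, std, `/`)
  list(out = sweep(sweep(xhat, 2, g, `*`), 2, be, `+`),
       xhat = xhat, std = std, mu = mu, v = v)
}

bn_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  dbe <- colSums(dy)
  m <- nrow(dy)
  dx <- sweep(dy, 2, g / cache$std, `*`)
  dx <- dx - matrix(colMeans(dx), m, ncol(dy), byrow = TRUE) -
    xhat * matrix(colMeans(sweep(dy, 2, g / cache$std, `*`) * xhat),
                  m, ncol(dy), byrow = TRUE)
  list(dx = dx, dg = dg, dbe = dbe)
}

# max-pool pairs (2t-1, 2t) along the position axis of an (N, L, C) array
pool_forward <- function(arr, n, l, ch) {
  np <- l %/% 2
  a <- arr[, seq(1, 2 * np - 1, by = 2), , drop = FALSE]
  b <- arr[, seq(2, 2 * np, by = 2), , drop = FALSE]
  take_a <- a >= b  # ties keep the earlier position (deterministic)
  list(out = pmax(a, b), take_a = take_a, np = np)
}

cnn_forward <- function(model, x, training = FALSE, dropout_mask = NULL) {
  p <- model$params; d <- model$dims
  n <- nrow(x)
  # conv1: (N*l1) x 64
  a1 <- matrix(p$b1, n * d$l1, 64, byrow = TRUE)
  xk <- vector("list", 3)
  for (k in 1:3) {
    xk[[k]] <- as.vector(x[, k:(d$l1 + k - 1), drop = FALSE])
    a1 <- a1 + outer(xk[[k]], p$W1[k, ])
  }
  bn1 <- bn_forward(a1, p$g1, p$be1, model$buffers$rm1, model$buffers$rv1, training)
  r1 <- pmax(bn1$out, 0)
  pl1 <- pool_forward(array(r1, c(n, d$l1, 64)), n, d$l1, 64)
  # conv2 im2col: (N*l2) x 192
  m2 <- matrix(0, n * d$l2, 192)
  for (k in 1:3) {
    m2[, ((k - 1) * 64 + 1):(k * 64)] <-
      matrix(pl1$out[, k:(d$l2 + k - 1), , drop = FALSE], n * d$l2, 64)
  }
  a2 <- sweep(m2 %*% p$W2, 2, p$b2, `+`)
  bn2 <- bn_forward(a2, p$g2, p$be2, model$buffers$rm2, model$buffers$rv2, training)
  r2 <- pmax(bn2$out, 0)
  pl2 <- pool_forward(array(r2, c(n, d$l2, 128)), n, d$l2, 128)
  f <- matrix(pl2$out, n, d$p2 * 128)
  h <- sweep(f %*% p$W3, 2, p$b3, `+`)
  hr <- pmax(h, 0)
  hd <- if (training && !is.null(dropout_mask)) hr * dropout_mask else hr
  z <- as.numeric(hd %*% p$W4 + p$b4)
  prob <- 1 / (1 + exp(-z))
  list(prob = prob, z = z, x = x, xk = xk, a1 = a1, bn1 = bn1, r1 = r1, pl1 = pl1,
       m2 = m2, bn2 = bn2, r2 = r2, pl2 = pl2, f = f, h = h, hr = hr, hd = hd, n = n)
}

# scatter pooled gradients back through argmax; dpool: (N, np, C) array
unpool <- function(dpool, take_a, n, l, ch) {
  np <- dim(dpool)[2]
  darr <- array(0, c(n, l, ch))
  darr[, seq(1, 2 * np - 1, by = 2), ] <- dpool * take_a
  darr[, seq(2, 2 * np, by = 2), ] <- dpool * !take_a
  darr
}

cnn_backward <- function(model, fw, y, w) {
  p <- model$params; d <- model$dims; n <- fw$n
  dz <- (fw$prob - y) * w / n
  dW4 <- crossprod(fw$hd, dz)
  db4 <- sum(dz)
  dh <- outer(dz, p$W4[, 1])
  if (!is.null(fw$dropout_mask)) dh <- dh * fw$dropout_mask
  dh <- dh * (fw$h > 0)
  dW3 <- crossprod(fw$f, dh)
  db3 <- colSums(dh)
  df <- dh %*% t(p$W3)
  dpl2 <- array(df, c(n, d$p2, 128))
  dr2 <- matrix(unpool(dpl2, fw$pl2$take_a, n, d$l2, 128), n * d$l2, 128)
  dbn2_out <- dr2 * (fw$bn2$out > 0)
  bb2 <- bn_backward(dbn2_out, fw$bn2, p$g2)
  da2 <- bb2$dx
  dW2 <- crossprod(fw$m2, da2)
  db2 <- colSums(da2)
  dm2 <- da2 %*% t(p$W2)
  dpl1 <- array(0, c(n, d$p1, 64))
  for (k in 1:3) {
    dpl1[, k:(d$l2 + k - 1), ] <- dpl1[, k:(d$l2 + k - 1), , drop = FALSE] +
      array(dm2[, ((k - 1) * 64 + 1):(k * 64)], c(n, d$l2, 64))
  }
  dr1 <- matrix(unpool(dpl1, fw$pl1$take_a, n, d$l1, 64), n * d$l1, 64)
  dbn1_out <- dr1 * (fw$bn1$out > 0)
  bb1 <- bn_backward(dbn1_out, fw$bn1, p$g1)
  da1 <- bb1$dx
  dW1 <- matrix(0, 3, 64)
  for (k in 1:3) dW1[k, ] <- crossprod(fw$xk[[k]], da1)
  db1 <- colSums(da1)
  list(W1 = dW1, b1 = db1, g1 = bb1$dg, be1 = bb1$dbe,
       W2 = dW2, b2 = db2, g2 = bb2$dg, be2 = bb2$dbe,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

weighted_bce <- function(prob, y, w) {
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  mean(w * (-y * log(p) - (1 - y) * log(1 - p)))
}

# Inference-only forward pass with batch-norm folded into the preceding
# convolution (BN in eval mode is a per-channel affine, so conv+BN collapses
# to a conv with rescaled weights). Used for prediction, where it is much
# cheaper than the training-mode graph.
cnn_infer <- function(model, x) {
  p <- model$params; b <- model$buffers; d <- model$dims
  n <- nrow(x)
  s1 <- p$g1 / sqrt(b$rv1 + BN_EPS)
  W1e <- p$W1 * matrix(s1, 3, 64, byrow = TRUE)
  b1e <- (p$b1 - b$rm1) * s1 + p$be1
  s2 <- p$g2 / sqrt(b$rv2 + BN_EPS)
  W2e <- p$W2 * matrix(s2, 192, 128, byrow = TRUE)
  b2e <- (p$b2 - b$rm2) * s2 + p$be2
  xc <- cbind(as.vector(x[, 1:d$l1]), as.vector(x[, 2:(d$l1 + 1)]),
              as.vector(x[, 3:(d$l1 + 2)]))
  a1 <- array(pmax(sweep(xc %*% W1e, 2, b1e, `+`), 0), c(n, d$l1, 64))
  p1 <- pmax(a1[, seq(1, 2 * d$p1 - 1, 2), , drop = FALSE],
             a1[, seq(2, 2 * d$p1, 2), , drop = FALSE])
  m2 <- cbind(matrix(p1[, 1:d$l2, ], n * d$l2, 64),
              matrix(p1[, 2:(d$l2 + 1), ], n * d$l2, 64),
              matrix(p1[, 3:(d$l2 + 2), ], n * d$l2, 64))
  a2 <- array(pmax(sweep(m2 %*% W2e, 2, b2e, `+`), 0), c(n, d$l2, 128))
  p2 <- pmax(a2[, seq(1, 2 * d$p2 - 1, 2), , drop = FALSE],
             a2[, seq(2, 2 * d$p2, 2), , drop = FALSE])
  h <- pmax(sweep(matrix(p2, n, d$p2 * 128) %*% p$W3, 2, p$b3, `+`), 0)
  z <- as.numeric(h %*% p$W4 + p$b4)
  1 / (1 + exp(-z))
}

#' Predict depression probabilities
#'
#' @param object A trained `eeg_cnn`.
#' @param newdata Scores matrix (samples x input_len).
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.eeg_cnn <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$input_len)
  # chunk large batches to bound memory
  n <- nrow(newdata)
  chunk <- 8192L
  if (n <= chunk) return(cnn_infer(object, newdata))
  starts <- seq(1L, n, by = chunk)
  unlist(lapply(starts, function(s) {
    e <- min(n, s + chunk - 1L)
    cnn_infer(object, newdata[s:e, , drop = FALSE])
  }))
}

#' Balanced class weights
#'
#' `weight_c = n_total / (2 * n_c)` for classes 0 and 1.
#'
#' @param labels Binary 0/1 label vector containing both classes.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
#' @examples
#' compute_class_weights(c(rep(0, 80), rep(1, 20)))
compute_class_weights <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0/1")
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 == 0 || n1 == 0) abort("both classes must be present")
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Training configuration
#'
#' The published regime: Adam with learning rate 1e-4, binary cross-entropy,
#' at most 100 epochs, batch size 64, early stopping with patience 10 on
#' validation loss (best weights restored), learning-rate reduction by
#' factor 0.2 on validation-loss plateau, balanced class weights, 70/30
#' stratified train/test split and 5 stratified CV folds.
#'
#' @param learning_rate,max_epochs,batch_size,patience,lr_factor,lr_patience
#'   Optimizer/schedule settings.
#' @param val_fraction Stratified slice of the training split monitored for
#'   early stopping / LR reduction (default 0.15).
#' @param test_fraction Held-out test share of the cohort (default 0.30).
#' @param folds Stratified CV folds (default 5).
#' @param class_weighting Use balanced class weights (default TRUE).
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 100,
                         batch_size = 64, patience = 10, lr_factor = 0.2,
                         lr_patience = 8, val_fraction = 0.15,
                         test_fraction = 0.30, folds = 5,
                         class_weighting = TRUE, seed = 1) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(vapply(cfg[num], function(v) v <= 0,
                 logical(1)) & names(cfg)[num] != "seed"))
    abort("train_config values must be positive")
  if (val_fraction >= 1 || test_fraction >= 1)
    abort("fractions must be in (0, 1)")
  structure(cfg, class = "train_config")
}

# Stratified index split: returns indices of the held-out part.
stratified_holdout <- function(labels, fraction, seed) {
  with_local_seed(seed, {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      k <- round(length(idx) * fraction)
      sample(idx, k)
    }))
  })
}

# Stratified k-fold assignment vector.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the CNN
#'
#' Trains with the configured regime on PCA scores. A stratified
#' `val_fraction` slice of the supplied training data is held aside and
#' monitored for early stopping (patience epochs without validation-loss
#' improvement halts training and restores the best weights) and for
#' learning-rate reduction (factor `lr_factor` after `lr_patience` stagnant
#' epochs). Deterministic given the config seed.
#'
#' @param scores Training score matrix (samples x input_len).
#' @param labels Binary 0/1 labels.
#' @param config A [train_config()].
#' @param model Optional pre-built `eeg_cnn` (defaults to a fresh
#'   [build_cnn()] seeded from the config).
#' @return A trained `eeg_cnn` with `history` (per-epoch tibble) and
#'   `config` attached.
#' @export
train_cnn <- function(scores, labels, config = train_config(), model = NULL) {
  stopifnot(is.matrix(scores))
  labels <- as.integer(labels)
  if (min(table(labels)) < 2) abort("need at least 2 samples per class")
  model <- model %||% build_cnn(ncol(scores), seed = derive_seed(config$seed, "init"))
  val_idx <- stratified_holdout(labels, config$val_fraction,
                                derive_seed(config$seed, "val-split"))
  if (length(val_idx) == 0 || length(val_idx) == length(labels))
    abort("validation slice is degenerate; adjust val_fraction")
  xv <- scores[val_idx, , drop = FALSE]; yv <- labels[val_idx]
  xt <- scores[-val_idx, , drop = FALSE]; yt <- labels[-val_idx]
  cw <- if (config$class_weighting) compute_class_weights(labels)
        else c("0" = 1, "1" = 1)
  wt <- unname(cw[as.character(yt)])
  wv <- unname(cw[as.character(yv)])
  opt <- adam_init(model$params)
  lr <- config$learning_rate
  best_loss <- Inf; best_params <- model$params; best_buffers <- model$buffers
  stale <- 0; lr_stale <- 0
  hist <- vector("list", config$max_epochs)
  rng_seed <- derive_seed(config$seed, "epochs")
  epochs_run <- 0
  with_local_seed(rng_seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(nrow(xt))
      batch_starts <- seq(1, length(ord), by = config$batch_size)
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (s in batch_starts) {
        bi <- ord[s:min(length(ord), s + config$batch_size - 1)]
        xb <- xt[bi, , drop = FALSE]; yb <- yt[bi]; wb <- wt[bi]
        mask <- matrix(stats::rbinom(length(bi) * 128, 1, 0.5), length(bi), 128) / 0.5
        fw <- cnn_forward(model, xb, training = TRUE, dropout_mask = mask)
        fw$dropout_mask <- mask
        gr <- cnn_backward(model, fw, yb, wb)
        st <- adam_step(model$params, gr, opt, lr)
        model$params <- st$params; opt <- st$state
        # update running BN statistics from the batch statistics
        model$buffers$rm1 <- BN_MOMENTUM * model$buffers$rm1 + (1 - BN_MOMENTUM) * fw$bn1$mu
        model$buffers$rv1 <- BN_MOMENTUM * model$buffers$rv1 + (1 - BN_MOMENTUM) * fw$bn1$v
        model$buffers$rm2 <- BN_MOMENTUM * model$buffers$rm2 + (1 - BN_MOMENTUM) * fw$bn2$mu
        model$buffers$rv2 <- BN_MOMENTUM * model$buffers$rv2 + (1 - BN_MOMENTUM) * fw$bn2$v
        ep_loss <- ep_loss + weighted_bce(fw$prob, yb, wb) * length(bi)
        ep_n <- ep_n + length(bi)
        ep_correct <- ep_correct + sum((fw$prob >= 0.5) == yb)
      }
      pv <- cnn_forward(model, xv, training = FALSE)$prob
      val_loss <- weighted_bce(pv, yv, wv)
      val_acc <- mean((pv >= 0.5) == yv)
      hist[[epoch]] <- tibble(epoch = epoch, loss = ep_loss / ep_n,
                              accuracy = ep_correct / ep_n,
                              val_loss = val_loss, val_accuracy = val_acc,
                              lr = lr)
      epochs_run <- epoch
      if (val_loss < best_loss - 1e-5) {
        best_loss <- val_loss; best_params <- model$params
        best_buffers <- model$buffers
        stale <- 0; lr_stale <- 0
      } else {
        stale <- stale + 1; lr_stale <- lr_stale + 1
        if (lr_stale >= config$lr_patience) {
          lr <- max(lr * config$lr_factor, 1e-7)
          lr_stale <- 0
        }
        if (stale >= config$patience) break
      }
      if (!is.finite(val_loss) || !is.finite(ep_loss))
        abort("NaN/Inf loss during training; check inputs and learning rate")
    }
  })
  model$params <- best_params
  model$buffers <- best_buffers
  model$history <- dplyr::bind_rows(hist[seq_len(epochs_run)])
  model$config <- config
  model
}

#' Evaluate predictions in a published-style metrics table
#'
#' Per-class precision, recall, F1 and support at the 0.5 probability
#' threshold, plus accuracy, macro (unweighted class mean) and weighted
#' (support-weighted) averages, and the confusion counts.
#'
#' @param model Trained `eeg_cnn`, or a numeric vector of probabilities.
#' @param scores Scores matrix (ignored when `model` is a vector).
#' @param labels Binary 0/1 labels.
#' @return An `eval_report` list: `metrics` tibble, `confusion` (2x2),
#'   `accuracy`, `probabilities`, `n`.
#' @export
evaluate_model <- function(model, scores = NULL, labels) {
  prob <- if (is.numeric(model) && is.null(dim(model))) model
          else predict(model, scores)
  labels <- as.integer(labels)
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n <- length(labels)
  prf <- function(tp, fp, fn) {
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }
  m1 <- prf(tp, fp, fn)
  m0 <- prf(tn, fn, fp)
  sup <- c(sum(labels == 0), sum(labels == 1))
  acc <- (tp + tn) / n
  metrics <- tibble(
    class = c("Non-depressed (0)", "Depressed (1)", "Accuracy",
              "Macro Avg", "Weighted Avg"),
    precision = c(m0[1], m1[1], NA, mean(c(m0[1], m1[1])),
                  sum(sup * c(m0[1], m1[1])) / n),
    recall = c(m0[2], m1[2], NA, mean(c(m0[2], m1[2])),
               sum(sup * c(m0[2], m1[2])) / n),
    f1 = c(m0[3], m1[3], acc, mean(c(m0[3], m1[3])),
           sum(sup * c(m0[3], m1[3])) / n),
    support = c(sup, n, n, n)
  )
  structure(list(metrics = metrics,
                 confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                                    dimnames = list(pred = c("0", "1"),
                                                    truth = c("0", "1"))),
                 accuracy = acc, probabilities = prob, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Classification report (threshold 0.5)\n")
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Stratified k-fold cross-validation of the full per-fold pipeline
#'
#' For each fold the standardizer, PCA and CNN are refit on the training
#' rows only; the held-out fold is transformed with the training statistics
#' and evaluated. Test rows never enter any fit step.
#'
#' @param table Feature table (31 features + `label`).
#' @param config A [train_config()]; `folds` controls k.
#' @param n_components PCA components (default 21).
#' @return A `cv_result`: `folds` (list of `eval_report`), `summary`
#'   tibble, `accuracy_mean`, `accuracy_sd`, `fold_assignment`.
#' @export
cross_validate <- function(table, config = train_config(), n_components = 21) {
  parts <- split_feature_table(table)
  if (is.null(parts$label)) abort("cross_validate() needs a `label` column")
  y <- parts$label
  if (min(sum(y == 0L), sum(y == 1L)) < config$folds)
    abort("need at least `folds` samples per class")
  fold <- stratified_folds(y, config$folds, derive_seed(config$seed, "cv-folds"))
  reports <- lapply(seq_len(config$folds), function(k) {
    tr <- which(fold != k); te <- which(fold == k)
    tab_tr <- table[tr, , drop = FALSE]
    st <- fit_standardizer(tab_tr)
    p <- fit_pca(standardize(st, tab_tr), n_components = n_components)
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, "cv-fold", k)
    m <- train_cnn(pca_project(p, standardize(st, tab_tr)), y[tr], fold_cfg)
    evaluate_model(m, pca_project(p, standardize(st, table[te, , drop = FALSE])),
                   y[te])
  })
  accs <- vapply(reports, `[[`, numeric(1), "accuracy")
  structure(list(
    folds = reports,
    summary = tibble(fold = seq_along(accs), accuracy = accs),
    accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
    fold_assignment = fold
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV accuracy: %.1f%% ± %.1f%%\n",
              length(x$folds), 100 * x$accuracy_mean, 100 * x$accuracy_sd))
  invisible(x)
}
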