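test_that("architecture matches the published layer stack and 74,753 params", {
  m <- build_cnn(21, seed = 1)
  expect_equal(cnn_n_params(m), 74753)
  arch <- architecture_spec(21)
  expect_equal(arch$layer,
               c("conv1d_1", "batchnorm_1", "maxpool_1", "conv1d_2",
                 "batchnorm_2", "maxpool_2", "flatten", "dense_1",
                 "dropout", "dense_2"))
  expect_equal(sum(arch$params), 74753)
  # length chain 21 -> 19 -> 9 -> 7 -> 3, flattened 384
  expect_equal(arch$output_len[c(1, 3, 4, 6, 7)], c(19, 9, 7, 3, 384))
  expect_error(build_cnn(9), ">= 11")
})

test_that("untrained and trained outputs are probabilities in (0,1)", {
  m <- build_cnn(21, seed = 2)
  x <- matrix(stats::rnorm(50 * 21), 50, 21)
  p <- predict(m, x)
  expect_length(p, 50)
  expect_true(all(p > 0 & p < 1))
})

test_that("training- and inference-mode forward passes agree after freezing", {
  # after enough updates the running statistics track the batch statistics,
  # and the folded-BN inference path must equal the explicit eval graph
  toy <- toy_separable_scores(30)
  m <- train_cnn(toy$scores, toy$labels,
                 train_config(max_epochs = 20, seed = 3))
  x <- toy$scores[1:10, ]
  p_graph <- neurodep:::cnn_forward(m, x, training = FALSE)$prob
  p_fold <- predict(m, x)
  expect_equal(p_fold, p_graph, tolerance = 1e-10)
})

test_that("class weights follow the balanced formula", {
  expect_equal(compute_class_weights(rep(c(0, 1), each = 116)),
               c("0" = 1, "1" = 1))
  expect_equal(compute_class_weights(c(rep(0, 80), rep(1, 20))),
               c("0" = 0.625, "1" = 2.5))
  expect_error(compute_class_weights(rep(1, 10)), "both classes")
  # all-ones weights leave the loss unchanged
  p <- c(0.2, 0.8, 0.6); y <- c(0, 1, 1)
  expect_equal(neurodep:::weighted_bce(p, y, rep(1, 3)),
               mean(-y * log(p) - (1 - y) * log(1 - p)))
})

test_that("the CNN fits linearly separable toy data to perfect train accuracy", {
  toy <- toy_separable_scores(60)
  m <- train_cnn(toy$scores, toy$labels, train_config(seed = 5))
  p <- predict(m, toy$scores)
  expect_equal(mean((p >= 0.5) == toy$labels), 1)
})

test_that("early stopping halts and LR reduction applies factor 0.2", {
  # pure-noise labels: validation loss cannot keep improving, so the run
  # must halt before the epoch cap and the LR schedule must have stepped
  xy <- neurodep:::with_local_seed(9, list(
    x = matrix(stats::rnorm(80 * 21), 80, 21),
    y = rep(c(0L, 1L), 40)
  ))
  m <- train_cnn(xy$x, xy$y, train_config(seed = 6))
  h <- m$history
  expect_lt(nrow(h), 100)
  expect_true(any(abs(h$lr - 1e-4 * 0.2) < 1e-12))
  # reproducibility: same seed, same history
  m2 <- train_cnn(xy$x, xy$y, train_config(seed = 6))
  expect_equal(m$history, m2$history)
  expect_equal(m$params$W4, m2$params$W4)
})

test_that("evaluation reproduces hand-computed confusion metrics", {
  # TN=34, FP=1, FN=2, TP=33 (n=70)
  truth <- c(rep(0, 35), rep(1, 35))
  prob <- c(rep(0.1, 34), 0.9, rep(0.05, 2), rep(0.95, 33))
  ev <- evaluate_model(prob, labels = truth)
  expect_equal(ev$accuracy, 67 / 70)
  mt <- ev$metrics
  dep <- mt[mt$class == "Depressed (1)", ]
  expect_equal(dep$precision, 33 / 34)
  expect_equal(dep$recall, 33 / 35)
  expect_equal(dep$support, 35)
  expect_equal(mt$support[mt$class == "Accuracy"], 70)
  # identities against the independent oracle
  o <- oracle_metrics(truth, as.integer(prob >= 0.5))
  expect_equal(ev$accuracy, o$accuracy)
  ctrl <- mt[mt$class == "Non-depressed (0)", ]
  expect_equal(ctrl$precision, unname(o$precision["0"]))
  expect_equal(ctrl$f1, unname(o$f1["0"]))
  macro <- mt[mt$class == "Macro Avg", ]
  expect_equal(macro$f1, mean(o$f1))
  expect_equal(sum(ev$confusion), 70)
})

test_that("perfect predictions give a table of ones", {
  truth <- rep(c(0, 1), 10)
  ev <- evaluate_model(ifelse(truth == 1, 0.99, 0.01), labels = truth)
  m <- ev$metrics
  expect_true(all(m$precision[1:2] == 1, m$recall[1:2] == 1, m$f1[1:2] == 1))
  expect_equal(ev$accuracy, 1)
})

test_that("cross-validation is a leakage-free stratified partition", {
  tbl <- synthesize_feature_table(25, seed = 21)
  cfg <- train_config(seed = 13, max_epochs = 5)
  cv <- cross_validate(tbl, cfg, n_components = 12)
  fold <- cv$fold_assignment
  # partition: every sample in exactly one test fold
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, 50)
  # stratification: fold class proportions within one sample of global
  for (k in 1:5) {
    n1 <- sum(tbl$label[fold == k] == 1)
    expect_lte(abs(n1 - 5), 1)
  }
  expect_length(cv$folds, 5)
  expect_equal(cv$accuracy_mean, mean(cv$summary$accuracy))
  # per-fold standardizers were fit on the training rows only
  expect_true(all(vapply(cv$folds, function(f) f$n, numeric(1)) == 10))
})

test_that("tidiers expose history and fit summaries", {
  toy <- toy_separable_scores(20)
  m <- train_cnn(toy$scores, toy$labels,
                 train_config(max_epochs = 8, seed = 2))
  h <- tidy(m)
  expect_true(all(c("epoch", "loss", "val_loss", "lr") %in% names(h)))
  g <- glance(m)
  expect_equal(g$n_params, 74753L)
  expect_lte(g$epochs_run, 8)
})
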