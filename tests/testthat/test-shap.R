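# Shapley attribution: axioms on constructed models, kernel-vs-exact
# equivalence, back-projection arithmetic, tiering.

test_that("a constant model gets zero attributions and the right base", {
  f <- function(m) rep(0.7, nrow(m))
  bg <- matrix(stats::rnorm(40), 10, 4)
  a <- kernel_shap(f, c(1, 2, 3, 4), bg, n_coalitions = 64, seed = 1)
  expect_equal(a$phi, rep(0, 4), tolerance = 1e-10)
  expect_equal(a$base, 0.7)
  expect_equal(a$fx, 0.7)
})

test_that("a linear model recovers its coefficients exactly", {
  f <- function(m) 2 * m[, 1] - m[, 2]
  a <- kernel_shap(f, c(1, 1), background = matrix(0, 10, 2),
                   n_coalitions = 8, seed = 1)
  expect_equal(a$phi, c(2, -1), tolerance = 1e-10)
})

test_that("exact Shapley satisfies symmetry and dummy axioms", {
  bg <- matrix(0, 5, 3)
  f_sym <- function(m) m[, 1] + m[, 2]
  a <- exact_shapley(f_sym, c(1, 1, 0.5), bg)
  expect_equal(a$phi[1], a$phi[2], tolerance = 1e-12)
  expect_equal(a$phi[1], 1, tolerance = 1e-12)
  # dummy: feature 3 ignored by the model
  expect_equal(a$phi[3], 0, tolerance = 1e-12)
  expect_error(exact_shapley(f_sym, rep(1, 13), matrix(0, 2, 13)), "M > 12")
})

test_that("kernel SHAP with full enumeration equals exact Shapley", {
  # twenty random nonlinear 8-input networks with random backgrounds
  for (trial in 1:20) {
    f <- random_toy_net(8, seed = 300 + trial)
    xs <- neurodep:::with_local_seed(400 + trial, list(
      x = stats::rnorm(8), bg = matrix(stats::rnorm(5 * 8), 5, 8)))
    ks <- kernel_shap(f, xs$x, xs$bg, n_coalitions = 2^8, seed = 1)
    ex <- exact_shapley(f, xs$x, xs$bg)
    expect_equal(ks$phi, ex$phi, tolerance = 1e-6)
    expect_equal(ks$base, ex$base, tolerance = 1e-10)
  }
})

test_that("additivity holds exactly on every explanation", {
  f <- random_toy_net(21, seed = 9)
  dat <- neurodep:::with_local_seed(10, list(
    x = matrix(stats::rnorm(4 * 21), 4, 21),
    bg = matrix(stats::rnorm(30 * 21), 30, 21)))
  ex <- explain_samples(f, dat$x, dat$bg, n_coalitions = 128, seed = 2)
  gap <- abs(ex$base + rowSums(ex$phi) - ex$fx)
  expect_lt(max(gap), 1e-6)
})

test_that("attributions are deterministic given seeds and background order-invariant", {
  f <- random_toy_net(6, seed = 21)
  x <- rep(0.5, 6)
  bg <- neurodep:::with_local_seed(3, matrix(stats::rnorm(60), 10, 6))
  a1 <- kernel_shap(f, x, bg, n_coalitions = 2^6, seed = 5)
  a2 <- kernel_shap(f, x, bg, n_coalitions = 2^6, seed = 5)
  expect_identical(a1$phi, a2$phi)
  # full enumeration + mean over background: row order cannot matter
  a3 <- kernel_shap(f, x, bg[10:1, ], n_coalitions = 2^6, seed = 5)
  expect_equal(a1$phi, a3$phi, tolerance = 1e-12)
})

test_that("coalition budget validation and sampled designs stay additive", {
  f <- random_toy_net(21, seed = 2)
  bg <- matrix(0, 5, 21)
  expect_error(kernel_shap(f, rep(0, 21), bg, n_coalitions = 10), ">=")
  a <- kernel_shap(f, rep(0.3, 21), bg, n_coalitions = 300, seed = 3)
  expect_equal(a$base + sum(a$phi), a$fx, tolerance = 1e-8)
})

test_that("back-projection follows the |phi| x |loading| formula", {
  # identity loadings: importance = mean |phi| per feature
  p_id <- structure(list(loadings = diag(3), variance_ratio = rep(1 / 3, 3),
                         center = rep(0, 3), n_components = 3,
                         features = c("a", "b", "c")),
                    class = "eeg_pca")
  expl <- structure(list(phi = rbind(c(1, -2, 0.5), c(-3, 2, 0.5)),
                         base = 0.5, fx = c(0.4, 0.6), m = 3),
                    class = "shap_explanation")
  imp <- backproject_importance(expl, p_id)
  expect_equal(imp$importance[match(c("a", "b", "c"), imp$feature)],
               c(2, 2, 0.5))
  # single nonzero component with loadings (0.6, 0.8): importances 3:4
  p_2 <- structure(list(loadings = matrix(c(0.6, 0.8), 1), center = c(0, 0),
                        variance_ratio = 1, n_components = 1,
                        features = c("f1", "f2")),
                   class = "eeg_pca")
  e_2 <- structure(list(phi = matrix(2, 1, 1), base = 0, fx = 2, m = 1),
                   class = "shap_explanation")
  i2 <- backproject_importance(e_2, p_2)
  expect_equal(i2$importance[i2$feature == "f1"] /
                 i2$importance[i2$feature == "f2"], 3 / 4)
  expect_error(backproject_importance(expl, p_2), "width")
})

test_that("tiering partitions all features with stable tie handling", {
  imp <- tibble::tibble(feature = letters[1:31], importance = rep(1, 31),
                        signed = 0, rank = 1:31)
  t1 <- rank_and_bucket(imp)
  expect_equal(levels(t1$tier), c("substantial", "moderate", "minimal"))
  expect_true(all(t1$tier == "substantial"))  # all-equal: one tier
  imp2 <- imp
  imp2$importance <- seq(1, 0.01, length.out = 31)
  t2 <- rank_and_bucket(imp2)
  expect_equal(sum(table(t2$tier)), 31)
  expect_true(all(diff(as.integer(t2$tier)) >= 0))
})

test_that("injected slowing markers dominate nondiscriminative moments", {
  # the property the attribution stage reliably delivers on this generator:
  # the two injected headline biomarkers rank far above the statistical
  # moment features that carry no class information
  tbl <- synthesize_feature_table(116, seed = 31)
  y <- tbl$label
  te <- neurodep:::stratified_holdout(y, 0.3, 77)
  st <- fit_standardizer(tbl[-te, ])
  p <- fit_pca(standardize(st, tbl[-te, ]), 21)
  sc_tr <- pca_project(p, standardize(st, tbl[-te, ]))
  sc_te <- pca_project(p, standardize(st, tbl[te, ]))
  m <- train_cnn(sc_tr, y[-te], train_config(seed = 78))
  ex <- explain_samples(m, sc_te[1:8, , drop = FALSE], sc_tr[1:50, ],
                        n_coalitions = 512, seed = 79)
  imp <- backproject_importance(ex, p)
  rk <- stats::setNames(imp$rank, imp$feature)
  inert <- c("mean", "median", "kurtosis", "skewness")
  expect_lt(rk[["delta_alpha_ratio"]], min(rk[inert]))
  expect_lt(rk[["fft_theta_max_power"]], min(rk[inert]))
})
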