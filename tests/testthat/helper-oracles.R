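# Independent oracles and small fixtures shared across the suite.

# Tiny cohort settings used throughout unit tests: long enough for every
# extractor precondition (Welch needs 1024 samples), short enough to be fast.
tiny_spec <- function(n_per_class = 2, seed = 101) {
  cohort_spec(n_per_class = n_per_class, duration = 8, sampling_rate = 256,
              seed = seed)
}

# Independent classification metrics from a confusion table (never reuses
# package code).
oracle_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  prec1 <- tp / (tp + fp); rec1 <- tp / (tp + fn)
  prec0 <- tn / (tn + fn); rec0 <- tn / (tn + fp)
  list(accuracy = (tp + tn) / length(truth),
       precision = c(`0` = prec0, `1` = prec1),
       recall = c(`0` = rec0, `1` = rec1),
       f1 = c(`0` = 2 * prec0 * rec0 / (prec0 + rec0),
              `1` = 2 * prec1 * rec1 / (prec1 + rec1)))
}

# Brute-force reimplementation of the three aggregation rules straight from
# the registry definition.
oracle_aggregate <- function(region_tbl) {
  reg <- feature_registry()
  feats <- intersect(names(region_tbl), reg$feature)
  out <- lapply(feats, function(f) {
    v <- region_tbl[[f]]
    rule <- reg$aggregation[reg$feature == f]
    if (rule == "max") max(v, na.rm = TRUE)
    else if (rule == "min") min(v, na.rm = TRUE)
    else mean(v, na.rm = TRUE)
  })
  stats::setNames(unlist(out), feats)
}

# Mean silhouette width for a 2-class labelling of 2-D points.
oracle_silhouette <- function(xy, label) {
  d <- as.matrix(stats::dist(xy))
  n <- nrow(xy)
  s <- vapply(seq_len(n), function(i) {
    own <- label == label[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !own & seq_len(n) != i])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Small random two-layer tanh network over `m` inputs, deterministic given
# seed; returns a batched prediction closure in (0, 1).
random_toy_net <- function(m, seed) {
  pars <- neurodep:::with_local_seed(seed, list(
    W1 = matrix(stats::rnorm(m * 8, sd = 0.8), m, 8),
    b1 = stats::rnorm(8, sd = 0.3),
    W2 = matrix(stats::rnorm(8), 8, 1),
    b2 = stats::rnorm(1, sd = 0.2)
  ))
  function(x) {
    h <- tanh(sweep(x %*% pars$W1, 2, pars$b1, `+`))
    as.numeric(1 / (1 + exp(-(h %*% pars$W2 + pars$b2))))
  }
}

# Linearly separable toy scores for classifier sanity checks.
toy_separable_scores <- function(n_per_class = 40, width = 21, gap = 6,
                                 seed = 7) {
  neurodep:::with_local_seed(seed, {
    x0 <- matrix(stats::rnorm(n_per_class * width), ncol = width)
    x1 <- matrix(stats::rnorm(n_per_class * width), ncol = width)
    x1[, 1:3] <- x1[, 1:3] + gap
    list(scores = rbind(x0, x1),
         labels = rep(c(0L, 1L), each = n_per_class))
  })
}

# Shared study-scale cohort for the acceptance blocks (computed once per
# test run: 116 per class, 60 s at 256 Hz, fixed seed).
acceptance_cache <- new.env(parent = emptyenv())
acceptance_cohort_features <- function() {
  if (is.null(acceptance_cache$feats)) {
    spec <- cohort_spec(n_per_class = 116, duration = 60,
                        sampling_rate = 256, seed = 20250929)
    acceptance_cache$feats <- extract_feature_table(spec)
  }
  acceptance_cache$feats
}
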