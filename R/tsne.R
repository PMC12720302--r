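# Exact (O(n^2)) t-SNE for visualization of PCA scores. At cohort scale
# (n ~ 232) the exact gradient is trivial, so no tree approximation is
# needed. The embedding is used for class-separability display only; it has
# no out-of-sample transform and is never fed to the classifier.

#' 2-D t-SNE embedding
#'
#' Classic t-SNE (Gaussian input affinities calibrated per point to the
#' target perplexity by bisection; Student-t output kernel; gradient descent
#' with momentum, adaptive gains, and early exaggeration for the first third
#' of the iterations). Deterministic given `seed`.
#'
#' @param scores Numeric matrix (samples x dims), e.g. PCA scores.
#' @param perplexity Target perplexity (default 50); requires
#'   `nrow(scores) > 3 * perplexity`.
#' @param iterations Gradient-descent iterations (default 300).
#' @param seed Integer seed for the random initialization.
#' @return An `eeg_embedding` tibble with columns `x`, `y` (and `label` if
#'   supplied), and attributes `perplexity`, `iterations`, `seed`.
#' @param label Optional label vector attached to the output for plotting.
#' @export
#' @examples
#' sc <- as.matrix(synthesize_feature_table(40, seed = 1)[, c("mobility", "complexity")])
#' emb <- tsne_embed(scale(sc), perplexity = 10, iterations = 50, seed = 1)
tsne_embed <- function(scores, perplexity = 50, iterations = 300, seed = 1,
                       label = NULL) {
  stopifnot(is.matrix(scores))
  n <- nrow(scores)
  if (n <= 3 * perplexity)
    abort(sprintf(
      "n = %d is too small for perplexity %g (need n > 3*perplexity); use a smaller perplexity",
      n, perplexity))
  P <- tsne_affinities(scores, perplexity)
  exaggeration_end <- max(1L, iterations %/% 3L)
  eta <- 200
  momentum <- 0.5
  Y <- with_local_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  P_run <- P * 12  # early exaggeration
  for (it in seq_len(iterations)) {
    if (it == exaggeration_end + 1L) P_run <- P
    if (it == 100L) momentum <- 0.8
    d2 <- 1 / (1 + sq_dist(Y))
    diag(d2) <- 0
    Q <- d2 / sum(d2)
    W <- (P_run - Q) * d2
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y), `-`)
  }
  out <- tibble(x = Y[, 1], y = Y[, 2])
  if (!is.null(label)) out$label <- label
  structure(out, class = c("eeg_embedding", class(out)),
            perplexity = perplexity, iterations = iterations, seed = seed)
}

sq_dist <- function(y) {
  s <- rowSums(y^2)
  d <- outer(s, s, `+`) - 2 * tcrossprod(y)
  d[d < 0] <- 0
  d
}

# Per-point Gaussian bandwidths matched to the target perplexity by
# bisection on log-precision; returns the symmetrized joint P (sums to 1).
tsne_affinities <- function(x, perplexity, tol = 1e-5) {
  n <- nrow(x)
  D <- sq_dist(x)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { p <- rep(1 / length(di), length(di)); break }
      p <- p / s
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < tol) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}
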