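# Model-agnostic Shapley attribution: Kernel SHAP (weighted least squares
# over feature coalitions with the Shapley kernel), an exact enumeration
# oracle for small input widths, and back-projection of component-level
# attributions through PCA loadings onto the original EEG features.

# Coerce a model argument to a batched prediction closure matrix -> numeric.
as_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "eeg_cnn")) return(function(x) predict(model, x))
  abort("`model` must be a function(matrix) -> numeric or an eeg_cnn")
}

# Coalition value function: v(S) = mean over background rows of
# f(x_S joined with background_complement); evaluated for many coalitions in
# bounded-size batches.
coalition_values <- function(f, x, background, Z, chunk = 16384L) {
  nb <- nrow(background)
  m <- length(x)
  nz <- nrow(Z)
  vals <- numeric(nz)
  per <- max(1L, chunk %/% nb)
  for (s in seq(1L, nz, by = per)) {
    e <- min(nz, s + per - 1L)
    rows <- (e - s + 1L) * nb
    big <- background[rep(seq_len(nb), times = e - s + 1L), , drop = FALSE]
    zrep <- Z[rep(s:e, each = nb), , drop = FALSE]
    xrep <- matrix(x, rows, m, byrow = TRUE)
    big[zrep == 1] <- xrep[zrep == 1]
    p <- f(big)
    vals[s:e] <- colMeans(matrix(p, nrow = nb))
  }
  vals
}

#' Kernel SHAP attribution for one sample
#'
#' Solves the Shapley-kernel weighted least-squares problem over feature
#' coalitions, with missing features imputed by background substitution
#' (averaging the model over the background rows). Coalition sizes are
#' enumerated completely from the outside in while the budget allows
#' (smallest and largest sizes carry the most kernel weight); any remaining
#' budget is filled by weighted sampling. The additivity constraint
#' `base + sum(phi) = f(x)` is enforced exactly by eliminating one
#' coefficient. When `2^M - 2 <= n_coalitions` the enumeration is complete
#' and the result equals the exact Shapley values.
#'
#' @param model An `eeg_cnn` or a prediction function `f(matrix) -> numeric`
#'   returning the positive-class probability.
#' @param x Numeric sample vector (length M = model input width).
#' @param background Background matrix (rows x M), drawn from training data.
#' @param n_coalitions Coalition evaluation budget (default 2048; must be
#'   >= 2M + 2).
#' @param seed Seed for coalition sampling (only used when sampling is
#'   needed).
#' @return A `shap_attribution`: `phi` (length M), `base` (expected model
#'   output over the background), `fx` (model output at `x`).
#' @export
#' @examples
#' f <- function(m) 2 * m[, 1] - m[, 2]
#' a <- kernel_shap(f, c(1, 1), background = matrix(0, 10, 2))
#' a$phi  # (2, -1)
kernel_shap <- function(model, x, background, n_coalitions = 2048, seed = 1) {
  f <- as_predict_fun(model)
  x <- as.numeric(x)
  m <- length(x)
  stopifnot(is.matrix(background), ncol(background) == m)
  if (nrow(background) < 1) abort("background must have rows")
  if (n_coalitions < 2 * m + 2)
    abort(sprintf("n_coalitions must be >= 2*M + 2 = %d", 2 * m + 2))
  base <- mean(f(background))
  fx <- f(matrix(x, nrow = 1))
  design <- shap_design(m, n_coalitions, seed)
  v <- coalition_values(f, x, background, design$Z)
  phi <- solve_kernel_wls(design$Z, design$w, v, base, fx)
  structure(list(phi = phi, base = base, fx = fx, m = m,
                 n_coalitions = nrow(design$Z)),
            class = "shap_attribution")
}

# Shapley kernel weight for a coalition of size s out of M (per coalition).
shapley_kernel_weight <- function(m, s) {
  (m - 1) / (choose(m, s) * s * (m - s))
}

# Build the coalition design: matrix Z (coalitions x M) and weights w.
shap_design <- function(m, budget, seed) {
  total <- 2^m - 2
  if (is.finite(total) && total <= budget) {
    # complete enumeration of all proper nonempty coalitions
    Z <- as.matrix(expand.grid(rep(list(0:1), m)))[-c(1, 2^m), , drop = FALSE]
    dimnames(Z) <- NULL
    s <- rowSums(Z)
    return(list(Z = Z, w = shapley_kernel_weight(m, s)))
  }
  # paired size enumeration from the outside in
  sizes <- seq_len(m - 1)
  order_sizes <- unique(as.vector(rbind(sizes, rev(sizes))))
  counts <- choose(m, order_sizes)
  Zs <- list(); ws <- list()
  left <- budget
  enumerated <- logical(length(order_sizes))
  for (i in seq_along(order_sizes)) {
    s <- order_sizes[i]
    if (counts[i] <= left) {
      comb <- utils::combn(m, s)
      Zi <- matrix(0L, ncol(comb), m)
      Zi[cbind(rep(seq_len(ncol(comb)), each = s), as.vector(comb))] <- 1L
      Zs[[length(Zs) + 1L]] <- Zi
      ws[[length(ws) + 1L]] <- rep(shapley_kernel_weight(m, s), nrow(Zi))
      left <- left - nrow(Zi)
      enumerated[i] <- TRUE
    }
  }
  rem_sizes <- order_sizes[!enumerated]
  if (length(rem_sizes) && left > 0) {
    # sample remaining coalitions by the kernel's size distribution; each
    # sampled coalition carries the residual weight mass equally
    size_mass <- vapply(rem_sizes, function(s)
      choose(m, s) * shapley_kernel_weight(m, s), numeric(1))
    Zr <- with_local_seed(seed, {
      pick_sizes <- sample(rem_sizes, left, replace = TRUE,
                           prob = size_mass / sum(size_mass))
      t(vapply(pick_sizes, function(s) {
        z <- integer(m); z[sample.int(m, s)] <- 1L; z
      }, integer(m)))
    })
    Zs[[length(Zs) + 1L]] <- Zr
    ws[[length(ws) + 1L]] <- rep(sum(size_mass) / left, left)
  }
  list(Z = do.call(rbind, Zs), w = unlist(ws))
}

# Constrained weighted least squares with the additivity constraint
# eliminated through the last feature (Lundberg-Lee formulation).
solve_kernel_wls <- function(Z, w, v, base, fx) {
  m <- ncol(Z)
  delta <- fx - base
  y <- v - base - Z[, m] * delta
  A <- Z[, -m, drop = FALSE] - Z[, m]
  aw <- A * w
  xtx <- crossprod(aw, A)
  xty <- crossprod(aw, y)
  phi_head <- tryCatch(solve(xtx, xty), error = function(e)
    abort("singular Kernel SHAP regression; increase n_coalitions"))
  phi <- c(phi_head, delta - sum(phi_head))
  as.numeric(phi)
}

#' Exact Shapley values by full subset enumeration
#'
#' Brute-force oracle: enumerates all 2^M coalitions with the background-
#' substitution value function and combines marginal contributions with the
#' exact Shapley weights. Refuses widths above 12.
#'
#' @inheritParams kernel_shap
#' @return A `shap_attribution` (exact).
#' @export
#' @examples
#' f <- function(m) m[, 1] + m[, 2]
#' exact_shapley(f, c(1, 1), matrix(0, 5, 2))$phi  # (1, 1)
exact_shapley <- function(model, x, background) {
  f <- as_predict_fun(model)
  x <- as.numeric(x)
  m <- length(x)
  if (m > 12)
    abort("exact_shapley() enumerates 2^M coalitions; refusing M > 12")
  stopifnot(is.matrix(background), ncol(background) == m)
  Z <- as.matrix(expand.grid(rep(list(0:1), m)))
  dimnames(Z) <- NULL
  v <- coalition_values(f, x, background, Z)
  sizes <- rowSums(Z)
  fact <- factorial(0:m)
  phi <- numeric(m)
  for (i in seq_len(m)) {
    without <- Z[, i] == 0
    idx_wo <- which(without)
    # index of S union {i}: flip bit i (expand.grid order: bit i has stride 2^(i-1))
    idx_wi <- idx_wo + 2^(i - 1)
    s <- sizes[idx_wo]
    wgt <- fact[s + 1] * fact[m - s] / fact[m + 1]
    phi[i] <- sum(wgt * (v[idx_wi] - v[idx_wo]))
  }
  structure(list(phi = phi, base = v[1], fx = v[2^m], m = m,
                 n_coalitions = 2^m),
            class = "shap_attribution")
}

#' Explain a set of samples
#'
#' Runs [kernel_shap()] (or the exact oracle when the width allows a
#' complete enumeration within the budget) on each row of `x`.
#'
#' @param model Model or prediction function.
#' @param x Matrix of samples to explain (rows) in model input space.
#' @param background Background matrix.
#' @param n_coalitions Budget per sample (default 2048).
#' @param seed Integer seed.
#' @return A `shap_explanation`: `phi` matrix (samples x M), `base`, `fx`
#'   vector.
#' @export
explain_samples <- function(model, x, background, n_coalitions = 2048,
                            seed = 1) {
  stopifnot(is.matrix(x))
  atts <- lapply(seq_len(nrow(x)), function(i)
    kernel_shap(model, x[i, ], background, n_coalitions,
                seed = derive_seed(seed, "coalitions", i)))
  structure(list(
    phi = do.call(rbind, lapply(atts, `[[`, "phi")),
    base = atts[[1]]$base,
    fx = vapply(atts, `[[`, numeric(1), "fx"),
    m = ncol(x)
  ), class = "shap_explanation")
}

#' Back-project component attributions onto original features
#'
#' Importance of original feature j is
#' `sum_k mean_samples(|phi_k|) * |L_kj|` over the PCA loading matrix L; the
#' signed summary `sum_k mean(phi_k) * L_kj` is retained as a secondary
#' column but is not the ranking basis. Ties rank alphabetically.
#'
#' @param explanation A `shap_explanation` (or `shap_attribution`).
#' @param pca An `eeg_pca` whose component count equals the attribution
#'   width.
#' @return A `feature_importance` tibble: `feature`, `importance`,
#'   `signed`, `rank`.
#' @export
backproject_importance <- function(explanation, pca) {
  phi <- if (inherits(explanation, "shap_attribution"))
    matrix(explanation$phi, nrow = 1) else explanation$phi
  stopifnot(inherits(pca, "eeg_pca"))
  if (ncol(phi) != nrow(pca$loadings))
    abort(sprintf("attribution width %d != PCA component count %d",
                  ncol(phi), nrow(pca$loadings)))
  mean_abs <- colMeans(abs(phi))
  mean_signed <- colMeans(phi)
  importance <- as.numeric(mean_abs %*% abs(pca$loadings))
  signed <- as.numeric(mean_signed %*% pca$loadings)
  feats <- pca$features %||% paste0("f", seq_len(ncol(pca$loadings)))
  out <- tibble(feature = feats, importance = importance, signed = signed)
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$feature)
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("feature_importance", class(out)))
}

#' Tier features by importance
#'
#' Buckets max-normalized importances into `substantial` (upper 30%:
#' normalized importance >= 0.7), `moderate` (middle 20%: >= 0.5) and
#' `minimal` tiers — a three-tier readout comparable to published
#' substantial/moderate/minimal feature hierarchies.
#'
#' @param importance A `feature_importance` tibble.
#' @return The tibble with an added `tier` factor column.
#' @export
rank_and_bucket <- function(importance) {
  stopifnot(is.data.frame(importance), "importance" %in% names(importance))
  mx <- max(importance$importance)
  norm <- if (mx > 0) importance$importance / mx else rep(1, nrow(importance))
  tier <- dplyr::case_when(norm >= 0.7 ~ "substantial",
                           norm >= 0.5 ~ "moderate",
                           TRUE ~ "minimal")
  importance$tier <- factor(tier, levels = c("substantial", "moderate", "minimal"))
  importance
}
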