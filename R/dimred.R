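# Standardization and PCA. The standardizer and PCA are fit on training
# rows only and reused for test data (no leakage); PCA keeps 21 components
# with a fixed sign convention for reproducible artifacts.

#' Fit a feature standardizer
#'
#' Learns per-feature means and standard deviations on (training) data.
#' Constant features are rejected by name.
#'
#' @param table Feature table (data frame); non-feature columns
#'   (`subject_id`, `label`) are ignored. A plain numeric matrix is also
#'   accepted.
#' @return An `eeg_standardizer`.
#' @export
#' @examples
#' tbl <- synthesize_feature_table(10, seed = 1)
#' st <- fit_standardizer(tbl)
#' colMeans(standardize(st, tbl))[1:3]
fit_standardizer <- function(table) {
  x <- feature_matrix(table)
  if (nrow(x) < 2) abort("fit_standardizer() needs at least 2 rows")
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    abort(paste("constant feature column(s):",
                paste(colnames(x)[sds == 0], collapse = ", ")))
  structure(list(mean = mu, sd = sds, features = colnames(x),
                 n_fit = nrow(x)),
            class = "eeg_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param standardizer An `eeg_standardizer`.
#' @param table Feature table or matrix with the same feature columns.
#' @return Numeric matrix of z-scored features (training statistics reused;
#'   test-column means are not re-centered).
#' @export
standardize <- function(standardizer, table) {
  stopifnot(inherits(standardizer, "eeg_standardizer"))
  x <- feature_matrix(table)
  missing <- setdiff(standardizer$features, colnames(x))
  if (length(missing))
    abort(paste("missing feature column(s):", paste(missing, collapse = ", ")))
  x <- x[, standardizer$features, drop = FALSE]
  sweep(sweep(x, 2, standardizer$mean, `-`), 2, standardizer$sd, `/`)
}

feature_matrix <- function(table) {
  if (is.matrix(table)) {
    storage.mode(table) <- "double"
    if (is.null(colnames(table)))
      colnames(table) <- paste0("f", seq_len(ncol(table)))
    return(table)
  }
  stopifnot(is.data.frame(table))
  drop <- intersect(c("subject_id", "label"), names(table))
  x <- as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Fit PCA on a standardized matrix
#'
#' Wraps [stats::prcomp()]; keeps the leading `n_components` loadings
#' (components x features) and explained-variance ratios. Sign convention:
#' each component is flipped so its largest-magnitude loading is positive,
#' making artifacts reproducible across runs and platforms.
#'
#' @param x Standardized numeric matrix (samples x features).
#' @param n_components Components to retain (default 21).
#' @return An `eeg_pca` with `loadings` (n_components x features),
#'   `variance_ratio`, `center`, `n_components`.
#' @export
#' @examples
#' tbl <- synthesize_feature_table(20, seed = 1)
#' st <- fit_standardizer(tbl)
#' p <- fit_pca(standardize(st, tbl), n_components = 5)
#' sum(p$variance_ratio)
fit_pca <- function(x, n_components = 21) {
  stopifnot(is.matrix(x))
  if (n_components > min(nrow(x), ncol(x)))
    abort(sprintf("n_components = %d exceeds min(n_rows, n_cols) = %d",
                  n_components, min(nrow(x), ncol(x))))
  if (nrow(x) < n_components) abort("need at least as many rows as components")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  k <- n_components
  L <- t(pr$rotation[, seq_len(k), drop = FALSE])
  # sign fix: largest-|loading| entry of each component made positive
  for (i in seq_len(k)) {
    j <- which.max(abs(L[i, ]))
    if (L[i, j] < 0) L[i, ] <- -L[i, ]
  }
  structure(list(loadings = L, variance_ratio = evr[seq_len(k)],
                 all_variance_ratio = evr, center = pr$center,
                 n_components = k, features = colnames(x)),
            class = "eeg_pca")
}

#' Project data onto fitted principal components
#'
#' @param pca An `eeg_pca`.
#' @param x Matrix with the same feature columns used at fit time.
#' @return Scores matrix (samples x n_components).
#' @export
pca_project <- function(pca, x) {
  stopifnot(inherits(pca, "eeg_pca"), is.matrix(x))
  if (ncol(x) != ncol(pca$loadings))
    abort("feature dimension mismatch with fitted PCA")
  sweep(x, 2, pca$center, `-`) %*% t(pca$loadings)
}
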