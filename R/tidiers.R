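# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted PCA
#'
#' @param x An `eeg_pca`.
#' @param ... Unused.
#' @return Tibble with `component`, `variance_ratio`, `cumulative`.
#' @export
tidy.eeg_pca <- function(x, ...) {
  tibble(component = seq_len(x$n_components),
         variance_ratio = x$variance_ratio,
         cumulative = cumsum(x$variance_ratio))
}

#' @rdname tidy.eeg_pca
#' @export
glance.eeg_pca <- function(x, ...) {
  tibble(n_components = x$n_components,
         variance_retained = sum(x$variance_ratio),
         n_features = ncol(x$loadings))
}

#' Tidy a standardizer
#' @param x An `eeg_standardizer`.
#' @param ... Unused.
#' @return Tibble with `feature`, `mean`, `sd`.
#' @export
tidy.eeg_standardizer <- function(x, ...) {
  tibble(feature = x$features, mean = unname(x$mean), sd = unname(x$sd))
}

#' Tidy a trained CNN (its training history)
#' @param x An `eeg_cnn`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.eeg_cnn <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), loss = numeric(),
                        accuracy = numeric(), val_loss = numeric(),
                        val_accuracy = numeric(), lr = numeric())
}

#' @rdname tidy.eeg_cnn
#' @export
glance.eeg_cnn <- function(x, ...) {
  h <- x$history
  tibble(n_params = cnn_n_params(x),
         epochs_run = if (is.null(h)) 0L else nrow(h),
         best_val_loss = if (is.null(h)) NA_real_ else min(h$val_loss),
         final_lr = if (is.null(h)) NA_real_ else h$lr[nrow(h)])
}

#' Tidy an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The metrics tibble.
#' @export
tidy.eval_report <- function(x, ...) x$metrics

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n,
         tp = x$confusion["1", "1"], tn = x$confusion["0", "0"],
         fp = x$confusion["1", "0"], fn = x$confusion["0", "1"])
}

#' Tidy a cross-validation result
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Per-fold accuracy tibble.
#' @export
tidy.cv_result <- function(x, ...) x$summary

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(folds = length(x$folds), accuracy_mean = x$accuracy_mean,
         accuracy_sd = x$accuracy_sd)
}

#' Tidy a SHAP explanation into long format
#' @param x A `shap_explanation`.
#' @param ... Unused.
#' @return Tibble with `sample`, `component`, `phi`.
#' @export
tidy.shap_explanation <- function(x, ...) {
  phi <- x$phi
  tibble(sample = rep(seq_len(nrow(phi)), times = ncol(phi)),
         component = rep(seq_len(ncol(phi)), each = nrow(phi)),
         phi = as.vector(phi))
}

#' @rdname tidy.shap_explanation
#' @export
glance.shap_explanation <- function(x, ...) {
  tibble(n_samples = nrow(x$phi), n_components = ncol(x$phi),
         base = x$base,
         max_additivity_gap = max(abs(x$base + rowSums(x$phi) - x$fx)))
}
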