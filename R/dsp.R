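# Signal-processing primitives: Welch PSD, STFT spectral entropy, db4 DWT.
# These are small, fully specified numerics; each is property- or
# oracle-tested (Parseval, frame counts, PyWavelets-frozen coefficients).

# Periodic Hann window (the spectral-averaging form).
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window, 512-sample segments
#' (2 s at 256 Hz, giving 0.5 Hz resolution) and 50% overlap. Segments are
#' demeaned individually. One-sided density scaling, so
#' `sum(psd) * df` approximates the signal variance (Parseval).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param n_seg Segment length in samples (default 512).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A tibble with columns `freq` (Hz) and `psd` (power / Hz).
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / 256))
#' p <- welch_psd(x, 256)
#' p$freq[which.max(p$psd)]  # ~10 Hz
welch_psd <- function(x, fs, n_seg = 512, overlap = 0.5) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (length(x) < 2 * n_seg)
    abort(sprintf("welch_psd() needs at least %d samples (2 segments); got %d",
                  2 * n_seg, length(x)))
  hop <- max(1L, as.integer(round(n_seg * (1 - overlap))))
  starts <- seq(1L, length(x) - n_seg + 1L, by = hop)
  w <- hann_window(n_seg)
  u <- sum(w^2)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + n_seg - 1L)]
    (seg - mean(seg)) * w
  }, numeric(n_seg))
  spec <- Mod(stats::mvfft(segs))^2 / (fs * u)
  nb <- n_seg %/% 2 + 1L
  psd <- rowMeans(spec)[seq_len(nb)]
  # one-sided: double everything except DC and Nyquist
  if (nb > 2) psd[2:(nb - 1)] <- 2 * psd[2:(nb - 1)]
  tibble(freq = (seq_len(nb) - 1) * fs / n_seg, psd = psd)
}

#' Band power from a PSD table
#'
#' `band_power()` integrates the PSD over the half-open interval
#' `[low, high)` Hz; `band_max_power()` returns the maximum PSD value in
#' the band ("FFT band max power").
#'
#' @param psd_tbl PSD tibble from [welch_psd()].
#' @param low,high Band edges in Hz (half-open).
#' @return Scalar power (or max PSD value).
#' @export
band_power <- function(psd_tbl, low, high) {
  df <- psd_tbl$freq[2] - psd_tbl$freq[1]
  sel <- psd_tbl$freq >= low & psd_tbl$freq < high
  sum(psd_tbl$psd[sel]) * df
}

#' @rdname band_power
#' @export
band_max_power <- function(psd_tbl, low, high) {
  sel <- psd_tbl$freq >= low & psd_tbl$freq < high
  if (!any(sel)) return(NA_real_)
  max(psd_tbl$psd[sel])
}

#' Short-time Fourier transform power spectrogram
#'
#' Hann-windowed STFT with 128-sample segments and 50% overlap (hop 64), no
#' zero padding, so a signal of `n` samples yields
#' `floor((n - 128) / 64) + 1` frames.
#'
#' @param x Numeric signal, length >= `n_seg`.
#' @param fs Sampling rate in Hz.
#' @param n_seg Segment length (default 128).
#' @return A list with `power` (bins x frames matrix), `freq`, `times`.
#' @export
stft_power <- function(x, fs, n_seg = 128) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < n_seg)
    abort(sprintf("stft_power() needs at least %d samples", n_seg))
  hop <- n_seg %/% 2L
  starts <- seq(1L, length(x) - n_seg + 1L, by = hop)
  w <- hann_window(n_seg)
  segs <- vapply(starts, function(s) x[s:(s + n_seg - 1L)] * w, numeric(n_seg))
  segs <- matrix(segs, nrow = n_seg)
  nb <- n_seg %/% 2 + 1L
  p <- Mod(stats::mvfft(segs))^2
  p <- p[seq_len(nb), , drop = FALSE]
  list(power = p,
       freq = (seq_len(nb) - 1) * fs / n_seg,
       times = (starts - 1 + n_seg / 2) / fs)
}

# Shannon entropy (nats) of a nonnegative weight vector after normalization.
shannon_entropy <- function(p) {
  s <- sum(p)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  p <- p[p > 0] / s
  -sum(p * log(p))
}

# Daubechies-4 analysis filters (orthonormal; exact published constants).
db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)

# One DWT analysis step with periodization: circular convolution with the
# analysis filter, downsampled by 2. Phase y[k] = sum_j f[j] x[(2k + L/2 - j)
# mod n] (k from 0), the PyWavelets "periodization" convention.
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  k <- 0:(n %/% 2L - 1L)
  idx <- (outer(2L * k + L %/% 2L, 0:(L - 1L), `-`) %% n) + 1L
  as.numeric(matrix(x[idx], ncol = L) %*% filt)
}

#' Multilevel db4 discrete wavelet decomposition
#'
#' Five-level (by default) Daubechies-4 DWT with periodization boundary
#' handling: every level halves the series, so detail coefficient counts are
#' `n/2, n/4, ...`. At 256 Hz the five detail levels approximate the
#' gamma-through-theta rhythms and the level-5 approximation covers delta.
#'
#' @param x Numeric signal; length must be a multiple of `2^levels` and at
#'   least `2^levels`.
#' @param levels Decomposition depth (default 5).
#' @return List with `details` (list of length `levels`, finest first) and
#'   `approximation` (level-`levels` approximation coefficients).
#' @export
dwt_db4 <- function(x, levels = 5) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  min_n <- 2^levels
  if (length(x) < min_n)
    abort(sprintf("dwt_db4() needs at least %d samples for %d levels; got %d",
                  min_n, levels, length(x)))
  if (length(x) %% min_n != 0)
    abort(sprintf("dwt_db4() requires length divisible by 2^levels = %d", min_n))
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    details[[l]] <- dwt_step(a, db4_dec_hi)
    a <- dwt_step(a, db4_dec_lo)
  }
  list(details = details, approximation = a)
}
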