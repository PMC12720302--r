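#' EEG frequency bands
#'
#' The five canonical EEG rhythm bands used throughout the package. Band
#' intervals are half-open `[low, high)` Hz; delta reaches down to 0 Hz and
#' gamma is capped at 50 Hz.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(0, 4, 8, 13, 30),
    high = c(4, 8, 13, 30, 50)
  )
}

#' The six cerebral regions
#'
#' @return Character vector of region names in canonical order.
#' @export
eeg_regions <- function() {
  c("frontal", "central", "temporal", "parietal", "occipital", "prefrontal")
}

#' The 31-feature registry
#'
#' Canonical registry of the 31 aggregated EEG features: display name, column
#' slug, extraction domain, the cross-region aggregation rule, and the
#' direction in which the feature shifts in depression (where established).
#'
#' Aggregation is direction-aware: features that flag depression when *high*
#' (delta/alpha ratio, FFT theta max power) take the cross-region maximum;
#' features that flag depression when *low* (mobility, complexity, wavelet
#' detailed entropy) take the minimum; everything else takes the mean.
#' Derived features are cross-regional by construction and carry the mean
#' rule for completeness.
#'
#' @return A tibble with columns `feature` (slug), `name`, `domain`
#'   (`STATISTICAL`, `FREQUENCY`, `TIME-FREQ`, `DERIVED`), `aggregation`
#'   (`max`, `min`, `mean`), `direction` (`high`, `low`, `none`).
#' @export
#' @examples
#' dplyr::count(feature_registry(), domain)
feature_registry <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~feature,                     ~name,                          ~domain,       ~aggregation, ~direction,
    "mobility",                   "Mobility",                     "STATISTICAL", "min",        "low",
    "complexity",                 "Complexity",                   "STATISTICAL", "min",        "low",
    "min",                        "Min",                          "STATISTICAL", "mean",       "none",
    "max",                        "Max",                          "STATISTICAL", "mean",       "none",
    "std",                        "STD",                          "STATISTICAL", "mean",       "none",
    "mean",                       "Mean",                         "STATISTICAL", "mean",       "none",
    "median",                     "Median",                       "STATISTICAL", "mean",       "none",
    "activity",                   "Activity",                     "STATISTICAL", "mean",       "none",
    "kurtosis",                   "Kurtosis",                     "STATISTICAL", "mean",       "none",
    "skewness",                   "Skewness",                     "STATISTICAL", "mean",       "none",
    "delta_alpha_ratio",          "Delta/Alpha Ratio",            "FREQUENCY",   "max",        "high",
    "fft_theta_max_power",        "FFT Theta Max Power",          "FREQUENCY",   "max",        "high",
    "fft_delta_max_power",        "FFT Delta Max Power",          "FREQUENCY",   "mean",       "none",
    "fft_alpha_max_power",        "FFT Alpha Max Power",          "FREQUENCY",   "mean",       "none",
    "fft_beta_max_power",         "FFT Beta Max Power",           "FREQUENCY",   "mean",       "none",
    "diff1_max",                  "1st Difference Max",           "FREQUENCY",   "mean",       "none",
    "diff2_max",                  "2nd Difference Max",           "FREQUENCY",   "mean",       "none",
    "diff1_mean",                 "1st Difference Mean",          "FREQUENCY",   "mean",       "none",
    "diff2_mean",                 "2nd Difference Mean",          "FREQUENCY",   "mean",       "none",
    "coeff_variation",            "Coefficient of Variation",     "FREQUENCY",   "mean",       "none",
    "wavelet_detailed_entropy",   "Wavelet Detailed Entropy",     "TIME-FREQ",   "min",        "low",
    "wavelet_approximate_mean",   "Wavelet Approximate Mean",     "TIME-FREQ",   "mean",       "none",
    "theta_band_power",           "Theta Band Power (avg)",       "DERIVED",     "mean",       "none",
    "alpha_band_power",           "Alpha Band Power (avg)",       "DERIVED",     "mean",       "none",
    "delta_band_power",           "Delta Band Power (avg)",       "DERIVED",     "mean",       "none",
    "beta_band_power",            "Beta Band Power (avg)",        "DERIVED",     "mean",       "none",
    "gamma_band_power",           "Gamma Band Power (avg)",       "DERIVED",     "mean",       "none",
    "hjorth_activity",            "Hjorth Activity",              "DERIVED",     "mean",       "none",
    "signal_complexity_spectral", "Signal Complexity (spectral)", "DERIVED",     "mean",       "none",
    "regional_power_asymmetry",   "Regional Power Asymmetry",     "DERIVED",     "mean",       "none",
    "theta_alpha_ratio",          "Theta/Alpha Ratio",            "DERIVED",     "mean",       "none"
  )
}

# Slugs of per-region features (computed on each region's signal, then
# aggregated); the DERIVED nine are cross-regional and computed once.
per_region_features <- function() {
  reg <- feature_registry()
  reg$feature[reg$domain != "DERIVED"]
}

# The five biomarkers with printed normal/depression ranges, their normal
# range and the depression threshold with its direction.
biomarker_ranges <- function() {
  tibble(
    feature   = c("fft_theta_max_power", "wavelet_detailed_entropy",
                  "mobility", "complexity", "delta_alpha_ratio"),
    normal_lo = c(0.0005, 0.0012, 0.30, 4.0, 50),
    normal_hi = c(0.0007, 0.0015, 0.40, 5.0, 70),
    threshold = c(0.0007, 0.0012, 0.30, 4.0, 70),
    direction = c("high", "low", "low", "low", "high")
  )
}
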