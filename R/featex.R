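# Multi-domain EEG feature extraction: per-region statistical, spectral and
# wavelet features, direction-aware cross-region aggregation, and a fixed
# positive-affine calibration onto the published unit scales.

#' Statistical descriptors of a signal
#'
#' Sample moments of the amplitude distribution: min, max, SD, mean, median,
#' skewness (bias-uncorrected g1), excess kurtosis (Gaussian -> 0), and the
#' coefficient of variation SD/mean. Skewness/kurtosis of a constant signal
#' and the CV at (numerically) zero mean are undefined and reported as NA
#' sentinels with a classed warning.
#'
#' @param x Numeric signal, length >= 4.
#' @return One-row tibble with columns `min`, `max`, `std`, `mean`,
#'   `median`, `skewness`, `kurtosis`, `coeff_variation`.
#' @export
#' @examples
#' statistical_features(c(1, 2, 3, 4, 5))
statistical_features <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < 4) abort("statistical_features() needs length >= 4")
  m <- mean(x)
  s <- stats::sd(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    skew <- sentinel("skewness", "constant signal")
    kurt <- sentinel("kurtosis", "constant signal")
  } else {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  }
  cv <- if (abs(m) < 1e-12 * s)
    sentinel("coeff_variation", "mean numerically zero")
  else s / m
  tibble(min = min(x), max = max(x), std = s, mean = m,
         median = stats::median(x), skewness = skew, kurtosis = kurt,
         coeff_variation = cv)
}

#' Hjorth parameters
#'
#' Activity = sample variance; mobility = sqrt(var(diff(x)) / var(x)), a
#' root-mean-square frequency proxy; complexity = mobility(diff(x)) /
#' mobility(x), a bandwidth/form-factor measure. Both mobility and
#' complexity are invariant to amplitude scaling.
#'
#' @param x Numeric signal, length >= 3, non-constant.
#' @return One-row tibble with `activity`, `mobility`, `complexity`.
#' @export
#' @examples
#' hjorth_parameters(sin(0.1 * 1:5000))$mobility  # ~2*sin(0.05)
hjorth_parameters <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < 3) abort("hjorth_parameters() needs length >= 3")
  v0 <- stats::var(x)
  if (v0 == 0) abort("hjorth_parameters() undefined for a constant signal")
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  tibble(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' First/second difference magnitude features
#'
#' Max and mean of `|diff(x)|` and `|diff(x, differences = 2)|`.
#'
#' @param x Numeric signal, length >= 3.
#' @return One-row tibble with `diff1_max`, `diff2_max`, `diff1_mean`,
#'   `diff2_mean`.
#' @export
difference_features <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < 3) abort("difference_features() needs length >= 3")
  a1 <- abs(diff(x))
  a2 <- abs(diff(x, differences = 2))
  tibble(diff1_max = max(a1), diff2_max = max(a2),
         diff1_mean = mean(a1), diff2_mean = mean(a2))
}

#' Welch-PSD band features
#'
#' Band maximum PSD values ("FFT band max power") and total band powers for
#' the five rhythm bands (half-open `[low, high)` intervals), plus the
#' delta/alpha total-power ratio. Based on [welch_psd()] (Hann, 512-sample
#' segments, 50% overlap).
#'
#' @param x Numeric signal (length >= 1024).
#' @param fs Sampling rate (>= 128 Hz).
#' @return One-row tibble: `fft_<band>_max_power` for delta/theta/alpha/
#'   beta, `<band>_power` totals for all five bands, `delta_alpha_ratio`.
#' @export
welch_band_features <- function(x, fs) {
  if (fs < 128) abort("welch_band_features() requires fs >= 128 Hz")
  psd <- welch_psd(x, fs)
  bands <- eeg_bands()
  maxp <- purrr::pmap_dbl(bands, function(band, low, high)
    band_max_power(psd, low, high))
  totp <- purrr::pmap_dbl(bands, function(band, low, high)
    band_power(psd, low, high))
  names(maxp) <- names(totp) <- bands$band
  ratio <- if (totp["alpha"] <= 0)
    sentinel("delta_alpha_ratio", "alpha band power is zero")
  else unname(totp["delta"] / totp["alpha"])
  tibble(
    fft_delta_max_power = maxp[["delta"]],
    fft_theta_max_power = maxp[["theta"]],
    fft_alpha_max_power = maxp[["alpha"]],
    fft_beta_max_power  = maxp[["beta"]],
    delta_power = totp[["delta"]], theta_power = totp[["theta"]],
    alpha_power = totp[["alpha"]], beta_power = totp[["beta"]],
    gamma_power = totp[["gamma"]],
    delta_alpha_ratio = ratio
  )
}

#' STFT spectral complexity
#'
#' Mean over STFT time frames (128-sample Hann segments, 50% overlap) of the
#' Shannon entropy (nats) of each frame's normalized power spectrum. Near 0
#' for a pure tone, near `log(n_bins)` for broadband noise.
#'
#' @param x Numeric signal, length >= 256.
#' @param fs Sampling rate in Hz.
#' @return Scalar spectral complexity (NA sentinel for silent input).
#' @export
stft_spectral_complexity <- function(x, fs) {
  if (length(x) < 256) abort("stft_spectral_complexity() needs length >= 256")
  s <- stft_power(x, fs)
  ent <- apply(s$power, 2, shannon_entropy)
  if (all(is.na(ent)))
    return(sentinel("signal_complexity_spectral", "silent signal"))
  mean(ent, na.rm = TRUE)
}

#' db4 wavelet features
#'
#' Five-level db4 decomposition ([dwt_db4()]). The detailed entropy is the
#' Shannon entropy of the energy distribution across the five detail levels,
#' divided by the total number of detail coefficients (an entropy density,
#' which the packaged calibration then maps onto the published 1e-3 scale);
#' the approximate mean is the mean level-5 approximation coefficient.
#'
#' @param x Numeric signal (length a multiple of 32, >= 32).
#' @return One-row tibble with `wavelet_detailed_entropy`,
#'   `wavelet_approximate_mean`.
#' @export
wavelet_features <- function(x) {
  dec <- dwt_db4(x, levels = 5)
  energies <- vapply(dec$details, function(d) sum(d^2), numeric(1))
  n_detail <- sum(lengths(dec$details))
  ent <- if (sum(energies) <= 0)
    sentinel("wavelet_detailed_entropy", "zero detail energy")
  else shannon_entropy(energies) / n_detail
  tibble(wavelet_detailed_entropy = ent,
         wavelet_approximate_mean = mean(dec$approximation))
}

# All per-region features for one signal: the 22 registry per-region
# features plus band total powers and STFT entropy needed downstream.
region_features <- function(x, fs) {
  dplyr::bind_cols(
    statistical_features(x)[, c("min", "max", "std", "mean", "median",
                                "kurtosis", "skewness", "coeff_variation")],
    hjorth_parameters(x),
    difference_features(x),
    welch_band_features(x, fs),
    wavelet_features(x),
    tibble(stft_entropy = stft_spectral_complexity(x, fs))
  )
}

#' Derived cross-regional features
#'
#' From a per-region table of band total powers (and optionally per-region
#' Hjorth activity and STFT entropy): region-averaged band powers for all
#' five bands, Hjorth activity averaged across regions, mean STFT spectral
#' complexity, the anterior-posterior alpha asymmetry
#' `(anterior - posterior) / (anterior + posterior)` with anterior =
#' frontal + prefrontal and posterior = parietal + occipital, and the
#' theta/alpha ratio of region-averaged powers.
#'
#' @param region_tbl Tibble with a `region` column covering all six regions
#'   and columns `delta_power` ... `gamma_power`; optional `activity`,
#'   `stft_entropy`.
#' @return One-row tibble with the nine derived features.
#' @export
#' @examples
#' tbl <- tidyr::expand_grid(region = eeg_regions()) |>
#'   dplyr::mutate(delta_power = 1, theta_power = 1, alpha_power = 1,
#'                 beta_power = 1, gamma_power = 1)
#' derived_features(tbl)$regional_power_asymmetry  # 0
derived_features <- function(region_tbl) {
  check_regions(region_tbl)
  need <- paste0(eeg_bands()$band, "_power")
  missing <- setdiff(need, names(region_tbl))
  if (length(missing))
    abort(paste("derived_features() missing band power columns:",
                paste(missing, collapse = ", ")))
  avg <- function(col) mean(region_tbl[[col]], na.rm = TRUE)
  alpha <- stats::setNames(region_tbl$alpha_power, region_tbl$region)
  ant <- sum(alpha[c("frontal", "prefrontal")])
  post <- sum(alpha[c("parietal", "occipital")])
  asym <- if ((ant + post) <= 0)
    sentinel("regional_power_asymmetry", "zero anterior+posterior alpha power")
  else (ant - post) / (ant + post)
  ap <- avg("alpha_power")
  tar <- if (ap <= 0)
    sentinel("theta_alpha_ratio", "alpha band power is zero")
  else avg("theta_power") / ap
  tibble(
    theta_band_power = avg("theta_power"),
    alpha_band_power = ap,
    delta_band_power = avg("delta_power"),
    beta_band_power  = avg("beta_power"),
    gamma_band_power = avg("gamma_power"),
    hjorth_activity  = if ("activity" %in% names(region_tbl))
      avg("activity") else NA_real_,
    signal_complexity_spectral = if ("stft_entropy" %in% names(region_tbl))
      avg("stft_entropy") else NA_real_,
    regional_power_asymmetry = asym,
    theta_alpha_ratio = tar
  )
}

check_regions <- function(region_tbl) {
  if (!"region" %in% names(region_tbl))
    abort("per-region table needs a `region` column")
  missing <- setdiff(eeg_regions(), region_tbl$region)
  if (length(missing))
    abort(paste("missing region(s):", paste(missing, collapse = ", ")))
  invisible(region_tbl)
}

#' Direction-aware cross-region aggregation
#'
#' Collapses a per-region feature table to one value per feature using the
#' registry rules: maximum across regions for delta/alpha ratio and FFT
#' theta max power (depression-when-high), minimum for mobility, complexity
#' and wavelet detailed entropy (depression-when-low), mean for everything
#' else. NA sentinels are excluded from means; a feature that is a sentinel
#' in every region stays a sentinel.
#'
#' @param region_tbl Tibble with a `region` column (all six regions) and one
#'   column per per-region feature.
#' @return One-row tibble of aggregated features.
#' @export
#' @examples
#' tbl <- tibble::tibble(region = eeg_regions(),
#'                       mobility = c(0.30, 0.25, 0.40, 0.35, 0.33, 0.31))
#' aggregate_regions(tbl)$mobility  # 0.25
aggregate_regions <- function(region_tbl) {
  check_regions(region_tbl)
  reg <- feature_registry()
  feats <- intersect(names(region_tbl), reg$feature)
  if (!length(feats)) abort("no registry feature columns to aggregate")
  rule <- stats::setNames(reg$aggregation, reg$feature)
  out <- purrr::map_dbl(feats, function(f) {
    v <- region_tbl[[f]]
    if (all(is.na(v))) return(NA_real_)
    switch(rule[[f]],
           max  = max(v, na.rm = TRUE),
           min  = min(v, na.rm = TRUE),
           mean = mean(v, na.rm = TRUE))
  })
  as_tibble(as.list(stats::setNames(out, feats)))
}

#' Identity calibration map
#'
#' @return A calibration tibble (`feature`, `scale`, `offset`) with scale 1
#'   and offset 0 for all 31 features.
#' @export
neutral_calibration <- function() {
  tibble(feature = feature_registry()$feature, scale = 1, offset = 0)
}

#' Apply a positive-affine calibration map to feature values
#'
#' @param values One-row tibble (or list) of feature values.
#' @param calibration Calibration tibble (`feature`, `scale`, `offset`);
#'   scales must be strictly positive.
#' @return The calibrated values.
#' @export
apply_calibration <- function(values, calibration) {
  stopifnot(all(c("feature", "scale", "offset") %in% names(calibration)))
  if (any(calibration$scale <= 0))
    abort("calibration scales must be strictly positive")
  for (i in seq_len(nrow(calibration))) {
    f <- calibration$feature[i]
    if (f %in% names(values))
      values[[f]] <- values[[f]] * calibration$scale[i] + calibration$offset[i]
  }
  values
}

#' Extract the 31 aggregated features from one recording
#'
#' Runs all per-region feature operations on each of the six region signals,
#' aggregates across regions with the direction-aware rules, computes the
#' nine derived cross-regional features, and applies the per-feature
#' positive-affine calibration.
#'
#' @param recording An `eeg_recording` (see [synthesize_recording()]).
#' @param calibration Calibration tibble (`feature`, `scale`, `offset`);
#'   defaults to the packaged calibration [default_calibration()].
#' @return One-row tibble: `subject_id`, the 31 features, `label` (if the
#'   recording carries one).
#' @export
extract_features <- function(recording, calibration = default_calibration()) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- attr(recording, "sampling_rate")
  region_tbl <- purrr::map_dfr(eeg_regions(), function(r) {
    dplyr::bind_cols(tibble(region = r), region_features(recording[[r]], fs))
  })
  agg <- aggregate_regions(region_tbl)
  der <- derived_features(region_tbl)
  vals <- dplyr::bind_cols(agg[, setdiff(names(agg), names(der))], der)
  vals <- apply_calibration(vals, calibration)
  vals <- vals[, feature_registry()$feature]
  out <- dplyr::bind_cols(
    tibble(subject_id = attr(recording, "subject_id") %||% NA_character_),
    vals
  )
  lab <- attr(recording, "label")
  if (!is.null(lab)) out$label <- as.integer(lab)
  out
}

#' Extract a feature table for a whole cohort
#'
#' Accepts either a materialized `eeg_cohort` or a [cohort_spec()] (in which
#' case subjects are synthesized and extracted one at a time, keeping memory
#' flat).
#'
#' @param cohort An `eeg_cohort`, or a `cohort_spec`.
#' @param calibration Calibration tibble; default packaged calibration.
#' @param profiles Class profiles, used only when `cohort` is a spec.
#' @return Tibble: `subject_id`, 31 features, `label`.
#' @export
extract_feature_table <- function(cohort,
                                  calibration = default_calibration(),
                                  profiles = default_class_profiles()) {
  if (inherits(cohort, "cohort_spec")) {
    manifest <- cohort_manifest(cohort)
    return(purrr::pmap_dfr(manifest, function(subject_id, label, seed) {
      prof <- if (label == 1L) profiles$depressed else profiles$control
      rec <- synthesize_recording(prof, cohort, seed, subject_id = subject_id)
      extract_features(rec, calibration)
    }))
  }
  stopifnot(inherits(cohort, "eeg_cohort"))
  purrr::map_dfr(cohort$recordings, extract_features, calibration = calibration)
}
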