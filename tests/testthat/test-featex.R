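# Per-signal feature extractors, checked against closed forms, hand
# arithmetic, Monte-Carlo oracles, and frozen PyWavelets reference values.

test_that("statistical features match hand values and flag degeneracies", {
  f <- statistical_features(c(1, 2, 3, 4, 5))
  expect_equal(f$mean, 3)
  expect_equal(f$median, 3)
  expect_equal(f$min, 1)
  expect_equal(f$max, 5)
  expect_equal(f$skewness, 0)
  # constant input: spread moments undefined
  expect_warning(
    expect_warning(fc <- statistical_features(rep(1, 4)), "skewness"),
    "kurtosis")
  expect_equal(fc$std, 0)
  expect_true(is.na(fc$skewness) && is.na(fc$kurtosis))
  # zero-mean input: CV sentinel
  expect_warning(fz <- statistical_features(c(-2, -1, 1, 2)), "coeff_variation")
  expect_true(is.na(fz$coeff_variation))
})

test_that("skewness and excess kurtosis vanish for a large Gaussian sample", {
  x <- neurodep:::with_local_seed(2024, stats::rnorm(1e6))
  f <- statistical_features(x)
  expect_lt(abs(f$skewness), 0.01)
  expect_lt(abs(f$kurtosis), 0.02)
})

test_that("Hjorth parameters match their closed forms", {
  # iid white noise: var(diff) = 2 sigma^2, so mobility -> sqrt(2)
  x <- neurodep:::with_local_seed(11, stats::rnorm(1e6))
  h <- hjorth_parameters(x)
  expect_equal(h$mobility, sqrt(2), tolerance = 0.01)
  # sinusoid: first difference has amplitude 2 sin(omega/2)
  n <- 0:(2e5 - 1)
  hs <- hjorth_parameters(sin(0.1 * n))
  expect_equal(hs$mobility, 2 * sin(0.05), tolerance = 1e-3)
  # amplitude scaling: activity x25, mobility/complexity invariant
  y <- x[1:10000]
  h1 <- hjorth_parameters(y); h5 <- hjorth_parameters(5 * y)
  expect_equal(h5$activity, 25 * h1$activity)
  expect_equal(h5$mobility, h1$mobility)
  expect_equal(h5$complexity, h1$complexity)
  expect_error(hjorth_parameters(rep(2, 10)), "constant")
})

test_that("difference features match hand arithmetic", {
  f <- difference_features(c(0, 1, 0, 1))
  expect_equal(f$diff1_max, 1)
  expect_equal(f$diff1_mean, 1)
  f2 <- difference_features(c(0, 1, 3, 6))
  expect_equal(f2$diff1_max, 3)
  expect_equal(f2$diff1_mean, 2)
  expect_equal(f2$diff2_max, 1)
  expect_equal(f2$diff2_mean, 1)
  fc <- difference_features(rep(4, 10))
  expect_true(all(unlist(fc) == 0))
})

test_that("Welch band features localize tones and integrate power", {
  fs <- 256
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  # pure 10 Hz tone: alpha max is the global PSD max, delta/alpha tiny
  x <- sin(2 * pi * 10 * t)
  w <- welch_band_features(x, fs)
  psd <- welch_psd(x, fs)
  expect_equal(w$fft_alpha_max_power, max(psd$psd))
  expect_lt(w$delta_alpha_ratio, 0.1)
  # equal-amplitude 2 Hz + 10 Hz tones: power ratio 1 within 5%
  x2 <- sin(2 * pi * 2 * t) + sin(2 * pi * 10 * t)
  w2 <- welch_band_features(x2, fs)
  expect_equal(w2$delta_alpha_ratio, 1, tolerance = 0.05)
})

test_that("band edges are half-open: theta counted over [4, 8)", {
  # spectral mass exactly on an edge frequency belongs to the upper band
  psd <- tibble::tibble(freq = seq(0, 128, by = 0.5), psd = 0)
  psd$psd[psd$freq == 4] <- 1
  expect_equal(band_power(psd, 0, 4), 0)
  expect_gt(band_power(psd, 4, 8), 0)
  psd$psd[] <- 0; psd$psd[psd$freq == 8] <- 1
  expect_equal(band_power(psd, 4, 8), 0)
  expect_gt(band_power(psd, 8, 13), 0)
  expect_equal(band_max_power(psd, 8, 13), 1)
})

test_that("Welch total power satisfies Parseval within 10%", {
  x <- neurodep:::with_local_seed(5, stats::rnorm(15360))
  psd <- welch_psd(x, 256)
  total <- sum(psd$psd) * (psd$freq[2] - psd$freq[1])
  expect_equal(total, stats::var(x), tolerance = 0.1)
})

test_that("STFT spectral complexity behaves at the two extremes", {
  fs <- 256
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tone <- stft_spectral_complexity(sin(2 * pi * 10 * t), fs)
  nbins <- 65
  expect_lt(tone, 0.25 * log(nbins))
  noise <- stft_spectral_complexity(
    neurodep:::with_local_seed(6, stats::rnorm(1e5)), fs)
  # per-frame periodogram entropy of white noise sits just below log(nbins)
  # (finite-sample deficit of a chi-squared spectrum); simulated oracle band
  expect_gt(noise, 0.88 * log(nbins))
  expect_lt(noise, log(nbins))
  # frame count: (2560 - 128)/64 + 1 = 39
  s <- stft_power(stats::rnorm(2560), fs)
  expect_equal(ncol(s$power), 39)
})

test_that("db4 decomposition matches frozen PyWavelets reference energies", {
  x <- neurodep:::with_local_seed(20259, round(stats::rnorm(256), 6))
  dec <- dwt_db4(x, levels = 5)
  expect_equal(lengths(dec$details), c(128, 64, 32, 16, 8))
  energies <- vapply(dec$details, function(d) sum(d^2), numeric(1))
  # reference energies computed once with PyWavelets (db4, periodization)
  expect_equal(energies,
               c(124.9399123507, 80.4024226927, 29.1071782972,
                 19.6048620256, 8.2330968533), tolerance = 1e-8)
  expect_equal(mean(dec$approximation), -0.938046640582, tolerance = 1e-9)
  # orthonormal + periodization: energy is conserved exactly
  expect_equal(sum(energies) + sum(dec$approximation^2), sum(x^2),
               tolerance = 1e-10)
})

test_that("wavelet features handle degenerate and concentrated signals", {
  expect_warning(wz <- wavelet_features(rep(0, 64)), "wavelet")
  expect_equal(wz$wavelet_approximate_mean, 0)
  expect_true(is.na(wz$wavelet_detailed_entropy))
  # low-frequency tone: detail energy concentrated in one level
  t <- seq(0, 8 - 1 / 256, by = 1 / 256)
  wt <- wavelet_features(sin(2 * pi * 6 * t))
  n_detail <- sum(2048 / 2^(1:5))
  expect_lt(wt$wavelet_detailed_entropy, 0.3 * log(5) / n_detail)
  expect_error(wavelet_features(rep(1, 16)), "at least")
})

test_that("derived features follow their formulas", {
  tbl <- tibble::tibble(region = eeg_regions(),
                        delta_power = 1, theta_power = c(1, 2, 3, 4, 5, 6),
                        alpha_power = 1, beta_power = 1, gamma_power = 1)
  d <- derived_features(tbl)
  expect_equal(d$theta_band_power, 3.5)
  expect_equal(d$regional_power_asymmetry, 0)
  # anterior alpha 3, posterior 1 -> asymmetry 0.5
  tbl2 <- tbl
  tbl2$alpha_power <- c(1.5, 9, 9, 0.5, 0.5, 1.5)  # ant 3, post 1
  expect_equal(derived_features(tbl2)$regional_power_asymmetry, 0.5)
  expect_error(derived_features(tbl[-2, ]), "central")
})

test_that("regional aggregation applies the three rules exactly", {
  tbl <- tibble::tibble(region = eeg_regions(),
                        mobility = c(0.30, 0.25, 0.40, 0.35, 0.33, 0.31))
  expect_equal(aggregate_regions(tbl)$mobility, 0.25)
  tbl$delta_alpha_ratio <- rep(60, 6)
  expect_equal(aggregate_regions(tbl)$delta_alpha_ratio, 60)
  expect_error(aggregate_regions(tbl[-1, ]), "frontal")
})

test_that("aggregation equals an independent brute-force reimplementation", {
  reg_feats <- neurodep:::per_region_features()
  for (i in 1:10) {
    vals <- neurodep:::with_local_seed(100 + i,
      matrix(stats::runif(6 * length(reg_feats)), nrow = 6))
    tbl <- dplyr::bind_cols(tibble::tibble(region = eeg_regions()),
                            tibble::as_tibble(as.data.frame(
                              stats::setNames(as.data.frame(vals), reg_feats))))
    got <- aggregate_regions(tbl)
    want <- oracle_aggregate(tbl)
    expect_equal(unlist(got[names(want)]), want)
    # order statistics: min <= mean <= max across regions per feature
    for (f in reg_feats) {
      expect_lte(min(tbl[[f]]), mean(tbl[[f]]))
      expect_lte(mean(tbl[[f]]), max(tbl[[f]]))
    }
  }
})

test_that("extraction yields all 31 registry features, calibration is affine", {
  sp <- tiny_spec()
  rec <- synthesize_recording(default_class_profiles()$control, sp, 7)
  raw <- extract_features(rec, neutral_calibration())
  expect_setequal(setdiff(names(raw), c("subject_id", "label")),
                  feature_registry()$feature)
  cal <- extract_features(rec)
  # calibration is positive-affine per feature: sign of differences is kept
  cc <- default_calibration()
  for (f in c("mobility", "delta_alpha_ratio")) {
    s <- cc$scale[cc$feature == f]
    expect_equal(cal[[f]], raw[[f]] * s, tolerance = 1e-12)
  }
  expect_error(
    apply_calibration(raw, tibble::tibble(feature = "mobility", scale = -1,
                                          offset = 0)),
    "positive")
})

test_that("calibration cannot flip class mean differences (neutrality)", {
  # any positive-scale affine map preserves the sign of group differences
  d0 <- c(mobility = 0.35, delta_alpha_ratio = 55)
  d1 <- c(mobility = 0.28, delta_alpha_ratio = 90)
  cal <- default_calibration()
  for (f in names(d0)) {
    s <- cal$scale[cal$feature == f]; o <- cal$offset[cal$feature == f]
    expect_equal(sign((d1[[f]] * s + o) - (d0[[f]] * s + o)),
                 sign(d1[[f]] - d0[[f]]))
  }
})
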