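test_that("cohort spec validates its invariants with explanatory errors", {
  expect_error(cohort_spec(n_per_class = 0), "n_per_class")
  expect_error(cohort_spec(sampling_rate = 80), "100 Hz")
  expect_error(cohort_spec(duration = 1, sampling_rate = 256), "degenerate")
  sp <- cohort_spec(n_per_class = 3, duration = 4, seed = 9)
  expect_s3_class(sp, "cohort_spec")
})

test_that("packaged profiles inject the documented effect directions", {
  pr <- default_class_profiles()
  ctrl <- pr$control; dep <- pr$depressed
  expect_equal(attr(ctrl, "label"), 0L)
  expect_equal(attr(dep, "label"), 1L)
  # control alpha gain exceeds delta gain in every region
  expect_true(all(ctrl$alpha > ctrl$delta))
  # depressed: strictly higher delta/theta, strictly lower alpha, per region
  expect_true(all(dep$delta > ctrl$delta))
  expect_true(all(dep$theta > ctrl$theta))
  expect_true(all(dep$alpha < ctrl$alpha))
  # injected slowing: depressed delta/alpha gain ratio exceeds control's
  expect_true(all(dep$delta / dep$alpha > ctrl$delta / ctrl$alpha))
})

test_that("recordings are deterministic, finite, and correctly shaped", {
  sp <- tiny_spec()
  pr <- default_class_profiles()
  r1 <- synthesize_recording(pr$control, sp, subject_seed = 42)
  r2 <- synthesize_recording(pr$control, sp, subject_seed = 42)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 8 * 256)
  expect_true(all(eeg_regions() %in% names(r1)))
  expect_true(all(is.finite(as.matrix(r1[eeg_regions()]))))
  r3 <- synthesize_recording(pr$control, sp, subject_seed = 43)
  expect_false(identical(r1$frontal, r3$frontal))
})

test_that("all-zero gains give an all-zero signal", {
  zero <- tibble::tibble(region = eeg_regions(), delta = 0, theta = 0,
                         alpha = 0, beta = 0, gamma = 0, broadband = 0)
  prof <- suppressWarnings(class_profile(zero, label = 0L))
  rec <- synthesize_recording(prof, tiny_spec(), subject_seed = 1)
  expect_true(all(as.matrix(rec[eeg_regions()]) == 0))
})

test_that("scaling all gains by c scales every region's variance by c^2", {
  pr <- default_class_profiles()$control
  sp <- tiny_spec()
  scaled <- pr
  bands <- c("delta", "theta", "alpha", "beta", "gamma", "broadband")
  scaled[bands] <- lapply(scaled[bands], function(g) 3 * g)
  scaled <- class_profile(scaled, label = 0L)
  r1 <- synthesize_recording(pr, sp, subject_seed = 5)
  r2 <- synthesize_recording(scaled, sp, subject_seed = 5)
  for (rg in eeg_regions())
    expect_equal(stats::var(r2[[rg]]), 9 * stats::var(r1[[rg]]),
                 tolerance = 1e-12)
})

test_that("single-band profiles concentrate Welch power inside the band", {
  sp <- cohort_spec(n_per_class = 1, duration = 60, seed = 1)
  bands <- eeg_bands()
  for (b in c("delta", "alpha", "gamma")) {
    gains <- tibble::tibble(region = eeg_regions(), delta = 0, theta = 0,
                            alpha = 0, beta = 0, gamma = 0, broadband = 0)
    gains[[b]] <- rep(1, 6)
    prof <- class_profile(gains, label = 0L, band_jitter_sd = 0,
                          amp_jitter_sd = 0)
    rec <- synthesize_recording(prof, sp, subject_seed = 11)
    psd <- welch_psd(rec$frontal, 256)
    row <- bands[bands$band == b, ]
    inband <- band_power(psd, row$low, row$high)
    total <- band_power(psd, 0, 128.001)
    expect_gt(inband / total, 0.9)
  }
})

test_that("cohorts are balanced with distinct deterministic subject seeds", {
  sp <- cohort_spec(n_per_class = 2, duration = 4, seed = 31)
  co <- synthesize_cohort(sp)
  expect_length(co$recordings, 4)
  expect_equal(sum(co$manifest$label == 0), 2)
  expect_equal(sum(co$manifest$label == 1), 2)
  expect_equal(anyDuplicated(co$manifest$seed), 0)
  co2 <- synthesize_cohort(sp)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(as.data.frame(co$recordings[[3]]),
                   as.data.frame(co2$recordings[[3]]))
})

test_that("cohort CSV round trip preserves signals and manifest", {
  dir <- withr::local_tempdir()
  sp <- cohort_spec(n_per_class = 1, duration = 4, seed = 77)
  co <- synthesize_cohort(sp)
  write_cohort_csv(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort_csv(dir)
  expect_equal(back$manifest$label, co$manifest$label)
  expect_equal(back$recordings[[1]]$frontal, co$recordings[[1]]$frontal,
               tolerance = 1e-12)
})

test_that("fast-path tables are deterministic with documented class means", {
  t1 <- synthesize_feature_table(30, seed = 4)
  t2 <- synthesize_feature_table(30, seed = 4)
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(60, 33))
  big <- synthesize_feature_table(600, seed = 8)
  cfg <- feature_table_config()
  ctrl <- big[big$label == 0, ]
  dep <- big[big$label == 1, ]
  # control mobility mean sits in the published normal range
  expect_gt(mean(ctrl$mobility), 0.30)
  expect_lt(mean(ctrl$mobility), 0.40)
  # depressed complexity mean is beyond the depression threshold
  expect_lt(mean(dep$complexity), 4.0)
  # sample means track the documented configuration
  for (f in c("delta_alpha_ratio", "fft_theta_max_power", "alpha_band_power")) {
    row <- cfg[cfg$feature == f, ]
    expect_equal(mean(ctrl[[f]]), row$mean_control,
                 tolerance = 4 * row$sd_control / sqrt(600) / abs(row$mean_control) + 0.01)
  }
})

test_that("21 components capture >= 95% of fast-path variance at large n", {
  tbl <- synthesize_feature_table(2500, seed = 33)
  st <- fit_standardizer(tbl)
  p <- fit_pca(standardize(st, tbl), n_components = 21)
  expect_gte(sum(p$variance_ratio), 0.95)
  # and meaningfully less than all of it: the floor dimensions are real
  expect_lt(sum(p$variance_ratio), 0.999)
})
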