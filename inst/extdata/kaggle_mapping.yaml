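# Column-mapping for wide per-region feature CSVs laid out like the public
# resting-state depression EEG feature table: one column per
# <region>_<feature> pair plus a binary label column. Per-region values are
# collapsed to the canonical 31 aggregated features with the registry
# rules (max for delta/alpha ratio and FFT theta max power, min for
# mobility/complexity/wavelet detailed entropy, mean otherwise).
format: per_region
pattern: "{region}_{feature}"
label: "label"
regions:
  frontal: "frontal"
  central: "central"
  temporal: "temporal"
  parietal: "parietal"
  occipital: "occipital"
  prefrontal: "prefrontal"
features:
  mobility: "mobility"
  complexity: "complexity"
  min: "min"
  max: "max"
  std: "std"
  mean: "mean"
  median: "median"
  activity: "activity"
  kurtosis: "kurtosis"
  skewness: "skewness"
  delta_alpha_ratio: "delta_alpha_ratio"
  fft_theta_max_power: "fft_theta_max_power"
  fft_delta_max_power: "fft_delta_max_power"
  fft_alpha_max_power: "fft_alpha_max_power"
  fft_beta_max_power: "fft_beta_max_power"
  diff1_max: "1st_difference_max"
  diff2_max: "2nd_difference_max"
  diff1_mean: "1st_difference_mean"
  diff2_mean: "2nd_difference_mean"
  coeff_variation: "coefficient_of_variation"
  wavelet_detailed_entropy: "wavelet_detailed_entropy"
  wavelet_approximate_mean: "wavelet_approximate_mean"
  theta_band_power: "theta_band_power"
  alpha_band_power: "alpha_band_power"
  delta_band_power: "delta_band_power"
  beta_band_power: "beta_band_power"
  gamma_band_power: "gamma_band_power"
  hjorth_activity: "hjorth_activity"
  signal_complexity_spectral: "signal_complexity_spectral"
  regional_power_asymmetry: "regional_power_asymmetry"
  theta_alpha_ratio: "theta_alpha_ratio"
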