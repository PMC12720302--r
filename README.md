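# neurodep

Interpretable EEG feature pipelines for depression phenotyping.

Resting-state EEG of depressed patients shows *spectral slowing*:
elevated delta/theta power, reduced alpha power, and reduced signal
complexity. `neurodep` implements, end to end and fully seeded, a
classification-plus-explanation pipeline built around that signature,
for methodologists who want a reproducible, dependency-light testbed for
EEG biomarker analysis:

1. **Synthetic cohorts** — six-region EEG recordings (frontal, central,
   temporal, parietal, occipital, prefrontal) built from band-limited
   Gaussian noise with per-class band gains, plus a fast path that samples
   feature vectors directly. The depressed class injects the slowing
   signature so that five published biomarkers cross their thresholds:
   delta/alpha ratio > 70, FFT theta max power > 0.0007, mobility < 0.30,
   complexity < 4.0, wavelet detailed entropy < 0.0012.
2. **31-feature extraction** — statistical moments, Hjorth parameters
   (activity = var(x), mobility = sqrt(var(Δx)/var(x)), complexity =
   mobility(Δx)/mobility(x)), difference magnitudes, Welch-PSD band
   features, STFT spectral entropy, five-level db4 wavelet features, and
   cross-regional derivatives, aggregated across regions direction-aware
   (max for depression-when-high markers, min for depression-when-low,
   mean otherwise).
3. **Dimensionality reduction** — standardization + PCA retaining 21
   components (≈95–97% of variance), t-SNE (perplexity 50, 300
   iterations) for class-separability display.
4. **Classification** — a lightweight 1-D CNN
   (Conv64/k3 → BN → pool → Conv128/k3 → BN → pool → Dense128-ReLU →
   Dropout 0.5 → sigmoid; 74,753 parameters) trained with Adam at lr 1e-4,
   weighted binary cross-entropy, early stopping (patience 10), LR
   reduction (factor 0.2), 70/30 stratified splits and 5-fold stratified
   cross-validation.
5. **Attribution** — Kernel SHAP over the 21 components (exact-Shapley
   oracle below 13 inputs), with importances back-projected through the
   PCA loadings onto the original EEG features:
   `importance_j = Σ_k mean|φ_k| · |L_kj|`.

Everything is implemented in plain R on top of base/stats, `signal`,
and the tidyverse; results are tibbles, fitted objects have
`tidy()`/`glance()` methods, and result types have `autoplot()` methods.

## Worked example

```r
library(neurodep)

# the default balanced 232-subject cohort, sampled on the fast path
tbl <- synthesize_feature_table(n_per_class = 116, seed = 1)

cfg <- pipeline_config(seed = 1, train = train_config(seed = 1),
                       n_explain = 2, n_coalitions = 256)
rep <- run_end_to_end(cfg, features = tbl)
rep
#> neurodep pipeline run
#>   stages: reduce -> embed -> train+evaluate -> cross-validate -> explain
#>   held-out accuracy: 97.1%
#>   CV accuracy: 93.1% ± 2.7%
#>   variance retained by 21 PCs: 97.6%
#>   top features: fft_theta_max_power, delta_alpha_ratio, wavelet_detailed_entropy

head(tidy(rep$eval), 5)
#> # A tibble: 5 × 5
#>   class             precision recall    f1 support
#>   <chr>                 <dbl>  <dbl> <dbl>   <int>
#> 1 Non-depressed (0)     0.946  1     0.972      35
#> 2 Depressed (1)         1      0.943 0.971      35
#> 3 Accuracy             NA     NA     0.971      70
#> 4 Macro Avg             0.973  0.971 0.971      70
#> 5 Weighted Avg          0.973  0.971 0.971      70
```

The held-out accuracy is computed on the 30% stratified test split (70
subjects) at the 0.5 probability threshold; the CV line is the mean ± SD
over 5 stratified folds with the standardizer, PCA and network refit
inside each fold; the top features are the back-projected SHAP
importances — the pipeline recovers the injected slowing markers (theta
peak power, delta/alpha ratio, wavelet entropy) as the most influential
features. `autoplot(rep$embedding)` draws the t-SNE scatter,
`autoplot(rep$model)` the training curves, and `autoplot(rep$tiers)` the
tiered importance chart.

At full study scale (116 subjects per class, 60 s raw recordings at
256 Hz — the default `pipeline_config()`), the same pipeline synthesizes
and extracts the cohort first and reaches ≥98% held-out accuracy; a run
takes a few minutes on one CPU.

A thin command-line interface over these functions is installed at
`exec/neurodep` (subcommands `simulate`, `extract`, `reduce`, `train`,
`cv`, `explain`, `run-all`, `report`).

## Package layout

| Area | Functions |
|---|---|
| Synthetic cohorts | `cohort_spec()`, `default_class_profiles()`, `synthesize_recording()`, `synthesize_cohort()`, `synthesize_feature_table()`, `write_cohort_csv()` |
| Features | `feature_registry()`, `extract_features()`, `extract_feature_table()`, `aggregate_regions()`, `welch_psd()`, `dwt_db4()`, `hjorth_parameters()`, `default_calibration()` |
| Reduction | `fit_standardizer()`, `standardize()`, `fit_pca()`, `pca_project()`, `tsne_embed()` |
| Classifier | `build_cnn()`, `train_cnn()`, `evaluate_model()`, `cross_validate()`, `compute_class_weights()` |
| Attribution | `kernel_shap()`, `exact_shapley()`, `explain_samples()`, `backproject_importance()`, `rank_and_bucket()` |
| Pipeline | `pipeline_config()`, `run_end_to_end()`, `make_report()`, `read_feature_csv()`, `write_feature_csv()`, `save_config()`/`load_config()` |

The methods vignette (`vignettes/neurodep-methods.Rmd`) documents the
signal model, numerical conventions, classifier design decisions, and
known limitations.
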