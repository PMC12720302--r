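# Packaged feature calibration. The five biomarkers with published ranges
# are mapped by fixed positive scales so that the *control* cohort mean of
# the aggregated feature lands on the normal-range midpoint; all other
# features keep the identity map. The constants were produced once by the
# documented calibration procedure in scripts/calibrate.R (a 200-subject
# control cohort at the default recording settings) and are frozen here;
# they are never re-fit at call time. A positive affine map is monotone and
# class-agnostic, so it reconciles units without touching class separation.

calibration_constants <- c(
  fft_theta_max_power      = 0.003092992931,
  wavelet_detailed_entropy = 14.31727942,
  mobility                 = 0.5673109328,
  complexity               = 2.056707564,
  delta_alpha_ratio        = 68.8954144
)

#' The packaged calibration map
#'
#' Per-feature positive affine constants (value * scale + offset) mapping
#' raw aggregated features onto the published unit conventions. Identity for
#' the 26 features without published ranges.
#'
#' @return Calibration tibble with columns `feature`, `scale`, `offset`.
#' @export
#' @examples
#' default_calibration()
default_calibration <- function() {
  cal <- neutral_calibration()
  idx <- match(names(calibration_constants), cal$feature)
  cal$scale[idx] <- unname(calibration_constants)
  cal
}
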