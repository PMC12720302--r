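#!/usr/bin/env Rscript
# One-time calibration procedure for the packaged feature calibration map.
#
# Procedure: synthesize a 200-subject control-class cohort at the default
# recording settings (60 s at 256 Hz), extract raw (uncalibrated) aggregated
# features, and set the scale for each of the five published biomarkers so
# the control-cohort mean lands on its normal-range midpoint (offset 0,
# scale = midpoint / raw mean). A 200-subject depressed cohort is then
# extracted for a direction/threshold report. The resulting constants are
# frozen in R/calibration.R; this script is documentation of how they were
# produced and is not run at package build, test, or call time.
suppressMessages(devtools::load_all(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), ".."), quiet = TRUE))

n_cal <- 200
spec0 <- cohort_spec(n_per_class = n_cal, duration = 60, sampling_rate = 256,
                     seed = 424242)
profiles <- default_class_profiles()

message("extracting control cohort (n = ", n_cal, ") ...")
manifest <- neurodep:::cohort_manifest(spec0)
ctrl <- manifest[manifest$label == 0L, ]
dep <- manifest[manifest$label == 1L, ]
extract_class <- function(mf, prof) {
  purrr::pmap_dfr(mf, function(subject_id, label, seed) {
    rec <- synthesize_recording(prof, spec0, seed, subject_id = subject_id)
    extract_features(rec, neutral_calibration())
  })
}
t0 <- proc.time()
f_ctrl <- extract_class(ctrl, profiles$control)
message("control done in ", round((proc.time() - t0)[3]), " s")
f_dep <- extract_class(dep, profiles$depressed)

ranges <- neurodep:::biomarker_ranges()
ranges$midpoint <- (ranges$normal_lo + ranges$normal_hi) / 2
raw_mean_ctrl <- vapply(ranges$feature, function(f) mean(f_ctrl[[f]]), numeric(1))
raw_mean_dep <- vapply(ranges$feature, function(f) mean(f_dep[[f]]), numeric(1))
scale <- ranges$midpoint / raw_mean_ctrl

report <- data.frame(
  feature = ranges$feature,
  raw_control = raw_mean_ctrl,
  raw_depressed = raw_mean_dep,
  scale = scale,
  cal_control = raw_mean_ctrl * scale,
  cal_depressed = raw_mean_dep * scale,
  threshold = ranges$threshold,
  direction = ranges$direction
)
report$crosses <- ifelse(report$direction == "high",
                         report$cal_depressed > report$threshold,
                         report$cal_depressed < report$threshold)
print(report, digits = 6)
cat("\ncalibration_constants <- c(\n")
cat(sprintf("  %s = %.10g,\n", report$feature, report$scale), sep = "")
cat(")\n")
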