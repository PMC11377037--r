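# Stage 2: event-triggered averages for the four stimulus conditions,
# the variance-ratio quality gate (>= 10 on a center condition), and
# sparse-PCA denoising with 8 condition-interpretable components.

source("analysis/common.R")
cfg <- analysis_config()

run_pipeline(cfg, stages = "eta")

q <- read.csv(file.path(cfg$out_dir, "eta_quality.csv"))
mse <- read.csv(file.path(cfg$out_dir, "pca_mse_curve.csv"))
report("quality gate: %d of %d neurons included (max center quality median %.1f)",
       sum(q$include), nrow(q),
       median(pmax(q$quality_green_c, q$quality_uv_c)))
report("sparse-PCA reconstruction mse: %.2e at 8 PCs (%.2e at 12)",
       mse$mse[mse$n == 8], mse$mse[mse$n == 12])
stopifnot(all(diff(mse$mse) <= 1e-12))  # monotone in component count
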