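# Stage 6: spatial receptive fields from the sparse-noise paradigm:
# 8 x 5 spatial ETAs, the prediction-correlation gate (r > 0.25),
# 40 x 25 upsampled peak-normalized maps, and the overlap index against
# the 37.5-degree center spot of the color-noise stimulus.

source("analysis/common.R")
cfg <- analysis_config()

run_pipeline(cfg, stages = "spatial")

srf <- read.csv(file.path(cfg$out_dir, "spatial_rf.csv"))
inc <- srf[srf$include, ]
report("included %d of %d neurons (prediction r > 0.25)", nrow(inc), nrow(srf))
report("%.0f%% of included RFs overlap the center spot by more than 2/3",
       100 * mean(inc$overlap > 2 / 3, na.rm = TRUE))
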