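# Stage 1: generate the balanced 4-channel color-noise stimulus and a
# ground-truth population of 17 planted response types, then simulate
# deconvolved event-rate responses through the rectified LN model.

source("analysis/common.R")
cfg <- analysis_config()

run_pipeline(cfg, stages = c("stimulus", "simulate"))

neurons <- read.csv(file.path(cfg$out_dir, "neurons.csv"))
report("simulated %d neurons (%d anterior / %d posterior) across %d types",
       nrow(neurons), sum(neurons$field == "anterior"),
       sum(neurons$field == "posterior"), length(unique(neurons$type_id)))
report("stimulus: %d s of 4-channel balanced binary noise at %d Hz",
       cfg$stimulus$duration_s, cfg$stimulus$rate_hz)
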