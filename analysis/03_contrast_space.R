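# Stage 3: map every included neuron into the 2-D luminance/color contrast
# space (signed green vs UV peak amplitudes, center and surround), compute
# spectral contrast, and split population variance between the luminance
# (diagonal) and color (off-diagonal) axes.

source("analysis/common.R")
cfg <- analysis_config()

run_pipeline(cfg, stages = "contrast")

pts <- read.csv(file.path(cfg$out_dir, "contrast_points.csv"))
vs <- jsonlite::read_json(file.path(cfg$out_dir, "variance_split.json"))
opp_c <- mean(grepl("^color", pts$quadrant_c))
report("center: %.0f%% luminance / %.0f%% color axis variance; %.1f%% of neurons in color quadrants",
       100 * vs$center$fraction_luminance, 100 * vs$center$fraction_color,
       100 * opp_c)
report("surround: %.0f%% luminance / %.0f%% color axis variance",
       100 * vs$surround$fraction_luminance, 100 * vs$surround$fraction_color)
report("mean spectral contrast (center): %.2f", mean(pts$sc, na.rm = TRUE))
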