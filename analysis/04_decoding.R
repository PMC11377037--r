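# Stage 4: cross-validated RBF-SVM decoding of stimulus luminance (On vs
# Off) and color (UV vs green) from trial-wise population features, for
# center and surround and a range of population sizes; accuracies are
# converted to discriminability in bits.

source("analysis/common.R")
cfg <- analysis_config()

run_pipeline(cfg, stages = c("eta", "decode"))

dec <- read.csv(file.path(cfg$out_dir, "decoding.csv"))
agg <- aggregate(bits ~ compartment + target + n_neurons, dec, mean)
print(reshape(agg, idvar = c("target", "n_neurons"),
              timevar = "compartment", direction = "wide"))
n_max <- max(agg$n_neurons)
col <- agg[agg$target == "color" & agg$n_neurons == n_max, ]
report("color discriminability at n=%d: center %.3f vs surround %.3f bits",
       n_max, col$bits[col$compartment == "center"],
       col$bits[col$compartment == "surround"])
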