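# Stage 5: Gaussian-mixture clustering of the 8-d sparse-PCA weights into
# functional response types (component count selected by held-out
# likelihood over 10 splits), cortical distribution index per type, and
# the enrichment partition (even / anterior / posterior at |index| 0.3).

source("analysis/common.R")
cfg <- analysis_config()

run_pipeline(cfg, stages = c("eta", "typing"))

curve <- read.csv(file.path(cfg$out_dir, "typing_selection.csv"))
types <- read.csv(file.path(cfg$out_dir, "typing_types.csv"))
report("selected K = %d (held-out log-likelihood curve over K = %s)",
       curve$K[which.max(curve$mean_holdout_loglik)],
       paste(curve$K, collapse = ", "))
print(table(types$group))
report("most posterior-enriched type: index %.2f; most anterior: %.2f",
       min(types$index, na.rm = TRUE), max(types$index, na.rm = TRUE))
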