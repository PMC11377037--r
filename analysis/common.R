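# Shared configuration for the numbered analysis scripts. Each script runs
# one pipeline stage (cached under results/run/cache) and reports what it
# found; run them in order from the repository root:
#   Rscript analysis/01_simulate.R  ... Rscript analysis/07_object_detection.R

library(chromv1)

analysis_config <- function(seed = 1) {
  cfg <- default_config(seed)
  cfg$out_dir <- "results/run"
  cfg$stimulus$duration_s <- 900        # 15 min of 5 Hz color noise
  cfg$population$n_neurons <- 600
  cfg$population$kernel_jitter <- 0.05
  cfg$decoding$n_neurons <- c(10, 50, 200)
  cfg$typing$k_range <- c(8, 12, 17, 21)
  cfg$typing$selection_restarts <- 1
  cfg$typing$final_restarts <- 5
  cfg$sparse$repeats <- 20
  cfg$objects$n_scenes <- 1000          # 1000 object + 1000 noise scenes
  cfg
}

report <- function(...) cat(sprintf(...), "\n")
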