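# Shared fixture builders. Everything is generated in code at test time;
# scales are kept small where a property does not depend on the full
# paper-scale run (the acceptance suite uses the stated scales).

# A short balanced noise stimulus (5 min) shared by several files.
fixture_stim <- function(duration_s = 300, seed = 101) {
  make_color_noise(duration_s = duration_s, rate_hz = 5, seed = seed)
}

# Construct a population object by hand from an explicit kernel array,
# bypassing the catalog (used for delta-kernel and linearity checks).
manual_population <- function(kernels, gain = 1, noise_sd = 0, baseline = 0,
                              field = "posterior", seed = 1) {
  n <- dim(kernels)[3]
  spec <- population_spec(n, noise_sd = noise_sd, baseline = baseline,
                          gain_sdlog = 0, seed = seed)
  neurons <- data.frame(
    neuron_id = seq_len(n), type_id = 1L, type_name = "manual",
    category = "manual", field = rep_len(field, n),
    gain = rep_len(gain, n), rf_x_deg = 0, rf_y_deg = 0,
    rf_sd_deg = spec$rf_sd_deg, stringsAsFactors = FALSE
  )
  structure(list(neurons = neurons, kernels = kernels, spec = spec),
            class = "population")
}

# Build an eta_set directly from a neurons x (4 * n_lag) coefficient matrix
# (for sparse-PCA recovery tests on noise-free synthetic ETAs).
manual_eta_set <- function(X, n_lag = 76, lag0_bin = 16) {
  n <- nrow(X)
  eta <- array(0, c(n_lag, 4L, n),
               dimnames = list(NULL, c("GreenC", "UVC", "GreenS", "UVS"), NULL))
  for (i in seq_len(n)) eta[, , i] <- matrix(X[i, ], n_lag, 4L)
  structure(
    list(eta = eta,
         lag_s = (seq_len(n_lag) - lag0_bin) / 30,
         excluded_zero = rep(FALSE, n),
         include = rep(TRUE, n),
         neurons = data.frame(neuron_id = seq_len(n),
                              field = rep("posterior", n))),
    class = "eta_set"
  )
}

# Balanced symmetric binary confusion table at a given accuracy.
symmetric_confusion <- function(accuracy, n = 1000) {
  correct <- round(n * accuracy)
  matrix(c(correct, n - correct, n - correct, correct), 2)
}

binary_entropy <- function(p) {
  ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
}
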