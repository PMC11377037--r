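test_that("population sampling follows the planted mixing structure", {
  cat2 <- default_type_catalog()[c(1, 4), ]
  cat2$weight <- c(0.5, 0.5)
  pop <- sample_population(population_spec(10000, catalog = cat2, seed = 2))
  counts <- table(pop$neurons$type_id)
  # binomial oracle: 3 s.d. of Binomial(10000, 0.5)
  sd3 <- 3 * sqrt(10000 * 0.25)
  expect_lt(abs(counts[[1]] - 5000), sd3)

  cat1 <- default_type_catalog()[14, ]
  cat1$weight <- 1
  cat1$p_anterior <- 0
  pop1 <- sample_population(population_spec(100, catalog = cat1, seed = 3))
  expect_true(all(pop1$neurons$field == "posterior"))
  expect_equal(distribution_index(0, 1), -1)

  expect_error(population_spec(10, catalog = default_type_catalog()[0, ]),
               "non-empty")
})

test_that("planted kernels are causal with center-surround antagonism", {
  pop <- sample_population(population_spec(40, seed = 5))
  expect_true(all(pop$kernels[1, , ] == 0))  # zero at lag 0 by profile shape
  cat_ <- default_type_catalog()
  peak_sign <- function(k) sign(k[which.max(abs(k))])
  for (i in seq_len(40)) {
    tid <- pop$neurons$type_id[i]
    if (cat_$green_s[tid] != 0) {
      expect_equal(peak_sign(pop$kernels[, "GreenC", i]),
                   -peak_sign(pop$kernels[, "GreenS", i]))
    }
  }
})

test_that("LN simulation obeys closed-form identities", {
  # zero kernels, zero noise, zero baseline -> all-zero response
  k0 <- array(0, c(61, 4, 2), dimnames = list(NULL, chromv1:::CHANNEL_NAMES, NULL))
  pop0 <- manual_population(k0)
  stim <- fixture_stim(60)
  r0 <- simulate_noise_responses(pop0, stim)
  expect_true(all(r0$rates == 0))

  # single positive delta kernel on GreenC: response is the shifted,
  # rectified GreenC contrast trace
  kd <- k0
  lag <- 7L
  kd[lag + 1L, "GreenC", 1] <- 1
  popd <- manual_population(kd)
  rd <- simulate_noise_responses(popd, stim)
  s30 <- chromv1:::upsample_stimulus(stim)[, "GreenC"]
  shifted <- c(rep(0, lag), s30[seq_len(length(s30) - lag)])
  expect_equal(rd$rates[, 1], pmax(shifted, 0))

  # mean rate scales linearly with gain in the supra-threshold regime
  kb <- kd
  popg1 <- manual_population(kb, gain = 1, baseline = 5)
  popg2 <- manual_population(kb, gain = 2, baseline = 5)
  m1 <- mean(simulate_noise_responses(popg1, stim)$rates[, 1] - 5)
  m2 <- mean(simulate_noise_responses(popg2, stim)$rates[, 1] - 5)
  expect_equal(m2, 2 * m1, tolerance = 1e-10)
})

test_that("forward/inverse consistency: threshold-free ETA recovers the kernel", {
  # the correlation estimator's error on a finite balanced sequence scales
  # as sqrt(n_lags / n_frames); a long stimulus updated at the analysis
  # rate (white at 30 Hz) puts it below the 0.999 bar
  stim <- make_color_noise(6000, 30, seed = 31)
  k <- array(0, c(61, 4, 2), dimnames = list(NULL, chromv1:::CHANNEL_NAMES, NULL))
  k[, , 1] <- type_kernels(c(0.7, -0.6, -0.4, 0.5))
  # neuron 2 is a zero-kernel control carrying only the baseline: its ETA
  # is exactly the balanced-regressor finite-sample bias shared by both
  # neurons, so differencing isolates the linear kernel recovery.
  # A large baseline keeps the rectification from ever binding.
  pop <- manual_population(k, baseline = 10, noise_sd = 0)
  resp <- simulate_noise_responses(pop, stim)
  es <- compute_eta(stim, resp, lag_window_s = c(-0.25, 1.5))
  causal <- which(es$lag_s >= 0)
  eta_corr <- es$eta[causal, , 1] - es$eta[causal, , 2]
  eta_vec <- as.vector(eta_corr)
  k_vec <- as.vector(k[seq_along(causal), , 1])
  cosine <- sum(eta_vec * k_vec) / sqrt(sum(eta_vec^2) * sum(k_vec^2))
  expect_gt(cosine, 0.999)
})

test_that("sparse-noise responses follow the Gaussian RF forward model", {
  cat1 <- default_type_catalog()[1, ]; cat1$weight <- 1
  spec <- population_spec(1, catalog = cat1, rf_jitter_deg = 0,
                          sparse_noise_sd = 0, seed = 7)
  pop <- sample_population(spec)
  sn <- make_sparse_noise(repeats = 2, seed = 8)
  resp <- simulate_sparse_noise_responses(pop, sn)
  cond <- sn$conditions[sn$sequence$cond_id, ]
  by_pos <- tapply(resp$rates[, 1], interaction(cond$ix, cond$iy), mean)
  # RF at screen center: central grid cells respond most
  best <- names(which.max(by_pos))
  ctr <- cond[which.min(cond$x_deg^2 + cond$y_deg^2), ]
  expect_equal(best, paste(ctr$ix, ctr$iy, sep = "."))
  # dots >= 5 sd away produce essentially no response
  far <- sqrt(cond$x_deg^2 + cond$y_deg^2) >= 5 * pop$neurons$rf_sd_deg[1]
  if (any(far)) expect_lt(max(resp$rates[far, 1]), 1e-3)
})
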