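test_that("ETA estimator identities: constant rate, single event, scaling", {
  stim <- fixture_stim(300, seed = 41)
  t_len <- 30 * 300

  # constant rate on a balanced stimulus: ETA ~ 0 at all lags
  rates <- matrix(1, t_len, 1)
  resp <- structure(list(rates = rates, rate_hz = 30,
                         neurons = data.frame(neuron_id = 1, field = "posterior"),
                         stim_seed = 41),
                    class = "response_matrix")
  es <- compute_eta(stim, resp)
  # shuffling oracle for the s.e. of a balanced-regressor mean
  n_valid <- t_len - 75
  se <- 1 / sqrt(n_valid)
  expect_lt(max(abs(es$eta[, , 1])), 3 * se * 6)  # 6 repeated 30 Hz samples per frame

  # single unit event at t0: ETA(tau) = s(t0 - tau) exactly
  r1 <- matrix(0, t_len, 1)
  t0 <- 2000L
  r1[t0, 1] <- 1
  resp1 <- structure(list(rates = r1, rate_hz = 30,
                          neurons = data.frame(neuron_id = 1, field = "posterior"),
                          stim_seed = 41),
                     class = "response_matrix")
  es1 <- compute_eta(stim, resp1)
  s30 <- chromv1:::upsample_stimulus(stim)
  lags <- round(es1$lag_s * 30)
  for (ch in 1:4) {
    expect_equal(es1$eta[, ch, 1], s30[t0 - lags, ch])
  }

  # scale invariance: c * response has the same ETA
  r2 <- resp1
  r2$rates <- r1 * 17.3
  expect_equal(compute_eta(stim, r2)$eta, es1$eta)

  # all-zero trace: flagged, never NaN
  r3 <- resp1
  r3$rates <- matrix(0, t_len, 1)
  es3 <- compute_eta(stim, r3)
  expect_true(es3$excluded_zero[1])
  expect_true(all(is.na(es3$eta[, , 1])))
})

test_that("ETA linearity: summed responses give response-weighted mean ETA", {
  stim <- fixture_stim(120, seed = 43)
  pop <- sample_population(population_spec(2, noise_sd = 0.5, seed = 44))
  resp <- simulate_noise_responses(pop, stim)
  es <- compute_eta(stim, resp)
  resp_sum <- resp
  resp_sum$rates <- cbind(resp$rates[, 1] + resp$rates[, 2])
  resp_sum$neurons <- resp$neurons[1, ]
  es_sum <- compute_eta(stim, resp_sum)
  t_idx_sums <- colSums(resp$rates[61:(nrow(resp$rates) - 15), ])
  w <- t_idx_sums / sum(t_idx_sums)
  expect_equal(es_sum$eta[, , 1],
               w[1] * es$eta[, , 1] + w[2] * es$eta[, , 2],
               tolerance = 1e-10)
})

test_that("variance-ratio quality gates neurons as specified", {
  n_lag <- 76
  base <- 1:15
  # kernel with baseline-like statistics everywhere: ratio ~ 1, excluded
  set.seed(9)
  flatk <- rnorm(n_lag)
  # kernel with a deflection 10x baseline s.d. outside the baseline
  bumpk <- c(rnorm(15, 0, 0.1), rep(0, 20), rep(1.8, 8), rep(0, 33))
  X <- rbind(c(flatk, flatk, flatk, flatk), c(bumpk, flatk, flatk, flatk))
  es <- manual_eta_set(X)
  es$include <- NULL
  es <- kernel_quality(es)
  expect_lt(es$quality[1, "GreenC"], 10)
  expect_false(es$include[1])
  # direct variance oracle
  expect_equal(unname(es$quality[2, "GreenC"]),
               var(bumpk) / var(bumpk[base]))
  expect_gt(es$quality[2, "GreenC"], 10)
  expect_true(es$include[2])

  # noiseless constant baseline: ratio -> Inf, passes with warning
  degk <- c(rep(0, 15), rep(1, 61))
  Xd <- rbind(c(degk, degk, degk, degk))
  esd <- manual_eta_set(Xd)
  expect_warning(esd <- kernel_quality(esd), "degenerate")
  expect_equal(unname(esd$quality[1, "GreenC"]), Inf)
  expect_true(esd$include[1])
})

test_that("sparse PCA recovers an exact 8-template basis and is monotone", {
  # 8 orthogonal condition-confined templates (2 temporal shapes x 4
  # conditions), noise-free weights
  n_lag <- 76
  shape1 <- sin(seq(0, pi, length.out = 20))
  shape2 <- sin(seq(0, 2 * pi, length.out = 20))
  tmpl <- matrix(0, 8, 4 * n_lag)
  for (cond in 1:4) {
    off <- (cond - 1) * n_lag + 20
    tmpl[2 * cond - 1, off + seq_along(shape1)] <- shape1
    tmpl[2 * cond, off + seq_along(shape2)] <- shape2
  }
  set.seed(12)
  W <- matrix(rnorm(60 * 8), 60, 8)
  X <- W %*% tmpl
  es <- manual_eta_set(X)
  # penalty 0: exact basis recovery; the group restriction alone carries
  # the condition structure
  basis <- fit_sparse_pca(es, n_components = 8, sparsity = 0,
                          mse_range = 2:12)
  expect_lt(basis$mse_curve$mse[basis$mse_curve$n == 8], 1e-6)
  expect_true(all(diff(basis$mse_curve$mse) <= 1e-12))
  # interpretability: every component concentrated in one condition segment
  expect_true(all(basis$attribution[, "energy"] >= 0.8))
  expect_setequal(unique(basis$attribution[, "condition"]), 1:4)

  # held-out neuron from the same templates reconstructs to < 5% of its
  # kernel variance (least-squares projection oracle)
  w_new <- rnorm(8)
  x_new <- drop(w_new %*% tmpl)
  es2 <- manual_eta_set(rbind(X, x_new))
  es2 <- apply_sparse_pca(es2, basis)
  resid <- es2$recon[, , 61] - es2$eta[, , 61]
  expect_lt(mean(resid^2), 0.05 * var(x_new))
})

test_that("simulated-neuron ETA recovery exceeds r = 0.9 at matched noise", {
  stim <- make_color_noise(1500, 5, seed = 46)
  pop <- sample_population(population_spec(30, noise_sd = 1, seed = 47))
  resp <- simulate_noise_responses(pop, stim)
  es <- kernel_quality(compute_eta(stim, resp))
  causal <- which(es$lag_s >= 0)[1:61]
  r <- sapply(which(es$include), function(i) {
    sapply(1:4, function(ch) {
      k <- pop$kernels[, ch, i]
      if (sd(k) == 0) return(NA_real_)
      cor(es$eta[causal, ch, i], k)
    })
  })
  expect_gt(min(apply(r, 1, median, na.rm = TRUE)), 0.9)
})
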