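test_that("color noise is exactly balanced, independent and seed-deterministic", {
  stim <- make_color_noise(duration_s = 1500, rate_hz = 5, seed = 1)
  expect_equal(stim$frames, 7500)
  expect_true(all(colSums(stim$channels) == stim$frames / 2))
  # pairwise independence (planted by construction)
  cc <- cor(stim_contrast(stim))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  # determinism
  expect_identical(stim$channels,
                   make_color_noise(1500, 5, seed = 1)$channels)

  # expected Hamming distance of two independent balanced sequences:
  # exhaustive enumeration at frames = 8
  seqs <- t(combn(8, 4, function(idx) {
    v <- integer(8); v[idx] <- 1L; v
  }))
  ham <- outer(seq_len(nrow(seqs)), seq_len(nrow(seqs)),
               Vectorize(function(i, j) sum(seqs[i, ] != seqs[j, ])))
  expect_equal(mean(ham), 4)  # frames / 2
  # empirical check at scale: distinct seeds differ by about frames/2
  a <- make_color_noise(1500, 5, seed = 1)$channels[, 1]
  b <- make_color_noise(1500, 5, seed = 2)$channels[, 1]
  expect_gt(sum(a != b), 0.45 * 7500)
  expect_lt(sum(a != b), 0.55 * 7500)
})

test_that("odd frame counts are rejected (balance impossible)", {
  expect_error(make_color_noise(duration_s = 1.4, rate_hz = 5),
               "balance impossible|even")
  expect_error(make_color_noise(duration_s = 1.23, rate_hz = 5), "integer")
})

test_that("sparse noise has exact condition counts and randomized order", {
  sn <- make_sparse_noise(seed = 3)
  expect_equal(nrow(sn$conditions), 8 * 5 * 2 * 2)
  expect_equal(nrow(sn$sequence), 160 * 50)
  expect_true(all(table(sn$sequence$cond_id) == 50))
  # one repeat: a permutation of all conditions, each exactly once
  sn1 <- make_sparse_noise(repeats = 1, seed = 5)
  expect_setequal(sn1$sequence$cond_id, seq_len(160))
  expect_false(all(sn1$sequence$cond_id == seq_len(160)))
})

test_that("scenes: independent channels, dark UV object, bounds checking", {
  sc <- make_scene(size_px = c(64, 64), seed = 11)
  expect_true(all(sc$green >= 0 & sc$green <= 1))
  expect_lt(abs(cor(as.vector(sc$green), as.vector(sc$uv))), 0.1)
  expect_false(sc$has_object)

  obj <- list(center = c(32, 32), axes = c(10, 6), angle = 0.5)
  so <- make_scene(size_px = c(64, 64), object = obj, seed = 11)
  mask <- chromv1:::ellipse_mask(c(64, 64), obj$center, obj$axes, obj$angle)
  expect_lt(mean(so$uv[mask]), mean(so$uv[!mask]))
  # green channel never carries the object
  expect_identical(so$green, sc$green)
  # object pixels strictly darker than the pre-object background there
  expect_true(all(so$uv[mask] <= sc$uv[mask]))

  expect_error(make_scene(object = list(center = c(2, 2), axes = c(10, 5),
                                        angle = 0), seed = 1),
               "bounds")
})

test_that("contrast matching equalizes the contrast distributions", {
  n <- 300
  noise_sc <- make_scenes(n, with_object = FALSE, seed = 21)
  obj_sc <- make_scenes(n, with_object = TRUE, seed = 21)
  matched <- match_contrast(obj_sc, noise_sc)
  c_m <- vapply(matched, scene_contrast, numeric(1))
  c_n <- vapply(noise_sc, scene_contrast, numeric(1))
  expect_lt(abs(mean(c_m) / mean(c_n) - 1), 0.01)
  expect_gt(suppressWarnings(ks.test(c_m, c_n)$p.value), 0.05)

  # idempotence: matching twice equals matching once
  twice <- match_contrast(matched, noise_sc)
  expect_equal(twice[[1]]$uv, matched[[1]]$uv, tolerance = 1e-10)
  expect_equal(max(abs(attr(twice, "scale") - 1)), 0, tolerance = 1e-8)

  # a scene already at its target contrast is returned unchanged
  one <- match_contrast(noise_sc[1], noise_sc[1])
  expect_equal(attr(one, "scale"), 1, tolerance = 1e-12)

  # RMS-halving oracle: doubling deviations then matching to the original
  # halves them again
  sc <- noise_sc[[1]]
  m <- mean(c(sc$green, sc$uv))
  doubled <- sc
  doubled$green <- m + 2 * (sc$green - m)
  doubled$uv <- m + 2 * (sc$uv - m)
  rematch <- match_contrast(list(doubled), list(sc))
  expect_equal(attr(rematch, "scale"), 0.5, tolerance = 1e-12)
  expect_equal(rematch[[1]]$green, sc$green, tolerance = 1e-12)

  flat <- sc; flat$green[] <- 0.5; flat$uv[] <- 0.5
  expect_error(match_contrast(list(flat), noise_sc), "zero-contrast")
})
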