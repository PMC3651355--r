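cfg_small <- iron_config(min_training_size = 20)

test_that("training-set selection applies every exclusion rule", {
  n <- 60
  sample <- seq(10, 600, length.out = n)
  reference <- seq(20, 1200, length.out = n)
  names(sample) <- names(reference) <- sprintf("p%02d", seq_len(n))
  # three probes tied at the sample minimum
  sample[1:3] <- 10
  # saturated probe on the reference chip
  reference[50] <- 65000
  lay <- chip_layout(names(sample),
                     c(NA, rep("ps", n - 1)),        # p01 unassigned
                     masked = "p05")
  idx <- build_training_set(sample, reference, lay, cfg_small)
  expect_false(any(1:3 %in% idx))                    # min-tied excluded
  expect_false(5 %in% idx)                           # masked
  expect_false(50 %in% idx)                          # saturated (> 64000)
  expect_false(n %in% idx)                           # sample maximum
  # without a layout, only intensity rules apply
  idx2 <- build_training_set(sample, reference, NULL, cfg_small)
  expect_true(5 %in% idx2)
  expect_false(any(1:3 %in% idx2))
})

test_that("a probe at 65000 is excluded by the default saturation threshold", {
  n <- 150
  reference <- seq(100, 50000, length.out = n)
  sample <- reference * 1.1
  sample[75] <- 65000
  idx <- build_training_set(sample, reference, config = iron_config())
  expect_false(75 %in% idx)
})

test_that("saturation is judged on raw values when supplied", {
  n <- 150
  reference <- seq(100, 50000, length.out = n)
  sample <- reference
  raw_sample <- sample
  raw_sample[40] <- 64500       # saturated before correction
  idx <- build_training_set(sample, reference, config = iron_config(),
                            raw_sample = raw_sample,
                            raw_reference = reference)
  expect_false(40 %in% idx)
})

test_that("too few survivors abort the fit", {
  v <- seq_len(50)
  expect_error(build_training_set(v, v, config = iron_config()),
               "minimum")
})

test_that("rank-preserving data converges immediately with nothing removed", {
  set.seed(41)
  x <- sort(rnorm(500))
  y <- x^3 + 2 * x          # strictly increasing transform
  ts <- iterative_rank_prune(x, y, cfg_small)
  expect_true(ts$converged)
  expect_identical(ts$iteration_sizes, 500L)
  expect_equal(ts$max_pct_delta, 0)
  expect_length(ts$indices, 500)
})

test_that("two adjacent swapped ranks among 200 points converge at once", {
  x <- seq_len(200) + 0.5
  y <- x
  y[c(100, 101)] <- y[c(101, 100)]
  ts <- iterative_rank_prune(x, y, cfg_small)
  expect_true(ts$converged)
  expect_equal(ts$max_pct_delta, 0.5)
  expect_identical(ts$iteration_sizes, 200L)
})

test_that("pruning removes a strongly up-shifted arm", {
  set.seed(42)
  n_base <- 10000; n_arm <- 3000
  x <- c(rnorm(n_base, 9, 2), rnorm(n_arm, 9, 2))
  y <- x + c(rnorm(n_base, 0, 0.05), runif(n_arm, 1.5, 3))
  is_arm <- c(rep(FALSE, n_base), rep(TRUE, n_arm))
  ts <- iterative_rank_prune(x, y, iron_config())
  surviving_arm <- sum(is_arm[ts$indices])
  expect_true(ts$converged)
  expect_lt(surviving_arm / n_arm, 0.05)
  expect_true(all(diff(ts$iteration_sizes) < 0))
})

test_that("pruning trajectories shrink strictly and terminate on random data", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(400); y <- rnorm(400)
    res <- tryCatch(iterative_rank_prune(x, y, cfg_small),
                    error = function(e) e)
    if (inherits(res, "iron_prune_error")) {
      expect_true(all(diff(res$iteration_sizes) < 0))
    } else {
      expect_true(res$converged)
      expect_lte(res$max_pct_delta, 1.0)
      expect_true(all(diff(res$iteration_sizes) < 0))
    }
  }
})

test_that("density weights: symmetry, sparse up-weighting, and the loop oracle", {
  cfg <- iron_config()
  # equally spaced -> all interior sigma equal -> near-uniform weights
  a <- seq(0, 10, length.out = 300)
  w <- density_weights(a, cfg)
  expect_lt(diff(range(w)) / max(w), 1e-10)
  # isolated high point far from a dense cluster gets up-weighted
  a2 <- sort(c(rnorm(200, 5, 0.1), 50))
  w2 <- density_weights(a2, cfg)
  expect_gt(w2[201], median(w2[1:200]))
  # brute-force oracle at n = 500
  set.seed(43)
  a3 <- sort(rnorm(500, 10, 2))
  expect_lt(max(abs(density_weights(a3, cfg) -
                      oracle_density_weights(a3))), 1e-10)
})

test_that("constant intensities give uniform weights with a warning", {
  expect_warning(w <- density_weights(rep(2, 50), iron_config()),
                 "uniform")
  expect_identical(w, rep(1, 50))
})

test_that("trend fitting reproduces exact and oracle cases", {
  cfg <- iron_config()
  set.seed(44)
  x <- sort(rnorm(400, 9, 2))
  # identical chips: M = 0 everywhere -> fitted identically zero
  expect_identical(fit_correction(x, x, rep(1, 400), cfg),
                   rep(0, 400))
  # constant offset: fitted equals the constant everywhere
  y <- x - 0.7
  f <- fit_correction(x, y, density_weights(x + y, cfg), cfg)
  expect_equal(f, rep(0.7, 400), tolerance = 1e-12)
  # linear trend with noise: matches the generator and the loop oracle
  set.seed(45)
  n <- 1000
  xr <- sort(rnorm(n, 9, 2))
  yr <- xr - (0.1 * (2 * xr) - 0.5) + rnorm(n, 0, 0.05)
  o <- order(xr + yr); xr <- xr[o]; yr <- yr[o]
  wts <- density_weights(xr + yr, cfg)
  got <- fit_correction(xr, yr, wts, cfg)
  expect_lt(max(abs(got - oracle_fit_correction(xr, yr, wts))), 1e-10)
  truthline <- 0.2 * xr - 0.5      # the generating M(x) relation
  expect_lt(median(abs(got - truthline)), 0.02)
})

test_that("curve construction preserves the projection identities", {
  set.seed(46)
  x <- sort(rnorm(200, 9, 2)); y <- x + rnorm(200, 0.3, 0.2)
  o <- order(x + y); x <- x[o]; y <- y[o]
  fitted <- fit_correction(x, y, rep(1, 200), iron_config())
  curve <- build_fit_curve(x, y, fitted, iron_config())
  expect_true(all(diff(curve$y_proj) > 0))
  expect_equal(curve$x_proj - curve$y_proj, curve$correction)
  # A-coordinate preserved: x_proj + y_proj = x + y (no merges here)
  expect_equal(sort(curve$x_proj + curve$y_proj), sort(x + y))
  # fitted == observed M -> d = 0 and the curve is the training points
  m0 <- x - y
  c0 <- build_fit_curve(x, y, m0, iron_config())
  expect_equal(c0$y_proj, sort(y))
  expect_equal(c0$correction, (x - y)[order(y)], tolerance = 1e-12)
})

test_that("points sharing a projected Y merge by averaging corrections", {
  # engineered so points 1 and 2 both project onto y_proj = 2.9
  x <- c(3, 3.4, 5)
  y <- c(3, 2.8, 4.5)
  fitted <- c(0.2, 0.4, 0.5)
  d <- fitted - (x - y)
  expect_equal((y - d / 2)[1], (y - d / 2)[2])  # construction sanity
  curve <- build_fit_curve(x, y, fitted, iron_config())
  expect_equal(nrow(curve), 2)
  expect_equal(curve$correction[1], 0.3)        # mean of 0.2 and 0.4
  expect_equal(curve$y_proj[1], 2.9)
})

test_that("curve application: identity, constant shift, extrapolation", {
  set.seed(47)
  v <- rlnorm(500, log(400), 1.2)
  x <- sort(log2(v)); y <- x
  zero_curve <- build_fit_curve(x, y, rep(0, 500), iron_config())
  expect_equal(apply_fit_curve(v, zero_curve, iron_config()), v,
               tolerance = 1e-12)
  one_curve <- build_fit_curve(x + 1, y, rep(1, 500), iron_config())
  expect_equal(apply_fit_curve(v, one_curve, iron_config()), 2 * v,
               tolerance = 1e-12)
  # below-range queries receive the mean of the first 10 corrections
  x2 <- seq(5, 15, length.out = 100)
  corr <- seq(0.1, 1, length.out = 100)
  curve2 <- build_fit_curve(x2 + corr, x2, corr, iron_config())
  low <- 2^(x2[1] - 3)
  got <- apply_fit_curve(low, curve2, iron_config())
  expect_equal(log2(got) - log2(low), mean(corr[1:10]), tolerance = 1e-12)
  hi <- 2^(x2[100] + 3)
  got_hi <- apply_fit_curve(hi, curve2, iron_config())
  expect_equal(log2(got_hi) - log2(hi), mean(corr[91:100]), tolerance = 1e-12)
  expect_error(apply_fit_curve(v, curve2[1, ], iron_config()))
})

test_that("interpolated correction is continuous within the curve range", {
  set.seed(48)
  x <- sort(rnorm(100, 10, 1.5))
  corr <- sin(x) * 0.3
  curve <- build_fit_curve(x + corr, x, corr, iron_config())
  grid <- seq(min(curve$y_proj), max(curve$y_proj), length.out = 5000)
  cvals <- log2(apply_fit_curve(2^grid, curve, iron_config())) - grid
  expect_lt(max(abs(diff(cvals))), 0.01)
})

test_that("self-normalization returns the input to near machine precision", {
  for (seed in 1:5) {
    v <- random_chip(3000, seed = seed)
    fit <- iron_fit(v, v)
    expect_lt(max(abs(fit$normalized - v) / v), 1e-9)
  }
})

test_that("a constant gain of 2 is removed almost exactly", {
  ref <- random_chip(10000, seed = 51)
  fit <- iron_fit(2 * ref, ref)
  expect_lt(median(abs(log2(fit$normalized / ref))), 0.01)
  # correction is ~ -1 everywhere in log2
  expect_equal(median(fit$curve$correction), -1, tolerance = 1e-6)
})

test_that("a warped chip with an asymmetric up-arm is recovered on non-arm probes", {
  ref <- random_chip(12000, seed = 52)
  set.seed(53)
  arm <- runif(12000) < 0.30
  sam <- warp_chip(ref, make_distortion("gamma_curve", g = 1.15),
                   noise_sd_log2 = 0.02, arm = arm,
                   arm_shift = runif(12000, 1, 3), seed = 54)
  pre <- median(abs(log2(sam / ref)[!arm]))
  fit <- iron_fit(sam, ref)
  post <- median(abs(log2(fit$normalized / ref)[!arm]))
  expect_lt(post, 0.10 * pre)
})

test_that("normalization is a pure function of the pair", {
  ref <- random_chip(2000, seed = 55)
  sam <- warp_chip(ref, make_distortion("gain", gain = 1.5),
                   noise_sd_log2 = 0.05, seed = 56)
  f1 <- iron_fit(sam, ref)
  f2 <- iron_fit(sam, ref)
  expect_identical(f1$normalized, f2$normalized)
  expect_identical(unname(ref), unname(f1$reference))
})

test_that("fit object methods expose the model sensibly", {
  ref <- random_chip(2000, seed = 57)
  sam <- warp_chip(ref, make_distortion("gain", gain = 2), seed = 58)
  fit <- iron_fit(sam, ref)
  expect_s3_class(fit, "iron_fit")
  expect_output(print(fit), "training")
  expect_output(print(summary(fit)), "trajectory")
  expect_identical(predict(fit), fit$normalized)
  doubled <- predict(fit, newdata = sam * 2)
  expect_equal(unname(log2(doubled) - log2(predict(fit, newdata = sam))),
               rep(1, 2000), tolerance = 0.2)
  expect_length(residuals(fit), length(fit$training$indices))
  expect_s3_class(coef(fit), "data.frame")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
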