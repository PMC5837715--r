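test_that("modified Silverman bandwidth matches hand evaluation", {
  # sd = 0.15811, raw mad = 0.1, min(sd, 1.4826*mad) = 0.14826,
  # h = 0.9 * 0.14826 * 5^(-1/5)
  expect_equal(modified_silverman_bandwidth(c(0, 0.1, 0.2, 0.3, 0.4), 1),
               0.9 * 0.14826 * 5^(-0.2), tolerance = 1e-12)
  expect_equal(modified_silverman_bandwidth(c(0, 0.1, 0.2, 0.3, 0.4), 1),
               0.09671025, tolerance = 1e-7)

  # h = phi * s is linear in phi
  r <- rnorm(20)
  expect_equal(modified_silverman_bandwidth(r, 0.5),
               0.5 * modified_silverman_bandwidth(r, 1))

  expect_error(modified_silverman_bandwidth(rep(0.3, 3), 1), "degenerate")
  expect_error(modified_silverman_bandwidth(0.3, 1), "at least 2")
})

test_that("the smoothed density is a proper weighted normal mixture", {
  # single kernel evaluated at its centre
  expect_equal(ratio_density(0.7, ratios = 0.7, h = 0.3),
               1 / (0.3 * sqrt(2 * pi)))

  # symmetry about the centre of a symmetric configuration
  r <- c(-0.4, 0.1, 0.6)  # symmetric about 0.1
  f <- ratio_density(0.1 + c(-0.25, 0.25), r, h = 0.2)
  expect_equal(f[1], f[2])

  # integrates to 1 (trapezoidal quadrature oracle)
  set.seed(7)
  r <- rnorm(12)
  w <- runif(12); w <- w / sum(w)
  g <- seq(min(r) - 8, max(r) + 8, length.out = 20001)
  f <- ratio_density(g, r, h = 0.4, weights = w)
  integral <- sum((f[-1] + f[-length(f)]) / 2) * diff(g)[1]
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_true(all(f >= 0))
})

test_that("the mode estimate finds the dominant ratio cluster", {
  # tight cluster below grid resolution
  d <- data_from_ratios(0.5 + c(-1e-6, 0, 1e-6, 2e-6))
  est <- mbe_point_estimate(compute_ratios(d),
                            mbe_settings(weighting = "simple"))
  expect_equal(est, 0.5, tolerance = 1e-4)

  # three near-identical ratios beat one outlier; dense-grid oracle agrees
  r <- c(0.29, 0.30, 0.31, 1.0)
  st <- mbe_settings(weighting = "simple", grid_points = 10000)
  est <- mbe_point_estimate(compute_ratios(data_from_ratios(r)), st)
  expect_equal(est, 0.30, tolerance = 0.01)
  h <- modified_silverman_bandwidth(r, 1)
  oracle <- brute_force_mode(r, rep(0.25, 4), h, grid_points = 1e6)
  step <- (diff(range(r)) + 6 * h) / (10000 - 1)
  expect_lt(abs(est - oracle), step + 1e-12)

  # exact twin peaks resolve to the leftmost grid point
  m <- modemr:::.mode_on_grid(c(-1, 1), c(0.5, 0.5), h = 0.3,
                              grid_points = 1001)
  step2 <- (2 + 6 * 0.3) / 1000
  expect_lt(abs(m - (-1)), step2 + 1e-12)

  # inverse-variance weights with equal SEs reduce to the simple MBE
  d2 <- data_from_ratios(c(0.1, 0.2, 0.25, 0.8, 0.82), rep(0.05, 5))
  r2 <- compute_ratios(d2)
  expect_identical(mbe_point_estimate(r2, mbe_settings("weighted")),
                   mbe_point_estimate(r2, mbe_settings("simple")))

  expect_error(mbe_point_estimate(compute_ratios(data_from_ratios(c(0, 1)))),
               "at least 3")
})

test_that("grid mode search matches a 10x finer brute-force oracle", {
  set.seed(99)
  for (i in 1:100) {
    L <- sample(4:40, 1)
    r <- rnorm(L, 0, runif(1, 0.05, 2))
    w <- runif(L); w <- w / sum(w)
    h <- modified_silverman_bandwidth(r, 1)
    coarse <- modemr:::.mode_on_grid(r, w, h, 1000L)
    fine <- brute_force_mode(r, w, h, grid_points = 10000)
    step <- (diff(range(r)) + 6 * h) / (1000 - 1)
    expect_lt(abs(coarse - fine), step + 1e-12)
    expect_true(coarse >= min(r) && coarse <= max(r))
  }
})

test_that("parametric bootstrap SE is seeded, shrinks with the ratio SEs, and matches Monte-Carlo spread", {
  d <- make_valid_data(12, beta = 0.2, seed = 3)
  st <- mbe_settings(weighting = "simple", boot_reps = 150, seed = 42,
                     grid_points = 1000)
  b1 <- mbe_bootstrap_se(d, st)
  b2 <- mbe_bootstrap_se(d, st)
  expect_identical(b1$se, b2$se)
  expect_identical(b1$boot_estimates, b2$boot_estimates)
  expect_length(b1$boot_estimates, 150)

  # se -> 0 as the ratio SEs -> 0
  tiny <- mr_summary(beta_exposure = d$beta_exposure,
                     se_exposure = rep(1e-9, 12),
                     beta_outcome = d$beta_outcome,
                     se_outcome = rep(1e-7, 12))
  expect_lt(mbe_bootstrap_se(tiny, st)$se, 1e-5)

  # identical ratios have no spread for the bandwidth rule to work with
  degen <- mr_summary(rep(1, 5), rep(1e-12, 5), rep(0.4, 5), rep(1e-12, 5))
  expect_error(mr_mbe(degen, mbe_settings(boot_reps = 3)), "degenerate")

  # the bootstrap SE brackets the Monte-Carlo SD of the estimator from
  # above: re-jittering already-noisy ratio estimates makes the mode's
  # bootstrap distribution conservative (the source of the estimator's
  # known CI over-coverage), but by a bounded factor
  set.seed(11)
  L <- 15; sd_r <- 0.05
  st2 <- mbe_settings(weighting = "simple", boot_reps = 300,
                      grid_points = 1000)
  est <- replicate(300, {
    d <- data_from_ratios(rnorm(L, 0.2, sd_r), se = rep(sd_r, L))
    mbe_point_estimate(compute_ratios(d), st2)
  })
  ses <- replicate(15, {
    d <- data_from_ratios(rnorm(L, 0.2, sd_r), se = rep(sd_r, L))
    mbe_bootstrap_se(d, st2)$se
  })
  expect_gt(mean(ses), 0.9 * sd(est))
  expect_lt(mean(ses), 1.6 * sd(est))
})

test_that("the full MBE assembles point, SE, CI and p-value coherently", {
  d <- make_valid_data(10, beta = 0.5, seed = 5, sy = 0.005)
  st <- mbe_settings(weighting = "weighted", boot_reps = 200, seed = 1,
                     grid_points = 2000)
  e <- mr_mbe(d, st)
  expect_s3_class(e, "causal_estimate")
  expect_equal(e$beta, 0.5, tolerance = 0.05)
  expect_true(e$ci_low <= 0.5 && 0.5 <= e$ci_high)
  # symmetric normal CI has width exactly 2 * 1.959964 * se
  expect_equal(e$ci_high - e$ci_low, 2 * 1.959964 * e$se)
  expect_true(e$p_value >= 0 && e$p_value <= 1)

  ep <- mr_mbe(d, mbe_settings(weighting = "weighted", boot_reps = 200,
                               seed = 1, grid_points = 2000,
                               ci_method = "percentile"))
  expect_identical(ep$beta, e$beta)
  qs <- quantile(mbe_bootstrap_se(d, st)$boot_estimates, c(0.025, 0.975))
  expect_equal(unname(qs), c(ep$ci_low, ep$ci_high))

  # majority-invalid configuration with distinct biases: the two-variant
  # valid cluster still carries the mode (six of eight instruments invalid)
  bias <- c(0.8, -0.6, 1.4, -1.1, 2.0, -1.7, 0, 0)
  bx <- rep(0.2, 8)
  dz <- mr_summary(beta_exposure = bx, se_exposure = rep(1e-6, 8),
                   beta_outcome = (0.3 + bias) * bx + c(rep(0, 6), 1e-4, -1e-4),
                   se_outcome = rep(0.002, 8))
  rz <- compute_ratios(dz)
  est <- mbe_point_estimate(rz, mbe_settings("simple"))
  h <- modified_silverman_bandwidth(rz$ratio, 1)
  oracle <- brute_force_mode(rz$ratio, rep(1 / 8, 8), h, 1e6)
  step <- (diff(range(rz$ratio)) + 6 * h) / (10000 - 1)
  expect_lt(abs(est - oracle), step + 1e-12)
  # closer to the truth than to every biased parameter value, and within
  # one smoothing bandwidth of the truth
  expect_true(all(abs(est - (0.3 + bias[1:6])) > abs(est - 0.3)))
  expect_lt(abs(est - 0.3), h)
})
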