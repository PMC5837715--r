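test_that("IVW matches the weighted normal equation and handles edge cases", {
  d <- mr_summary(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.2), c(0.02, 0.02))
  e <- mr_ivw(d)
  expect_equal(e$beta, 1.25)  # sum(w bx by) / sum(w bx^2) by hand

  # identical variants: estimate is the common ratio, no inflation
  d2 <- mr_summary(rep(0.2, 4), rep(0.01, 4), rep(0.08, 4), rep(0.02, 4))
  e2 <- mr_ivw(d2)
  expect_equal(e2$beta, 0.4)
  expect_equal(e2$settings$inflation, 1)

  # single instrument falls back to the ratio estimate with NOME SE
  d1 <- mr_summary(0.1, 0.01, 0.05, 0.02)
  e1 <- mr_ivw(d1)
  expect_equal(e1$beta, 0.5)
  expect_equal(e1$se, 0.2)
  expect_equal(e1$settings$model, "fixed-effect-only")

  # weighted regression-through-origin oracle via lm()
  set.seed(8)
  d3 <- make_valid_data(20, beta = 0.3, sy = 0.05)
  fit <- lm(d3$beta_outcome ~ d3$beta_exposure - 1,
            weights = d3$se_outcome^-2)
  e3 <- mr_ivw(d3)
  expect_equal(e3$beta, unname(coef(fit)), tolerance = 1e-12)
  s <- summary(fit)$sigma
  se_lm <- unname(coef(summary(fit))[1, 2])
  expect_equal(e3$se, se_lm / s * max(1, s), tolerance = 1e-10)
})

test_that("MR-Egger equals the closed-form weighted least squares solution", {
  # exact line: intercept and slope recovered with inflation 1
  bx <- c(0.1, 0.15, 0.2, 0.3)
  d <- mr_summary(bx, rep(0.01, 4), 0.02 + 0.5 * bx, rep(0.03, 4))
  e <- mr_egger(d)
  expect_equal(e$intercept$beta, 0.02, tolerance = 1e-12)
  expect_equal(e$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$slope$settings$inflation, 1)

  # generic data: agree with lm(weights=) to numerical precision
  set.seed(9)
  d2 <- mr_summary(runif(15, 0.05, 0.3), rep(0.01, 15),
                   rnorm(15, 0, 0.2), runif(15, 0.01, 0.05))
  fit <- lm(d2$beta_outcome ~ d2$beta_exposure,
            weights = d2$se_outcome^-2)
  e2 <- mr_egger(d2)
  expect_equal(e2$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(e2$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  s <- summary(fit)$sigma
  expect_equal(e2$slope$se,
               unname(coef(summary(fit))[2, 2]) / s * max(1, s),
               tolerance = 1e-8)
  # t-based p-value with L-2 df
  expect_equal(e2$slope$p_value,
               2 * pt(-abs(e2$slope$beta / e2$slope$se), df = 13))

  expect_error(mr_egger(mr_summary(rep(0.2, 5), rep(0.01, 5),
                                   rnorm(5), rep(0.02, 5))), "singular")
  expect_error(mr_egger(make_valid_data(2)), "at least 3")
})

test_that("median estimators interpolate the weighted 50th percentile", {
  d <- data_from_ratios(c(0.1, 0.2, 0.3))
  e <- mr_median(d, "simple", boot_reps = 50, seed = 1)
  expect_equal(e$beta, 0.2)

  # weights (0.5, 0.25, 0.25): interpolate between p1=25 and p2=62.5
  expect_equal(modemr:::.weighted_median(c(0.1, 0.2, 0.3),
                                         c(0.5, 0.25, 0.25)),
               0.1 + 0.1 * 25 / 37.5, tolerance = 1e-12)

  # equal weights reproduce the simple median (odd L)
  r <- c(0.12, 0.4, 0.21, 0.35, 0.3)
  expect_equal(modemr:::.weighted_median(r, rep(0.2, 5)), median(r))

  d2 <- data_from_ratios(c(0.1, 0.2, 0.3, 0.31, 0.29), rep(0.01, 5))
  es <- mr_median(d2, "weighted", boot_reps = 100, seed = 2)
  expect_equal(es$ci_high - es$ci_low, 2 * 1.959964 * es$se)
  expect_error(mr_median(make_valid_data(2)), "at least 3")
})

test_that("Cochran's Q measures ratio heterogeneity around the fixed-effect IVW", {
  # identical ratios: no heterogeneity
  d0 <- data_from_ratios(rep(0.4, 5), rep(0.1, 5))
  q0 <- cochran_q(d0)
  expect_equal(q0$q, 0)
  expect_equal(q0$p_value, 1)
  expect_equal(q0$df, 4L)

  # ratios (0, 1) with unit weights: IVW = 0.5, Q = 0.25 + 0.25
  d1 <- mr_summary(c(1, 1), c(0.01, 0.01), c(0, 1), c(1, 1))
  expect_equal(cochran_q(d1)$q, 0.5)

  # Q strictly increases as one ratio moves away from the bulk
  qs <- sapply(c(0.5, 1, 2, 4), function(shift) {
    cochran_q(data_from_ratios(c(0.2, 0.2, 0.2, 0.2 + shift),
                               rep(0.05, 4)))$q
  })
  expect_true(all(diff(qs) > 0))
})

test_that("instrument strength diagnostics quantify NOME violation", {
  # per-variant F exactly 400
  d <- mr_summary(rep(2, 6), rep(0.1, 6), rnorm(6), rep(0.1, 6))
  st <- instrument_strength(d)
  expect_equal(st$mean_f, 400)
  expect_equal(st$f_attenuation, 399 / 400)

  # all-zero exposure estimates: attenuation undefined
  d0 <- mr_summary(rep(0, 4), rep(0.1, 4), rnorm(4), rep(0.1, 4))
  expect_warning(st0 <- instrument_strength(d0), "undefined")
  expect_true(is.na(st0$f_attenuation))
  expect_equal(st0$mean_f, 0)

  # igx2 equals its definition and the floored copy never goes negative
  set.seed(10)
  d2 <- mr_summary(rnorm(8, 0.2, 0.05), runif(8, 0.01, 0.03),
                   rnorm(8), rep(0.05, 8))
  st2 <- instrument_strength(d2)
  wx <- d2$se_exposure^-2
  bw <- sum(wx * d2$beta_exposure) / sum(wx)
  qgx <- sum(wx * (d2$beta_exposure - bw)^2)
  expect_equal(st2$igx2, (qgx - 7) / qgx)
  expect_gte(st2$igx2_floored, 0)
})

test_that("ZEMPA breakdown bounds follow the closed form and limit to (50, 100)", {
  b30 <- zempa_breakdown_bounds(30)
  expect_equal(b30$lower_pct, 1600 / 30, tolerance = 1e-12)
  expect_equal(b30$upper_pct, 2800 / 30, tolerance = 1e-12)
  b8 <- zempa_breakdown_bounds(8)
  expect_equal(b8$lower_pct, 62.5)
  expect_equal(b8$upper_pct, 75)
  big <- zempa_breakdown_bounds(1e6)
  expect_equal(big$lower_pct, 50, tolerance = 1e-3)
  expect_equal(big$upper_pct, 100, tolerance = 1e-3)
  expect_error(zempa_breakdown_bounds(5), "fewer than 6")
})

test_that("estimates are equivariant under exposure rescaling", {
  set.seed(12)
  d <- make_valid_data(15, beta = 0.25, sy = 0.03)
  for (cc in c(0.5, 2, 10)) {
    ds <- mr_summary(beta_exposure = cc * d$beta_exposure,
                     se_exposure = cc * d$se_exposure,
                     beta_outcome = d$beta_outcome,
                     se_outcome = d$se_outcome)
    expect_equal(mr_ivw(ds)$beta, mr_ivw(d)$beta / cc, tolerance = 1e-12)
    expect_equal(mr_egger(ds)$slope$beta, mr_egger(d)$slope$beta / cc,
                 tolerance = 1e-10)
    m <- mr_median(d, "weighted", boot_reps = 1, seed = 1)$beta
    ms <- mr_median(ds, "weighted", boot_reps = 1, seed = 1)$beta
    expect_equal(ms, m / cc, tolerance = 1e-12)
  }
})
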