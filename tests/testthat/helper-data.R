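# Small summary-level dataset builders used across the test files.

# valid-instrument dataset: strong exposure effects, outcome = beta * bx
# plus noise at the nominal outcome SE
make_valid_data <- function(L = 10, beta = 0.2, seed = 1,
                            sy = 0.01, sx = 0.005) {
  set.seed(seed)
  bx <- runif(L, 0.1, 0.3)
  by <- beta * bx + rnorm(L, 0, sy)
  mr_summary(beta_exposure = bx, se_exposure = rep(sx, L),
             beta_outcome = by, se_outcome = rep(sy, L))
}

# dataset whose ratio estimates are exactly `ratios`, with unit exposure
# effects (tiny exposure SE) and chosen outcome SEs
data_from_ratios <- function(ratios, se = rep(0.01, length(ratios))) {
  L <- length(ratios)
  mr_summary(beta_exposure = rep(1, L), se_exposure = rep(1e-9, L),
             beta_outcome = ratios, se_outcome = se)
}

# dense-grid argmax of the weighted normal-kernel density, kept independent
# of the package's mode search (plain R, full evaluation, no windowing)
brute_force_mode <- function(ratios, weights, h, grid_points = 20000) {
  g <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h,
           length.out = grid_points)
  f <- colSums(weights * exp(-0.5 * (outer(ratios, g, "-") / h)^2))
  g[which.max(f)]
}
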