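#' Inverse-variance weighted (IVW) estimate
#'
#' Weighted regression of the SNP-outcome associations on the SNP-exposure
#' associations through the origin, with weights \eqn{\sigma_{Yj}^{-2}}
#' (equivalently, the inverse-variance weighted mean of the ratio estimates
#' under NOME). Standard errors use a multiplicative random-effects model:
#' the fixed-effect SE is inflated by the residual standard deviation
#' (L-1 degrees of freedom), floored at 1, so balanced heterogeneity widens
#' the interval but precision is never overstated.
#'
#' @param data an [mr_summary] dataset.
#' @return a `causal_estimate`. The CI and p-value use the t distribution
#'   with L-1 degrees of freedom, as is conventional for multiplicative
#'   random-effects models. With a single instrument the ratio estimate
#'   with its NOME standard error is returned, flagged fixed-effect-only.
#' @export
mr_ivw <- function(data) {
  stopifnot(inherits(data, "mr_summary"))
  L <- nrow(data)
  if (L == 1L) {
    r <- compute_ratios(data)
    beta <- r$ratio
    se <- r$se_nome
    p <- 2 * stats::pnorm(-abs(beta) / se)
    return(new_causal_estimate("IVW", beta, se, beta - Z95 * se,
                               beta + Z95 * se, p,
                               settings = list(model = "fixed-effect-only")))
  }
  w <- data$se_outcome^-2
  bx <- data$beta_exposure
  by <- data$beta_outcome
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  resid_sd <- sqrt(sum(w * (by - beta * bx)^2) / (L - 1))
  se <- se_fixed * max(1, resid_sd)
  crit <- stats::qt(0.975, df = L - 1)
  p <- 2 * stats::pt(-abs(beta) / se, df = L - 1)
  new_causal_estimate("IVW", beta, se, beta - crit * se, beta + crit * se,
                      p,
                      settings = list(model = "multiplicative random effects",
                                      inflation = max(1, resid_sd),
                                      df = L - 1))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome on the SNP-exposure
#' associations *with* an intercept, weights \eqn{\sigma_{Yj}^{-2}}. The
#' intercept estimates the average directional pleiotropic effect; the slope
#' estimates the causal effect and is consistent under the InSIDE assumption
#' (pleiotropy independent of instrument strength) even when all instruments
#' are invalid. Multiplicative random-effects SEs (residual SD with L-2 df,
#' floored at 1); p-values from the t distribution with L-2 df.
#'
#' @param data an [mr_summary] dataset with at least 3 instruments and
#'   non-constant SNP-exposure associations.
#' @return list with elements `intercept` and `slope`, each a
#'   `causal_estimate`.
#' @export
mr_egger <- function(data) {
  stopifnot(inherits(data, "mr_summary"))
  L <- nrow(data)
  if (L < 3L) stop("MR-Egger requires at least 3 instruments")
  bx <- data$beta_exposure
  by <- data$beta_outcome
  if (stats::sd(bx) == 0)
    stop("singular design: SNP-exposure associations are constant")
  w <- data$se_outcome^-2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  a <- (swxx * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  resid <- by - a - b * bx
  resid_sd <- sqrt(sum(w * resid^2) / (L - 2))
  infl <- max(1, resid_sd)
  se_a <- sqrt(swxx / det) * infl
  se_b <- sqrt(sw / det) * infl
  crit <- stats::qt(0.975, df = L - 2)
  p_a <- 2 * stats::pt(-abs(a) / se_a, df = L - 2)
  p_b <- 2 * stats::pt(-abs(b) / se_b, df = L - 2)
  meta <- list(model = "multiplicative random effects", inflation = infl,
               df = L - 2)
  list(intercept = new_causal_estimate("MR-Egger intercept", a, se_a,
                                       a - crit * se_a, a + crit * se_a,
                                       p_a, meta),
       slope = new_causal_estimate("MR-Egger slope", b, se_b,
                                   b - crit * se_b, b + crit * se_b,
                                   p_b, meta))
}

# interpolated weighted median of ordered ratio estimates
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  p <- 100 * (cumsum(w) - w / 2)
  if (50 <= p[1]) return(r[1])
  if (50 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 50, ties = "ordered")$y
}

#' Simple and weighted median estimates
#'
#' The median of the per-variant ratio estimates: either the plain sample
#' median (simple) or the weighted median, which linearly interpolates the
#' ratio estimates at the 50th weighted percentile using cumulative
#' percentiles \eqn{p_k = 100 (S_k - w_k/2)} of the standardized
#' inverse-variance weights (computed under NOME, as is conventional for
#' this estimator). The weighted median is consistent when valid instruments
#' contribute more than half of the total weight. Standard errors come from
#' the same ratio-scale parametric bootstrap as the MBE (1.4826 x MAD of the
#' bootstrap estimates) with a symmetric normal confidence interval.
#'
#' @param data an [mr_summary] dataset with at least 3 instruments.
#' @param weighting `"weighted"` or `"simple"`.
#' @param boot_reps bootstrap replicates for the standard error.
#' @param seed optional integer seed for the bootstrap.
#' @return a `causal_estimate`.
#' @export
mr_median <- function(data, weighting = c("weighted", "simple"),
                      boot_reps = 1000, seed = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(data, "mr_summary"))
  L <- nrow(data)
  if (L < 3L) stop("median estimators require at least 3 instruments")
  ratios <- compute_ratios(data)
  w <- standardized_weights(ratios, weighting, nome = TRUE)
  point <- function(r) {
    if (weighting == "simple") stats::median(r) else .weighted_median(r, w)
  }
  beta <- point(ratios$ratio)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(boot_reps), function(i) {
    point(stats::rnorm(L, ratios$ratio, ratios$se_nome))
  }, numeric(1))
  se <- stats::mad(boot)  # constant 1.4826
  p <- 2 * stats::pnorm(-abs(beta) / se)
  new_causal_estimate(sprintf("%s median",
                              if (weighting == "simple") "Simple" else "Weighted"),
                      beta, se, beta - Z95 * se, beta + Z95 * se, p,
                      settings = list(weighting = weighting,
                                      boot_reps = boot_reps,
                                      bootstrap = "ratio-scale"))
}

#' Cochran's Q heterogeneity test
#'
#' Tests for excess heterogeneity between the per-variant ratio estimates --
#' evidence of horizontal pleiotropy if pleiotropy is the only source of
#' heterogeneity beyond chance. Uses NOME inverse-variance weights around
#' the fixed-effect IVW estimate:
#' \eqn{Q = \sum_j \sigma_{Rj}^{-2} (\hat\beta_{Rj} - \hat\beta_{IVW})^2},
#' referred to a chi-squared distribution with L-1 degrees of freedom.
#'
#' @param data an [mr_summary] dataset with at least 2 instruments.
#' @return list of class `heterogeneity_stats` with `q`, `df`, `p_value`.
#' @export
cochran_q <- function(data) {
  stopifnot(inherits(data, "mr_summary"), nrow(data) >= 2L)
  ratios <- compute_ratios(data)
  w <- ratios$se_nome^-2
  beta_fixed <- sum(w * ratios$ratio) / sum(w)
  q <- sum(w * (ratios$ratio - beta_fixed)^2)
  df <- nrow(data) - 1L
  structure(list(q = q, df = df,
                 p_value = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_stats")
}

#' @export
print.heterogeneity_stats <- function(x, digits = 4, ...) {
  cat(sprintf("Cochran's Q = %.*g on %d df, p = %.*g\n",
              digits, x$q, x$df, digits, x$p_value))
  invisible(x)
}

#' Instrument strength and regression-dilution diagnostics
#'
#' Quantifies expected weak-instrument attenuation (violation of the NOME
#' assumption) in IVW and MR-Egger estimates:
#' * `mean_f`: mean per-variant F statistic,
#'   \eqn{\bar F = \mathrm{mean}_j(\hat\beta_{Xj}^2/\sigma_{Xj}^2)};
#' * `f_attenuation`: \eqn{(\bar F - 1)/\bar F}, the expected proportional
#'   attenuation of the IVW estimate;
#' * `igx2`: \eqn{I^2_{GX} = (Q_{GX} - (L-1))/Q_{GX}} with
#'   \eqn{Q_{GX} = \sum_j \sigma_{Xj}^{-2}(\hat\beta_{Xj} - \bar\beta_{X,w})^2},
#'   the analogous dilution factor for MR-Egger. Stored raw (it can be
#'   negative in small samples); `igx2_floored` reports `max(0, igx2)`.
#'
#' @param data an [mr_summary] dataset with at least 2 instruments.
#' @return list of class `instrument_strength` with `mean_f`,
#'   `f_attenuation`, `igx2`, `igx2_floored`.
#' @export
instrument_strength <- function(data) {
  stopifnot(inherits(data, "mr_summary"), nrow(data) >= 2L)
  L <- nrow(data)
  bx <- data$beta_exposure
  sx <- data$se_exposure
  mean_f <- mean(bx^2 / sx^2)
  if (mean_f == 0) {
    warning("all SNP-exposure estimates are zero; F attenuation undefined")
    f_att <- NA_real_
  } else {
    f_att <- (mean_f - 1) / mean_f
  }
  wx <- sx^-2
  bw <- sum(wx * bx) / sum(wx)
  qgx <- sum(wx * (bx - bw)^2)
  igx2 <- (qgx - (L - 1)) / qgx
  structure(list(mean_f = mean_f, f_attenuation = f_att,
                 igx2 = igx2, igx2_floored = max(0, igx2)),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, digits = 4, ...) {
  cat(sprintf("mean F = %.*g, (F-1)/F = %.*g, I2GX = %.*g (floored: %.*g)\n",
              digits, x$mean_f, digits, x$f_attenuation,
              digits, x$igx2, digits, x$igx2_floored))
  invisible(x)
}

#' ZEMPA breakdown bounds of the simple mode-based estimate
#'
#' The breakdown level (maximum proportion of invalid instruments tolerated)
#' of the simple MBE depends on how the invalid instruments' biases cluster:
#' it ranges from \eqn{100(\lfloor L/2\rfloor + 1)/L}\% (all invalid
#' instruments share one bias value) up to \eqn{100(L-2)/L}\% (all biases
#' distinct, so two valid instruments suffice). As L grows the bounds tend
#' to 50% and 100%.
#'
#' @param L number of instruments (at least 6; below that the printed bounds
#'   invert).
#' @return list with `lower_pct`, `upper_pct`.
#' @export
zempa_breakdown_bounds <- function(L) {
  stopifnot(length(L) == 1L, L == as.integer(L))
  if (L < 6) stop("breakdown bounds are undefined for fewer than 6 instruments")
  list(lower_pct = 100 * (floor(L / 2) + 1) / L,
       upper_pct = 100 * (L - 2) / L)
}
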