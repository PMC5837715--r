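#' Configuration of the individual-level data-generating model
#'
#' Parameters of the simulation model used to evaluate the estimators. For
#' individual i with genotype vector \eqn{G_{i1},...,G_{iL}} (independent
#' bi-allelic SNPs, \eqn{G_{ij} \sim Binomial(2, p_j)},
#' \eqn{p_j \sim U(maf_{low}, maf_{high})}):
#' \deqn{U_i = \gamma_U Z_{Ui} + \epsilon_{Ui}}
#' \deqn{X_i = \gamma_X Z_{Xi} + \theta_X U_i + \epsilon_{Xi}}
#' \deqn{Y_i = \gamma_Y Z_{Yi} + \beta X_i + \theta_Y U_i + \epsilon_{Yi}}
#' where \eqn{Z_U, Z_X, Z_Y} are allele scores weighted by
#' \eqn{\delta_{Uj}, \delta_{Xj}, \delta_{Yj}} and standardized by their own
#' sample SD, and the error variances are set so U, X and Y each have unit
#' variance. The score and confounder parameters
#' \eqn{\gamma_U, \gamma_X, \gamma_Y, \theta_X, \theta_Y} are variance
#' fractions: the coefficient applied to the corresponding unit-variance
#' term is the square root of the parameter, so e.g. `gamma_x = 0.1` makes
#' the allele score explain 10% of the exposure variance. The causal effect
#' `beta` is a plain coefficient on the unit-variance exposure (it explains
#' `beta^2` of the outcome variance). Positive `theta_x`, `theta_y` induce
#' positive confounding.
#' Invalid instruments are the first `rho` indices; their pleiotropic path
#' is direct (`delta_y`, respecting InSIDE) or through the confounder
#' (`delta_u`, violating InSIDE), per `pleiotropy_mode`.
#'
#' @param L number of variants.
#' @param rho number of invalid instruments (0..L).
#' @param beta true causal effect of X on Y (in SD units).
#' @param theta_x,theta_y confounder variance fractions of exposure and
#'   outcome.
#' @param gamma_x allele-score variance fraction of the exposure.
#' @param gamma_u,gamma_y allele-score variance fractions of confounder and
#'   outcome; default `rho * 0.1 / L` so the total pleiotropic signal scales
#'   with the number of invalid instruments.
#' @param n_exposure,n_outcome sample sizes for the SNP-exposure and
#'   SNP-outcome association estimates.
#' @param overlap fraction of outcome-sample individuals shared with the
#'   exposure sample (0 = two-sample, 1 = single sample).
#' @param pleiotropy_mode `"none"`, `"direct"` or `"confounded"`.
#' @param delta_low,delta_high bounds of the uniform distribution for the
#'   nonzero per-SNP effects (instrument strength and pleiotropy alike).
#' @param maf_low,maf_high bounds of the uniform allele-frequency
#'   distribution.
#' @param seed optional integer master seed for [run_scenario()].
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(L = 30, rho = 0, beta = 0,
                            theta_x = 0.3, theta_y = 0.3,
                            gamma_x = 0.1,
                            gamma_u = rho * 0.1 / L,
                            gamma_y = rho * 0.1 / L,
                            n_exposure = 50000, n_outcome = 50000,
                            overlap = 0,
                            pleiotropy_mode = c("none", "direct",
                                                "confounded"),
                            delta_low = 0.01, delta_high = 0.2,
                            maf_low = 0.1, maf_high = 0.9,
                            seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(L >= 1, rho >= 0, rho <= L,
            gamma_x >= 0, gamma_x <= 1, gamma_u >= 0, gamma_u <= 1,
            gamma_y >= 0, gamma_y <= 1,
            theta_x >= 0, theta_x <= 1, theta_y >= 0, theta_y <= 1,
            overlap >= 0, overlap <= 1,
            maf_low > 0, maf_high < 1, maf_low <= maf_high,
            delta_low <= delta_high,
            n_exposure >= 2, n_outcome >= 2)
  structure(list(L = as.integer(L), rho = as.integer(rho), beta = beta,
                 theta_x = theta_x, theta_y = theta_y,
                 gamma_x = gamma_x, gamma_u = gamma_u, gamma_y = gamma_y,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 overlap = overlap, pleiotropy_mode = pleiotropy_mode,
                 delta_low = delta_low, delta_high = delta_high,
                 maf_low = maf_low, maf_high = maf_high, seed = seed),
            class = "scenario_config")
}

#' Preset simulation scenarios
#'
#' Four study designs, all with L = 30 variants, confounder effects
#' `theta_x = theta_y = 0.3`, instrument effect `gamma_x = 0.1` and
#' `gamma_u = gamma_y = rho * 0.1 / L`:
#' * `simulation1` -- causal null, direct (InSIDE-respecting) pleiotropy in
#'   the `rho` invalid instruments; 100,000 individuals split in half
#'   between the exposure and outcome samples.
#' * `simulation2` -- causal null, confounder-mediated (InSIDE-violating)
#'   pleiotropy; same design.
#' * `simulation3` -- no pleiotropy, causal effect `beta = 0.1`; exposure /
#'   outcome sample sizes in {25,000, 50,000, 100,000}.
#' * `simulation4` -- causal null, no pleiotropy, overlapping samples
#'   (`overlap` 0.5 or 1, the latter the single-sample design) with
#'   `n` in {1,000, 5,000, 10,000}.
#'
#' @param name preset name.
#' @param rho number of invalid instruments, a multiple of 3 in 0..30
#'   (simulations 1-2 only).
#' @param n_exposure,n_outcome sample sizes (simulation 3; equal sizes are
#'   used for simulation 4 via `n_exposure`).
#' @param overlap sample overlap fraction (simulation 4).
#' @param seed optional master seed.
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(name = c("simulation1", "simulation2",
                                     "simulation3", "simulation4"),
                            rho = 0, n_exposure = 25000, n_outcome = NULL,
                            overlap = 0.5, seed = NULL) {
  name <- match.arg(name)
  if (name %in% c("simulation1", "simulation2")) {
    if (!(rho %in% seq(0L, 30L, by = 3L)))
      stop("rho must be in {0, 3, 6, ..., 30}")
    scenario_config(L = 30, rho = rho, beta = 0,
                    n_exposure = 50000, n_outcome = 50000, overlap = 0,
                    pleiotropy_mode = if (name == "simulation1") "direct"
                                      else "confounded",
                    seed = seed)
  } else if (name == "simulation3") {
    if (is.null(n_outcome)) n_outcome <- n_exposure
    scenario_config(L = 30, rho = 0, beta = 0.1,
                    n_exposure = n_exposure, n_outcome = n_outcome,
                    overlap = 0, pleiotropy_mode = "none", seed = seed)
  } else {
    scenario_config(L = 30, rho = 0, beta = 0,
                    n_exposure = n_exposure, n_outcome = n_exposure,
                    overlap = overlap, pleiotropy_mode = "none", seed = seed)
  }
}

# replicate-level SNP parameters: allele frequencies and per-SNP effects.
# delta_x (instrument strength) is uniform for every variant; the
# pleiotropic delta (delta_y or delta_u) is uniform for the first rho
# variants and zero otherwise.
.draw_snp_params <- function(config) {
  L <- config$L
  p <- stats::runif(L, config$maf_low, config$maf_high)
  delta_x <- stats::runif(L, config$delta_low, config$delta_high)
  delta_u <- numeric(L)
  delta_y <- numeric(L)
  if (config$rho > 0) {
    d <- stats::runif(config$rho, config$delta_low, config$delta_high)
    if (config$pleiotropy_mode == "direct") delta_y[seq_len(config$rho)] <- d
    if (config$pleiotropy_mode == "confounded")
      delta_u[seq_len(config$rho)] <- d
  }
  list(p = p, delta_u = delta_u, delta_x = delta_x, delta_y = delta_y)
}

#' Generate an individual-level cohort
#'
#' Draws genotypes and the confounder, exposure and outcome traits under the
#' model in [scenario_config()]. Allele scores with all-zero weights are the
#' zero vector; each error variance is set to one minus the sample variance
#' of the trait's systematic component, so U, X and Y have unit variance.
#'
#' @param config a [scenario_config()].
#' @param n number of individuals (>= 2).
#' @param params optional SNP parameter list (allele frequencies and delta
#'   vectors); drawn from `config` when `NULL`. Supply this to share SNP
#'   effects between cohorts of one replicate.
#' @return list of class `mr_cohort` with `genotypes` (n x L), traits `u`,
#'   `x`, `y`, the standardized `scores`, the error SDs used, and `params`.
#' @export
generate_cohort <- function(config, n, params = NULL) {
  stopifnot(inherits(config, "scenario_config"), n >= 2)
  if (is.null(params)) params <- .draw_snp_params(config)
  G <- .cpp_genotypes(n, params$p)
  score <- function(delta) {
    if (all(delta == 0)) return(numeric(n))
    z <- .cpp_score(G, delta)
    z / stats::sd(z)
  }
  zu <- score(params$delta_u)
  zx <- score(params$delta_x)
  zy <- score(params$delta_y)
  noise <- function(systematic, label) {
    v <- 1 - stats::var(systematic)
    if (v < 0)
      stop(sprintf("systematic variance of %s exceeds 1; reduce effect sizes",
                   label))
    list(value = systematic + stats::rnorm(n, 0, sqrt(v)), sd = sqrt(v))
  }
  u <- noise(sqrt(config$gamma_u) * zu, "U")
  x <- noise(sqrt(config$gamma_x) * zx + sqrt(config$theta_x) * u$value, "X")
  y <- noise(sqrt(config$gamma_y) * zy + config$beta * x$value +
               sqrt(config$theta_y) * u$value, "Y")
  structure(list(genotypes = G, u = u$value, x = x$value, y = y$value,
                 scores = list(zu = zu, zx = zx, zy = zy),
                 error_sd = c(u = u$sd, x = x$sd, y = y$sd),
                 params = params),
            class = "mr_cohort")
}

#' Per-variant association summary statistics
#'
#' Univariate ordinary-least-squares slope and standard error of `trait` on
#' each genotype column, computed in closed form from per-column sums
#' (residual variance on n-2 degrees of freedom).
#'
#' @param genotypes n x L genotype matrix.
#' @param trait numeric vector of length n.
#' @return data frame with columns `beta`, `se` (one row per variant).
#' @export
extract_summary <- function(genotypes, trait) {
  n <- length(trait)
  stopifnot(nrow(genotypes) == n, n >= 3)
  storage.mode(genotypes) <- "integer"
  st <- .cpp_col_regress(genotypes, as.numeric(trait), 0L, n)
  mono <- which(st[, 3] <= 0)
  if (length(mono))
    stop("monomorphic variant(s): ", paste(mono, collapse = ", "))
  data.frame(beta = st[, 1], se = st[, 2])
}

# one replicate: shared SNP parameters, one cohort sliced into the exposure
# and outcome subsamples with the configured overlap
.simulate_two_sample <- function(config) {
  params <- .draw_snp_params(config)
  nx <- config$n_exposure
  ny <- config$n_outcome
  n_shared <- round(ny * config$overlap)
  n_tot <- nx + ny - n_shared
  cohort <- generate_cohort(config, n_tot, params)
  sx <- .cpp_col_regress(cohort$genotypes, cohort$x, 0L, nx)
  sy <- .cpp_col_regress(cohort$genotypes, cohort$y, n_tot - ny, n_tot)
  if (any(sx[, 3] <= 0) || any(sy[, 3] <= 0))
    stop("monomorphic variant in subsample")
  mr_summary(beta_exposure = sx[, 1], se_exposure = sx[, 2],
             beta_outcome = sy[, 1], se_outcome = sy[, 2])
}

# run one estimator on one dataset; returns c(beta, se, ci_low, ci_high)
.apply_estimator <- function(data, name, settings, point_only) {
  mbe_like <- function(weighting, nome) {
    st <- mbe_settings(weighting = weighting, nome = nome,
                       phi = settings$phi, boot_reps = settings$boot_reps,
                       grid_points = settings$grid_points,
                       ci_method = settings$ci_method)
    if (point_only) {
      b <- mbe_point_estimate(compute_ratios(data), st)
      return(c(b, NA, NA, NA))
    }
    e <- mr_mbe(data, st)
    c(e$beta, e$se, e$ci_low, e$ci_high)
  }
  med_like <- function(weighting) {
    if (point_only) {
      ratios <- compute_ratios(data)
      b <- if (weighting == "simple") stats::median(ratios$ratio)
           else .weighted_median(ratios$ratio,
                                 standardized_weights(ratios, weighting,
                                                      nome = TRUE))
      return(c(b, NA, NA, NA))
    }
    e <- mr_median(data, weighting, boot_reps = settings$boot_reps)
    c(e$beta, e$se, e$ci_low, e$ci_high)
  }
  est <- switch(name,
    ivw = mr_ivw(data),
    egger = mr_egger(data)$slope,
    egger_intercept = mr_egger(data)$intercept,
    median_simple = return(med_like("simple")),
    median_weighted = return(med_like("weighted")),
    mbe_simple = return(mbe_like("simple", FALSE)),
    mbe_weighted = return(mbe_like("weighted", FALSE)),
    mbe_simple_nome = return(mbe_like("simple", TRUE)),
    mbe_weighted_nome = return(mbe_like("weighted", TRUE)),
    stop("unknown estimator: ", name)
  )
  c(est$beta, est$se, est$ci_low, est$ci_high)
}

#' Monte-Carlo evaluation of the estimators under a scenario
#'
#' Repeatedly simulates two-sample summary datasets under `config`, runs the
#' requested estimators on each, and aggregates mean estimate, mean
#' estimated standard error, 95% CI coverage of the true effect and power
#' (proportion of CIs excluding zero), together with the mean
#' instrument-strength diagnostics of the exposure sample.
#'
#' Each replicate runs under its own seed derived from the master seed, so
#' results are reproducible and independent of the estimator list.
#'
#' @param config a [scenario_config()].
#' @param n_reps number of Monte-Carlo replicates (>= 1).
#' @param estimators character vector among `"ivw"`, `"egger"`,
#'   `"egger_intercept"`, `"median_simple"`, `"median_weighted"`,
#'   `"mbe_simple"`, `"mbe_weighted"`, `"mbe_simple_nome"`,
#'   `"mbe_weighted_nome"`.
#' @param settings an [mbe_settings()] controlling `phi`, `boot_reps`,
#'   `grid_points` and `ci_method` for the MBE and median estimators (their
#'   weighting/NOME options come from the estimator names).
#' @param seed master seed; defaults to `config$seed`.
#' @param point_only logical; when `TRUE` the bootstrap is skipped for the
#'   MBE and median estimators (their SE, coverage and power are `NA`) --
#'   useful when only mean estimates are needed.
#' @return data frame of class `mc_report` with one row per estimator and
#'   columns `estimator`, `mean_beta`, `mean_se`, `coverage_pct`,
#'   `power_pct`, `n_ok`; attributes `mean_f_attenuation`, `mean_igx2`
#'   (fractions), `n_reps`, `config` and `failures`.
#' @export
run_scenario <- function(config, n_reps,
                         estimators = c("ivw", "egger", "median_weighted",
                                        "mbe_simple", "mbe_weighted"),
                         settings = mbe_settings(boot_reps = 200,
                                                 grid_points = 2000),
                         seed = config$seed, point_only = FALSE) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_reps)
  nE <- length(estimators)
  res <- array(NA_real_, dim = c(n_reps, nE, 4L),
               dimnames = list(NULL, estimators,
                               c("beta", "se", "lo", "hi")))
  f_att <- numeric(n_reps)
  igx2 <- numeric(n_reps)
  failures <- stats::setNames(integer(nE), estimators)
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    data <- .simulate_two_sample(config)
    strength <- instrument_strength(data)
    f_att[i] <- strength$f_attenuation
    igx2[i] <- strength$igx2_floored
    for (k in seq_len(nE)) {
      out <- tryCatch(.apply_estimator(data, estimators[k], settings,
                                       point_only),
                      error = function(e) rep(NA_real_, 4L))
      if (all(is.na(out))) failures[k] <- failures[k] + 1L
      res[i, k, ] <- out
    }
  }
  truth <- config$beta
  bet <- matrix(res[, , "beta"], nrow = n_reps)
  ses <- matrix(res[, , "se"], nrow = n_reps)
  lo <- matrix(res[, , "lo"], nrow = n_reps)
  hi <- matrix(res[, , "hi"], nrow = n_reps)
  report <- data.frame(
    estimator = estimators,
    mean_beta = colMeans(bet, na.rm = TRUE),
    mean_se = colMeans(ses, na.rm = TRUE),
    coverage_pct = 100 * colMeans(lo <= truth & hi >= truth, na.rm = TRUE),
    power_pct = 100 * colMeans(lo > 0 | hi < 0, na.rm = TRUE),
    n_ok = n_reps - failures,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(report, class = c("mc_report", "data.frame"),
            mean_f_attenuation = mean(f_att),
            mean_igx2 = mean(igx2),
            n_reps = n_reps, config = config, failures = failures)
}

#' @export
print.mc_report <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Monte-Carlo report: %d replicates, L=%d, rho=%d, beta=%g, NX=%d, NY=%d, overlap=%g\n",
              attr(x, "n_reps"), cfg$L, cfg$rho, cfg$beta,
              cfg$n_exposure, cfg$n_outcome, cfg$overlap))
  cat(sprintf("mean (F-1)/F = %.1f%%, mean I2GX = %.1f%%\n",
              100 * attr(x, "mean_f_attenuation"),
              100 * attr(x, "mean_igx2")))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
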