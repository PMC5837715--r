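---
title: "Mode-based causal effect estimation for summary-data Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mode-based causal effect estimation for summary-data Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(modemr)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure X on an outcome Y from per-variant GWAS summary statistics: for
each genetic instrument j, the SNP-exposure association
$\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) and the SNP-outcome association
$\hat\beta_{Yj}$ (SE $\sigma_{Yj}$), estimated in non-overlapping samples.
Each variant supplies a ratio (Wald) estimate
$\hat\beta_{Rj} = \hat\beta_{Yj}/\hat\beta_{Xj}$ of the causal effect
$\beta$, with delta-method standard error

$$\sigma_{Rj} = \sqrt{\frac{\sigma_{Yj}^2}{\hat\beta_{Xj}^2} +
  \frac{\hat\beta_{Yj}^2\sigma_{Xj}^2}{\hat\beta_{Xj}^4}},$$

which simplifies to $\sigma_{Yj}/|\hat\beta_{Xj}|$ under the
NO-Measurement-Error (NOME) assumption that treats $\hat\beta_{Xj}$ as
exact. A horizontally pleiotropic variant — one affecting Y other than
through X — identifies $\beta + b_j$ instead of $\beta$, with bias
$b_j = \alpha_j/\beta_{Xj}$; a handful of such invalid instruments can
badly mislead the classical inverse-variance weighted (IVW) pooled
estimate.

## The mode-based estimate

The mode-based estimate (MBE) takes as the causal estimate the mode of the
smoothed empirical density of the ratio estimates,

$$f(x) = \frac{1}{h\sqrt{2\pi}}\sum_{j=1}^{L} w_j
  \exp\left[-\frac12\left(\frac{x-\hat\beta_{Rj}}{h}\right)^2\right],
  \qquad \hat\beta_M = \arg\max_x f(x),$$

with simple weights $w_j = 1/L$ or standardized inverse-variance weights
$w_j \propto \sigma_{Rj}^{-2}$ (computed with or without NOME). It is
consistent under the ZEro Modal Pleiotropy Assumption (ZEMPA): among the
bias values $b_j$, the most common one is zero. Valid instruments all
estimate the same quantity ($\beta$), so as samples grow their ratio
estimates pile up at one point; invalid instruments scatter unless several
share exactly the same bias. ZEMPA tolerates a *majority* of invalid
instruments — for the simple MBE the breakdown level ranges from
$100(\lfloor L/2\rfloor+1)/L$% (all invalid instruments share one bias) to
$100(L-2)/L$% (all biases distinct), computed by
`zempa_breakdown_bounds()`.

The bandwidth is $h = \phi s$ with $s$ from the modified Silverman rule

$$s = 0.9\,\min(\mathrm{sd}(\hat\beta_{R}),\,
  1.4826\,\mathrm{mad}(\hat\beta_{R}))\,L^{-1/5},$$

where the mad is the raw median absolute deviation from the median and the
1.4826 normal-consistency factor is applied inside the min. The tuning
parameter $\phi$ trades bias for variance: larger values smooth more
(precise but contaminable by invalid instruments with small biases),
smaller values sharpen the density. `density_scan()` evaluates the density
across a ladder of $\phi$ values on a shared grid so secondary peaks —
clusters of invalid instruments — can be inspected before choosing the
analysis value.

### Numerical choices

The density is maximized by exhaustive search on a uniform grid of
`grid_points` points (default 10,000) spanning
$[\min\hat\beta_R - 3h,\ \max\hat\beta_R + 3h]$; exact ties resolve to the
leftmost grid point. Kernels are truncated eight bandwidths from their
centre (a relative error below $e^{-32}$, far under double rounding at the
peak). The sd/mad in the bandwidth rule are always computed unweighted;
weights enter only through $f(x)$. Identical ratio estimates leave the rule
without a scale and raise a degenerate-bandwidth error rather than
guessing one.

### Uncertainty

Standard errors come from a parametric bootstrap on the ratio scale: each
replicate redraws $\hat\beta_{Rj}^* \sim N(\hat\beta_{Rj}, \sigma_{Rj}^2)$
(NOME or full SD matching the weight setting), recomputes the bandwidth,
and relocates the mode; the SE is 1.4826 times the median absolute
deviation of the bootstrap estimates, and the default 95% interval is
$\hat\beta_M \pm 1.959964\,\mathrm{SE}$ with a two-sided normal p-value. A
percentile interval (`ci_method = "percentile"`) is available, but the
normal interval is the default: in our Monte-Carlo runs percentile
intervals over-cover even more with few invalid instruments and lose
coverage abruptly past ~50% invalid. The ratio scale is the natural
resampling space because the ratio estimates and their SEs are exactly the
sufficient inputs the estimator consumes; $\sigma_{Rj}$ is held at its
observed value, and replicates with a degenerate bandwidth are redrawn
(with a warning past 10%). An alternative — resampling
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ jointly — would push ratio noise
slightly heavier-tailed at weak instruments; the bootstrap choice is
recorded in the estimate's metadata.

```{r example}
d <- generate_fixture("zempa_ok", L = 30, seed = 2, beta = 0.3)
mr_mbe(d, mbe_settings(weighting = "simple", phi = 1,
                       boot_reps = 500, seed = 1))
mr_ivw(d)
```

## Comparator estimators and diagnostics

* `mr_ivw()` — weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin, weights $\sigma_{Yj}^{-2}$; consistent only if
  pleiotropy is absent or balanced (under InSIDE).
* `mr_egger()` — the same regression with an intercept (the average
  directional pleiotropic effect); the slope is consistent under InSIDE
  even with 100% invalid instruments; p-values use $t_{L-2}$.
* `mr_median()` — simple median of the ratio estimates, or the weighted
  median interpolated at the 50th weighted percentile
  ($p_k = 100(S_k - w_k/2)$, NOME weights); consistent when valid
  instruments carry more than half the weight. SEs use the same
  ratio-scale bootstrap as the MBE.
* `cochran_q()` — heterogeneity of the ratio estimates about the
  fixed-effect IVW value (chi-squared, $L-1$ df), a pleiotropy screen.
* `instrument_strength()` — mean instrument F, the IVW attenuation factor
  $(\bar F - 1)/\bar F$, and $I^2_{GX}$, the analogous dilution factor for
  MR-Egger. $I^2_{GX}$ is stored raw (it can go negative in small samples)
  and additionally reported floored at zero.

Both regression estimators use multiplicative random-effects standard
errors: the fixed-effect SE times the residual standard deviation, floored
at 1 ($L-1$ df for IVW, $L-2$ for MR-Egger — the natural residual degrees
of freedom of each fit), with t-distribution quantiles on the same degrees
of freedom for intervals and p-values, as is conventional for that model
(the small extra width is what yields the mild over-coverage these
estimators are known for under valid instruments). The bootstrap-based
estimators (MBE, medians) use the fixed normal multiplier 1.959964 on
their robust bootstrap SE. These conventions are deliberate, documented
choices where several defensible ones exist.

## The simulation engine

`generate_cohort()` implements an individual-level generative model with a
genetic confounder pathway. For individual i with genotypes
$G_{ij} \sim \mathrm{Binomial}(2, p_j)$, $p_j \sim U(0.1, 0.9)$:

$$U_i = \sqrt{\gamma_U}\,Z_{Ui} + \epsilon_{Ui},\qquad
  X_i = \sqrt{\gamma_X}\,Z_{Xi} + \sqrt{\theta_X}\,U_i + \epsilon_{Xi},$$
$$Y_i = \sqrt{\gamma_Y}\,Z_{Yi} + \beta X_i + \sqrt{\theta_Y}\,U_i +
  \epsilon_{Yi},$$

where $Z_U, Z_X, Z_Y$ are allele scores with per-SNP loadings
$\delta_{Uj}, \delta_{Xj}, \delta_{Yj}$, each standardized by its sample
SD, and each error variance is set to one minus the sample variance of the
trait's systematic part so U, X and Y all have unit variance. The
parameters $\gamma$ and $\theta$ are **variance fractions** — e.g.
`gamma_x = 0.1` means the allele score explains 10% of exposure variance —
while $\beta$ is a plain coefficient on the unit-variance exposure, so
$\beta = 0.1$ explains exactly $\beta^2 = 1\%$ of outcome variance. This
variance-fraction parameterization is what makes the instrument-strength
diagnostics, estimator sampling variances and bias magnitudes of the four
preset scenarios mutually coherent; coding the same symbols as raw
coefficients would give per-variant F statistics an order of magnitude
smaller than the reference values the presets are designed to reproduce.

The four presets (`scenario_preset()`) share L = 30 variants,
$\theta_X = \theta_Y = 0.3$, $\gamma_X = 0.1$ and
$\gamma_U = \gamma_Y = \rho\,0.1/L$ with $\rho$ invalid instruments:

1. **simulation1** — causal null; the $\rho$ invalid instruments get
   direct outcome loadings $\delta_{Yj} \sim U(0.01, 0.2)$
   (InSIDE-respecting pleiotropy); 100,000 individuals split equally into
   exposure and outcome samples.
2. **simulation2** — causal null; invalid instruments load on the
   confounder, $\delta_{Uj} \sim U(0.01, 0.2)$ (InSIDE-violating).
3. **simulation3** — no pleiotropy, $\beta = 0.1$; sample sizes 25,000 to
   100,000 per side.
4. **simulation4** — causal null with 50% or 100% sample overlap at small
   sample sizes (the weak-instrument / winner's-curse regime).

The instrument-strength loadings $\delta_{Xj} \sim U(0.01, 0.2)$ for every
variant are drawn fresh each replicate, like the allele frequencies and
pleiotropic loadings, so instrument strength varies across variants and
replicates. Invalid instruments occupy the first $\rho$ indices.
Per-variant summary statistics are univariate OLS fits computed in a
single compiled pass (`extract_summary()`), and `run_scenario()` assembles
coverage (95% CI contains the truth) and power (CI excludes zero) across
replicates, reseeding each replicate from a master seed so results do not
depend on which estimators are requested.

```{r simulate}
cfg <- scenario_preset("simulation1", rho = 15)
run_scenario(cfg, n_reps = 20,
             estimators = c("ivw", "egger", "mbe_simple"),
             settings = mbe_settings(boot_reps = 100, grid_points = 2000),
             seed = 42)
```

What the generator emulates is the sampling structure of two-sample
summary MR with independent bi-allelic SNPs in Hardy–Weinberg equilibrium;
what it does not emulate includes linkage disequilibrium between
instruments, binary outcomes, allele-coding/harmonization errors, and
instrument selection by significance threshold (winner's curse beyond the
overlap design). Passing tests on this generator therefore validate the
estimators' statistical behaviour under the stated model, not robustness
to those real-data complications.

### Problem sizes used in the checks

The packaged test suite reruns the scenario grid at 1,000 replicates per
cell (the reference tables used 10,000) with bootstrap SEs from 200
replicates and a 2,000-point mode grid inside the Monte-Carlo loop
(10,000 points where mean point estimates are the quantity of interest);
`scripts/acceptance.R` uses 500 replicates. At these sizes Monte-Carlo
error is a few tenths of a point on coverage and about 0.003 on mean
estimates, comfortably inside the tolerances asserted. Single-dataset
analyses use the full defaults (1,000 bootstrap replicates, 10,000 grid
points).

## Known limitations

* The MBE's finite-sample mode can be contaminated by invalid instruments
  whose biases are small relative to the bandwidth, even when ZEMPA holds;
  the $\phi$-scan is a diagnostic, not a cure.
* The bandwidth rule needs spread: datasets whose ratio estimates are all
  identical are rejected rather than estimated.
* Bootstrap SEs assume normal sampling error on the ratio scale; with very
  weak instruments the true ratio distribution is heavier-tailed.
* The normal-approximation CI over-covers when instruments are valid
  (~99% observed), so power comparisons against IVW are conservative.
* No regression-dilution (NOME-violation) correction is applied to the
  MBE or median estimators; `instrument_strength()` quantifies the
  expected dilution for IVW and MR-Egger only.
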