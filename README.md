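# modemr

Pleiotropy-robust causal inference for two-sample Mendelian randomization
(MR) from per-variant GWAS summary statistics, built around the
**mode-based estimate (MBE)**.

## The problem and the method

MR uses genetic variants as instrumental variables: each variant j with
SNP-exposure association β̂<sub>Xj</sub> (SE σ<sub>Xj</sub>) and
SNP-outcome association β̂<sub>Yj</sub> (SE σ<sub>Yj</sub>) yields a ratio
estimate β̂<sub>Rj</sub> = β̂<sub>Yj</sub>/β̂<sub>Xj</sub> of the causal
effect β. Horizontally pleiotropic ("invalid") variants instead identify
β + b<sub>j</sub>, and a few of them can badly bias the classical
inverse-variance weighted (IVW) pooled estimate.

The MBE takes as the causal estimate the **mode of the smoothed density**
of the ratio estimates,

    f(x) = (1 / (h√(2π))) Σⱼ wⱼ exp(−½((x − β̂_Rj)/h)²),   β̂_M = argmaxₓ f(x),

with simple (1/L) or inverse-variance weights, bandwidth h = φ·s from the
modified Silverman rule s = 0.9·min(sd, 1.4826·mad)·L^(−1/5), standard
errors from a ratio-scale parametric bootstrap (1.4826 × MAD of the
bootstrap modes), and symmetric normal 95% intervals. The estimator is
consistent under the **ZEro Modal Pleiotropy Assumption (ZEMPA)** — the
most common bias value among the instruments is zero — which can hold even
when *most* instruments are invalid, provided their biases differ.

The package also provides the comparator estimators (IVW, MR-Egger,
simple/weighted median, all with multiplicative random-effects standard
errors), heterogeneity and instrument-strength diagnostics (Cochran's Q,
mean F, (F̄−1)/F̄, I²GX), a bandwidth-scan density explorer for
multimodality triage, and a compiled individual-level Monte-Carlo
simulator of valid and invalid instruments for evaluating bias, coverage
and power.

## Worked example

```r
library(modemr)

# 30 instruments, 23 of them invalid with distinct pleiotropic biases,
# true causal effect 0.3 (ZEMPA holds: the modal bias is zero)
d <- generate_fixture("zempa_ok", L = 30, seed = 2, beta = 0.3)

mr_mbe(d, mbe_settings(weighting = "simple", phi = 1,
                       boot_reps = 500, seed = 1))
#> MBE (simple, phi=1)
#>   beta = 0.3673 (SE 0.1207)
#>   95% CI [0.1307, 0.6039], p = 0.002346

mr_ivw(d)
#> IVW
#>   beta = 0.7744 (SE 0.2725)
#>   95% CI [0.2403, 1.309], p = 0.004489
```

The simple MBE recovers the true effect 0.3 within its interval while IVW,
which averages over every instrument, is biased upward by more than a
factor of two. `cochran_q(d)` flags the heterogeneity (Q ≈ 23 887 on 29
df), and `density_scan(d, phis = c(1, 0.5, 0.25))` shows the ratio-estimate
density sharpening into its constituent peaks as φ decreases.

Real summary data are read with
`read_summary_table()` (tab-separated columns `snp`, `beta_exposure`,
`se_exposure`, `beta_outcome`, `se_outcome`; SEs recoverable from p-values
when absent). A command-line interface wrapping the same functions is
installed at `system.file("cli", "modemr", package = "modemr")` with
`estimate`, `density`, `simulate` and `fixtures` subcommands.

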