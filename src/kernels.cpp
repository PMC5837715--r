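#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Genotypes G_ij ~ Binomial(2, p_j), drawn as two Bernoulli trials from the
// R RNG stream so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".cpp_genotypes")]]
IntegerMatrix cpp_genotypes(int n, NumericVector p) {
  const int L = p.size();
  IntegerMatrix G(n, L);
  for (int j = 0; j < L; ++j) {
    const double pj = p[j];
    int *col = &G(0, j);
    for (int i = 0; i < n; ++i) {
      col[i] = (unif_rand() < pj) + (unif_rand() < pj);
    }
  }
  return G;
}

// Allele score sum_j delta_j G_ij without converting G to double.
// [[Rcpp::export(name = ".cpp_score")]]
NumericVector cpp_score(IntegerMatrix G, NumericVector delta) {
  const int n = G.nrow(), L = G.ncol();
  NumericVector z(n);
  for (int j = 0; j < L; ++j) {
    const double d = delta[j];
    if (d == 0.0) continue;
    const int *col = &G(0, j);
    for (int i = 0; i < n; ++i) z[i] += d * col[i];
  }
  return z;
}

// Univariate OLS slope and SE of trait on each genotype column, restricted
// to rows [row_start, row_end) (0-based). One pass per column; residual
// variance on n-2 df. Returns L x 3 matrix: beta, se, sxx.
// [[Rcpp::export(name = ".cpp_col_regress")]]
NumericMatrix cpp_col_regress(IntegerMatrix G, NumericVector trait,
                              int row_start, int row_end) {
  const int L = G.ncol();
  const int n = row_end - row_start;
  if (n < 3) stop("need at least 3 individuals");
  double st = 0.0, st2 = 0.0;
  for (int i = row_start; i < row_end; ++i) {
    st += trait[i];
    st2 += trait[i] * trait[i];
  }
  const double tm = st / n;
  const double syy = st2 - n * tm * tm;
  NumericMatrix out(L, 3);
  for (int j = 0; j < L; ++j) {
    const int *col = &G(0, j);
    double sg = 0.0, sg2 = 0.0, sgt = 0.0;
    for (int i = row_start; i < row_end; ++i) {
      const double g = col[i];
      sg += g;
      sg2 += g * g;
      sgt += g * trait[i];
    }
    const double gm = sg / n;
    const double sxx = sg2 - n * gm * gm;
    if (sxx <= 0.0) {
      out(j, 0) = NA_REAL; out(j, 1) = NA_REAL; out(j, 2) = 0.0;
      continue;
    }
    const double sxy = sgt - n * gm * tm;
    const double beta = sxy / sxx;
    double rss = syy - beta * sxy;
    if (rss < 0.0) rss = 0.0;
    out(j, 0) = beta;
    out(j, 1) = std::sqrt(rss / (n - 2) / sxx);
    out(j, 2) = sxx;
  }
  return out;
}

static double density_mode(const std::vector<double> &r,
                           const NumericVector &w, double h,
                           int grid_points) {
  // leftmost argmax of the weighted normal-kernel density on a uniform grid
  // spanning [min - 3h, max + 3h]; kernels truncated at 8h (exp(-32)).
  const int L = r.size();
  double rmin = r[0], rmax = r[0];
  for (int j = 1; j < L; ++j) {
    if (r[j] < rmin) rmin = r[j];
    if (r[j] > rmax) rmax = r[j];
  }
  const double lo = rmin - 3.0 * h, hi = rmax + 3.0 * h;
  const double step = (hi - lo) / (grid_points - 1);
  std::vector<double> f(grid_points, 0.0);
  const double inv_h = 1.0 / h;
  for (int j = 0; j < L; ++j) {
    const double wj = w[j];
    int k0 = (int)std::ceil((r[j] - 8.0 * h - lo) / step);
    int k1 = (int)std::floor((r[j] + 8.0 * h - lo) / step);
    if (k0 < 0) k0 = 0;
    if (k1 > grid_points - 1) k1 = grid_points - 1;
    for (int k = k0; k <= k1; ++k) {
      const double z = (lo + k * step - r[j]) * inv_h;
      f[k] += wj * std::exp(-0.5 * z * z);
    }
  }
  int best = 0;
  for (int k = 1; k < grid_points; ++k)
    if (f[k] > f[best]) best = k;
  return lo + best * step;
}

// [[Rcpp::export(name = ".cpp_mode_grid")]]
double cpp_mode_grid(NumericVector ratios, NumericVector weights, double h,
                     int grid_points) {
  std::vector<double> r(ratios.begin(), ratios.end());
  return density_mode(r, weights, h, grid_points);
}

static double sd_of(const std::vector<double> &x) {
  const int n = x.size();
  double m = 0.0;
  for (double v : x) m += v;
  m /= n;
  double s2 = 0.0;
  for (double v : x) s2 += (v - m) * (v - m);
  return std::sqrt(s2 / (n - 1));
}

static double median_of(std::vector<double> x) {
  const int n = x.size();
  std::sort(x.begin(), x.end());
  return (n % 2) ? x[n / 2] : 0.5 * (x[n / 2 - 1] + x[n / 2]);
}

// Parametric bootstrap of the density mode: each replicate redraws every
// ratio from N(ratio_j, sd_j), recomputes the modified Silverman bandwidth
// (raw mad, 1.4826 inside the min) and relocates the grid mode. Replicates
// with a degenerate bandwidth are rejected and redrawn. Returns the vector
// of estimates with attribute n_rejected.
// [[Rcpp::export(name = ".cpp_mbe_boot")]]
NumericVector cpp_mbe_boot(NumericVector ratios, NumericVector weights,
                           NumericVector sd_r, int boot_reps, double phi,
                           int grid_points) {
  const int L = ratios.size();
  NumericVector est(boot_reps);
  const double lcorr = 0.9 * std::pow((double)L, -0.2);
  std::vector<double> r(L), dev(L);
  int n_rejected = 0;
  const long max_reject = 100L * boot_reps;
  for (int b = 0; b < boot_reps;) {
    for (int j = 0; j < L; ++j) r[j] = ratios[j] + sd_r[j] * norm_rand();
    const double med = median_of(r);
    for (int j = 0; j < L; ++j) dev[j] = std::fabs(r[j] - med);
    const double mad = median_of(dev);
    const double s = lcorr * std::min(sd_of(r), 1.4826 * mad);
    if (!(s > 0.0)) {
      if (++n_rejected > max_reject)
        stop("bootstrap failed: resampled ratios are persistently degenerate");
      continue;
    }
    est[b++] = density_mode(r, weights, phi * s, grid_points);
  }
  est.attr("n_rejected") = n_rejected;
  return est;
}
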