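// Compiled hot paths: empirical-control resampling sums for the fluorescence
// noise model, and the two-sample distribution statistics used as ABC
// distances. All random draws use R's RNG stream so results are reproducible
// from set.seed() alone.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Per-cell sums of floor(p) draws from the particle control plus the
// fractional remainder times one further draw, plus one autofluorescence
// draw per cell. Equivalent to uniform-with-replacement resampling.
// [[Rcpp::export(name = ".simulate_fluorescence_cpp")]]
NumericVector simulate_fluorescence_cpp(NumericVector p,
                                        NumericVector cells,
                                        NumericVector particles) {
  const int n = p.size();
  const int ncell = cells.size();
  const int npart = particles.size();
  NumericVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    const double pi = p[i];
    const double fl = std::floor(pi);
    double s = cells[std::min((int)(unif_rand() * ncell), ncell - 1)];
    const int m = (int)fl;
    for (int k = 0; k < m; ++k) {
      s += particles[std::min((int)(unif_rand() * npart), npart - 1)];
    }
    s += (pi - fl) * particles[std::min((int)(unif_rand() * npart), npart - 1)];
    out[i] = s;
  }
  return out;
}

// Shared preparation: sorted pooled sample with origin flags. Each sample is
// sorted separately (skipped when already sorted, which the SMC loop exploits
// by pre-sorting the fixed observed sample) and the two runs are merged.
static void pool_sort(const NumericVector& x, const NumericVector& y,
                      std::vector<std::pair<double, int> >& z) {
  const int n1 = x.size(), n2 = y.size();
  z.resize(n1 + n2);
  for (int i = 0; i < n1; ++i) z[i] = std::make_pair(x[i], 0);
  for (int j = 0; j < n2; ++j) z[n1 + j] = std::make_pair(y[j], 1);
  if (!std::is_sorted(z.begin(), z.begin() + n1))
    std::sort(z.begin(), z.begin() + n1);
  if (!std::is_sorted(z.begin() + n1, z.end()))
    std::sort(z.begin() + n1, z.end());
  std::inplace_merge(z.begin(), z.begin() + n1, z.end());
}

// Tie-adjusted, non-standardized two-sample Anderson-Darling statistic
// (k-sample family, k = 2, midrank version).
// [[Rcpp::export(name = ".ad2_stat_cpp")]]
double ad2_stat_cpp(NumericVector x, NumericVector y) {
  const int n1 = x.size(), n2 = y.size();
  const int N = n1 + n2;
  std::vector<std::pair<double, int> > z;
  pool_sort(x, y, z);
  double sum = 0.0;
  int f1 = 0, fall = 0;  // cumulative counts up to the current distinct value
  int i = 0;
  while (i < N) {
    int j = i;
    int c1 = 0;
    while (j < N && z[j].first == z[i].first) {
      if (z[j].second == 0) ++c1;
      ++j;
    }
    const int l = j - i;
    const double Ma1 = f1 + c1 / 2.0;
    const double Ba = fall + l / 2.0;
    const double Ma2 = Ba - Ma1;
    const double denom = Ba * (N - Ba) - N * l / 4.0;
    if (denom > 0) {
      const double t1 = N * Ma1 - n1 * Ba;
      const double t2 = N * Ma2 - n2 * Ba;
      sum += (double)l / N * (t1 * t1 / n1 + t2 * t2 / n2) / denom;
    }
    f1 += c1;
    fall += l;
    i = j;
  }
  return (N - 1.0) / N * sum;
}

// Two-sample Cramer-von Mises statistic: n1 n2 / N^2 * sum over pooled
// observations of the squared ECDF difference.
// [[Rcpp::export(name = ".cvm2_stat_cpp")]]
double cvm2_stat_cpp(NumericVector x, NumericVector y) {
  const int n1 = x.size(), n2 = y.size();
  const int N = n1 + n2;
  std::vector<std::pair<double, int> > z;
  pool_sort(x, y, z);
  double sum = 0.0;
  int f1 = 0, fall = 0;
  int i = 0;
  while (i < N) {
    int j = i, c1 = 0;
    while (j < N && z[j].first == z[i].first) {
      if (z[j].second == 0) ++c1;
      ++j;
    }
    const int l = j - i;
    f1 += c1;
    fall += l;
    const double d = (double)f1 / n1 - (double)(fall - f1) / n2;
    sum += l * d * d;
    i = j;
  }
  return (double)n1 * n2 / ((double)N * N) * sum;
}

// Two-sample Kolmogorov-Smirnov distance.
// [[Rcpp::export(name = ".ks2_stat_cpp")]]
double ks2_stat_cpp(NumericVector x, NumericVector y) {
  const int n1 = x.size(), n2 = y.size();
  const int N = n1 + n2;
  std::vector<std::pair<double, int> > z;
  pool_sort(x, y, z);
  double best = 0.0;
  int f1 = 0, fall = 0;
  int i = 0;
  while (i < N) {
    int j = i, c1 = 0;
    while (j < N && z[j].first == z[i].first) {
      if (z[j].second == 0) ++c1;
      ++j;
    }
    f1 += c1;
    fall += j - i;
    const double d = std::fabs((double)f1 / n1 - (double)(fall - f1) / n2);
    if (d > best) best = d;
    i = j;
  }
  return best;
}
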