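#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Two-sample ECDF statistics and label-permutation inference.
// Values are sorted once; permutations only shuffle the group labels, so each
// shuffle costs O(N) statistic evaluation. All randomness goes through R's RNG
// (unif_rand), so set.seed() in R controls reproducibility.

// Tie-adjusted (midrank) two-sample Anderson-Darling statistic A2akN.
// `values` ascending, `grp` 0/1 aligned with values.
static double ad_stat_sorted(const std::vector<double>& values,
                             const std::vector<int>& grp) {
  const int N = values.size();
  int n1 = 0;
  for (int i = 0; i < N; ++i) n1 += (grp[i] == 0);
  const int n2 = N - n1;
  if (n1 == 0 || n2 == 0) return NA_REAL;

  double inner1 = 0.0, inner2 = 0.0;
  int i = 0;
  double M1 = 0.0, B = 0.0; // cumulative counts through previous distinct value
  while (i < N) {
    int j = i;
    int f1 = 0;
    while (j < N && values[j] == values[i]) {
      f1 += (grp[j] == 0);
      ++j;
    }
    const double lj = j - i;          // multiplicity of this distinct value
    const double f1j = f1;
    const double Bt = B + lj / 2.0;   // midrank cumulative pooled count
    const double M1t = M1 + f1j / 2.0;
    const double M2t = (B - M1) + (lj - f1j) / 2.0;
    const double denom = Bt * (N - Bt) - N * lj / 4.0;
    if (denom > 0) {
      const double t1 = N * M1t - n1 * Bt;
      const double t2 = N * M2t - n2 * Bt;
      inner1 += lj / (double)N * (t1 * t1) / denom;
      inner2 += lj / (double)N * (t2 * t2) / denom;
    }
    M1 += f1j;
    B += lj;
    i = j;
  }
  return (N - 1.0) / N * (inner1 / n1 + inner2 / n2);
}

// DTS: integral of |F1 - F2| over the gaps between pooled order statistics,
// weighted by the reciprocal binomial standard deviation of the pooled ECDF.
static double dts_stat_sorted(const std::vector<double>& values,
                              const std::vector<int>& grp) {
  const int N = values.size();
  int n1 = 0;
  for (int i = 0; i < N; ++i) n1 += (grp[i] == 0);
  const int n2 = N - n1;
  if (n1 == 0 || n2 == 0) return NA_REAL;

  double c1 = 0.0, c2 = 0.0, stat = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    if (grp[i] == 0) c1 += 1.0; else c2 += 1.0;
    const double gap = values[i + 1] - values[i];
    if (gap <= 0) continue;
    const double Fp = (c1 + c2) / N;
    const double w = std::sqrt(Fp * (1.0 - Fp));
    if (w > 0)
      stat += std::fabs(c1 / n1 - c2 / n2) * gap / w;
  }
  return stat;
}

static double meandiff_stat(const std::vector<double>& values,
                            const std::vector<int>& grp) {
  double s1 = 0.0, s2 = 0.0;
  int n1 = 0, n2 = 0;
  for (size_t i = 0; i < values.size(); ++i) {
    if (grp[i] == 0) { s1 += values[i]; ++n1; } else { s2 += values[i]; ++n2; }
  }
  if (n1 == 0 || n2 == 0) return NA_REAL;
  return std::fabs(s1 / n1 - s2 / n2);
}

static double eval_stat(const std::vector<double>& values,
                        const std::vector<int>& grp, int method) {
  switch (method) {
    case 0: return ad_stat_sorted(values, grp);
    case 1: return dts_stat_sorted(values, grp);
    default: return meandiff_stat(values, grp);
  }
}

// [[Rcpp::export(name = ".ecdf_stat_cpp")]]
double ecdf_stat_cpp(NumericVector x, NumericVector y, std::string method) {
  const int n1 = x.size(), n2 = y.size(), N = n1 + n2;
  std::vector<std::pair<double, int> > pooled(N);
  for (int i = 0; i < n1; ++i) pooled[i] = std::make_pair(x[i], 0);
  for (int i = 0; i < n2; ++i) pooled[n1 + i] = std::make_pair(y[i], 1);
  std::sort(pooled.begin(), pooled.end());
  std::vector<double> values(N);
  std::vector<int> grp(N);
  for (int i = 0; i < N; ++i) { values[i] = pooled[i].first; grp[i] = pooled[i].second; }
  const int m = (method == "ad") ? 0 : (method == "dts") ? 1 : 2;
  return eval_stat(values, grp, m);
}

// [[Rcpp::export(name = ".ecdf_perm_test_cpp")]]
List ecdf_perm_test_cpp(NumericVector x, NumericVector y, std::string method,
                        int n_perm) {
  const int n1 = x.size(), n2 = y.size(), N = n1 + n2;
  std::vector<std::pair<double, int> > pooled(N);
  for (int i = 0; i < n1; ++i) pooled[i] = std::make_pair(x[i], 0);
  for (int i = 0; i < n2; ++i) pooled[n1 + i] = std::make_pair(y[i], 1);
  std::sort(pooled.begin(), pooled.end());
  std::vector<double> values(N);
  std::vector<int> grp(N);
  for (int i = 0; i < N; ++i) { values[i] = pooled[i].first; grp[i] = pooled[i].second; }
  const int m = (method == "ad") ? 0 : (method == "dts") ? 1 : 2;

  const double obs = eval_stat(values, grp, m);
  if (!R_finite(obs))
    return List::create(_["statistic"] = obs, _["p_value"] = NA_REAL);

  int count_ge = 0;
  std::vector<int> perm(grp);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates over the label vector (values stay sorted in place)
    for (int i = N - 1; i > 0; --i) {
      const int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(perm[i], perm[j]);
    }
    const double s = eval_stat(values, perm, m);
    if (R_finite(s) && s >= obs) ++count_ge;
  }
  const double p = (1.0 + count_ge) / (n_perm + 1.0);
  return List::create(_["statistic"] = obs, _["p_value"] = p);
}
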