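#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation core: the O(n^2) scan for the maximal
// circular mean-shift statistic and its permutation test.  The statistic for
// the arc (i, j] of an n-bin segment is |D| / sqrt(m (n - m)) with
// D = (S_j - S_i) - (m / n) S_n, m = j - i, which is the circular t
// statistic up to the (permutation-invariant) scale of the residual
// variance, so the permutation test is unchanged by dropping that factor.

// [[Rcpp::export]]
List cbs_max_stat(NumericVector x) {
  const int n = x.size();
  if (n < 2)
    return List::create(_["i"] = 0, _["j"] = n, _["stat"] = 0.0);
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double Sn = S[n];
  double best = -1.0;
  int bi = 0, bj = n;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      const int m = j - i;
      if (m >= n) continue;
      const double D = (S[j] - S[i]) - (double(m) / n) * Sn;
      const double z = std::fabs(D) / std::sqrt(double(m) * (n - m));
      if (z > best) { best = z; bi = i; bj = j; }
    }
  }
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = best);
}

// Permutation exceedance count for the observed maximal statistic, with two
// accelerations that do not change the decision: the scan of a permuted
// vector stops at the first arc reaching the observed statistic, and the
// permutation loop stops once the exceedance count already exceeds
// max_exceed (the largest count still compatible with significance).
// Uses R's RNG (seed from set.seed in the caller).

// [[Rcpp::export]]
int cbs_perm_exceed(NumericVector x, double obs, int nperm, int max_exceed) {
  const int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  std::vector<double> S(n + 1, 0.0);
  int exceed = 0;
  for (int p = 0; p < nperm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int r = int(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(y[k], y[r]);
    }
    for (int t = 0; t < n; ++t) S[t + 1] = S[t] + y[t];
    const double Sn = S[n];
    bool hit = false;
    for (int i = 0; i < n && !hit; ++i) {
      for (int j = i + 1; j <= n; ++j) {
        const int m = j - i;
        if (m >= n) continue;
        const double D = (S[j] - S[i]) - (double(m) / n) * Sn;
        if (std::fabs(D) >= obs * std::sqrt(double(m) * (n - m)) - 1e-12) {
          hit = true;
          break;
        }
      }
    }
    if (hit && ++exceed > max_exceed) return exceed;
  }
  return exceed;
}
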