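// Felsenstein pruning for the isolation-with-migration sampler: HKY
// log-likelihood of a coalescent genealogy over compressed site
// patterns. Called once per likelihood-affecting MCMC move, so it is the
// sampler's hot path.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export]]
double cpp_state_loglik(NumericVector times, IntegerVector parent,
                        IntegerMatrix child, int root, int n_tip,
                        IntegerMatrix pattern_idx, NumericVector weights,
                        NumericMatrix U, NumericMatrix Uinv,
                        NumericVector lambda, NumericVector freqs,
                        double mu_scale) {
  const int n_nodes = times.size();
  const int P = pattern_idx.ncol();

  // internal nodes in ascending time order (children precede parents in
  // a coalescent genealogy)
  std::vector<int> internal;
  internal.reserve(n_nodes - n_tip);
  for (int v = n_tip; v < n_nodes; ++v) internal.push_back(v);
  std::sort(internal.begin(), internal.end(),
            [&](int a, int b) { return times[a] < times[b]; });

  std::vector<std::vector<double>> partial(n_nodes),
      lsc(n_nodes, std::vector<double>());
  double Pm[16];

  for (int v : internal) {
    std::vector<double> acc(4 * P, 1.0);
    std::vector<double> sc(P, 0.0);
    for (int ci = 0; ci < 2; ++ci) {
      int ch = child(v, ci) - 1; // R 1-based
      double b = (times[v] - times[ch]) * mu_scale;
      // Pm = U diag(exp(lambda b)) Uinv
      double el[4];
      for (int k = 0; k < 4; ++k) el[k] = std::exp(lambda[k] * b);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += U(i, k) * el[k] * Uinv(k, j);
          Pm[4 * i + j] = s > 0.0 ? s : 0.0;
        }
      if (ch < n_tip) {
        for (int p = 0; p < P; ++p) {
          int s = pattern_idx(ch, p) - 1;
          for (int i = 0; i < 4; ++i) acc[4 * p + i] *= Pm[4 * i + s];
        }
      } else {
        const std::vector<double>& cp = partial[ch];
        const std::vector<double>& cs = lsc[ch];
        for (int p = 0; p < P; ++p) {
          for (int i = 0; i < 4; ++i) {
            double s = 0.0;
            for (int j = 0; j < 4; ++j)
              s += Pm[4 * i + j] * cp[4 * p + j];
            acc[4 * p + i] *= s;
          }
          sc[p] += cs[p];
        }
      }
    }
    // rescale per pattern
    for (int p = 0; p < P; ++p) {
      double mx = 0.0;
      for (int i = 0; i < 4; ++i) mx = std::max(mx, acc[4 * p + i]);
      if (mx <= 0.0) return R_NegInf;
      for (int i = 0; i < 4; ++i) acc[4 * p + i] /= mx;
      sc[p] += std::log(mx);
    }
    partial[v] = std::move(acc);
    lsc[v] = std::move(sc);
  }

  const std::vector<double>& rp = partial[root - 1];
  const std::vector<double>& rs = lsc[root - 1];
  double ll = 0.0;
  for (int p = 0; p < P; ++p) {
    double lik = 0.0;
    for (int i = 0; i < 4; ++i) lik += freqs[i] * rp[4 * p + i];
    if (lik <= 0.0) return R_NegInf;
    ll += weights[p] * (std::log(lik) + rs[p]);
  }
  return ll;
}
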