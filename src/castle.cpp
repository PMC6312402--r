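#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-element log-likelihood curves for the efficacy-mixture effect model.
// For element i with enrichment rho_i and candidate effect e, the likelihood
// is the mean over an efficacy grid t in [0,1] of f0(rho_i - t*e), where f0
// is the control-derived null density given on an equally spaced grid
// (x0, dx, f) and evaluated by linear interpolation with a positive floor.
// Returns an n x G matrix of log-likelihoods.
// [[Rcpp::export]]
NumericMatrix loglik_curves_cpp(NumericVector rho, NumericVector grid_e,
                                NumericVector grid_t, double x0, double dx,
                                NumericVector f, double floor_val) {
  int n = rho.size(), G = grid_e.size(), m = grid_t.size(), nf = f.size();
  NumericMatrix out(n, G);
  std::vector<double> fr(f.begin(), f.end());
  for (int g = 0; g < G; ++g) {
    double e = grid_e[g];
    for (int i = 0; i < n; ++i) {
      double s = 0.0, r = rho[i];
      for (int t = 0; t < m; ++t) {
        double v = r - grid_t[t] * e;
        double pos = (v - x0) / dx;
        double fv;
        if (pos <= 0.0 || pos >= nf - 1) {
          fv = floor_val;
        } else {
          int lo = (int) pos;
          double w = pos - lo;
          fv = fr[lo] * (1.0 - w) + fr[lo + 1] * w;
          if (fv < floor_val) fv = floor_val;
        }
        s += fv;
      }
      out(i, g) = std::log(s / m);
    }
    if (g % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Permutation null for gene scores: B random k-subsets of the targeting
// pool. Each subset's curve is the column sum of its element curves; the
// score is 2 * (max over the effect grid - value at e = 0), floored at 0.
// Uses R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector perm_scores_cpp(NumericMatrix E, int e0_idx, int k, int B) {
  int n = E.nrow(), G = E.ncol();
  if (k > n) stop("subset size exceeds pool size");
  NumericVector out(B);
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<double> acc(G);
  int e0 = e0_idx - 1;
  for (int b = 0; b < B; ++b) {
    if (b % 512 == 0) Rcpp::checkUserInterrupt();
    for (int j = 0; j < k; ++j) {
      int r = j + (int) (unif_rand() * (n - j));
      if (r >= n) r = n - 1;
      std::swap(pool[j], pool[r]);
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < k; ++j) {
      int row = pool[j];
      for (int g = 0; g < G; ++g) acc[g] += E(row, g);
    }
    double mx = acc[0];
    for (int g = 1; g < G; ++g) if (acc[g] > mx) mx = acc[g];
    double sc = 2.0 * (mx - acc[e0]);
    out[b] = sc > 0.0 ? sc : 0.0;
  }
  return out;
}
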