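#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Circular binary segmentation kernel.
//
// For a stretch x[0..n-1] joined into a circle, every arc (i, j] (inside =
// x[i..j-1], 0-based) is scored with the pooled two-sample t statistic of
// inside vs outside means. Arcs wrapping the origin are equivalent to their
// complements, so scanning i < j covers all circular splits. Significance of
// the maximal statistic is assessed by permutation; the permutation loop
// stops early once the exceedance count already forces p > alpha.

struct ArcMax {
  double t;
  int i, j; // inside = (i, j] in 0-based half-open terms: x[i..j-1]
};

static ArcMax max_arc_t(const std::vector<double>& x) {
  const int n = (int)x.size();
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    cs[k + 1] = cs[k] + x[k];
    css[k + 1] = css[k] + x[k] * x[k];
  }
  ArcMax best = {0.0, 0, 1};
  const double stot = cs[n], sstot = css[n];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      const int m = j - i;
      if (m == n) continue;
      const int out = n - m;
      const double sin = cs[j] - cs[i];
      const double ssin = css[j] - css[i];
      const double sout = stot - sin;
      const double ssout = sstot - ssin;
      const double min_ = sin / m, mout = sout / out;
      double ssw = (ssin - sin * sin / m) + (ssout - sout * sout / out);
      if (ssw < 0) ssw = 0;
      const double sp2 = ssw / (n - 2);
      const double se2 = sp2 * (1.0 / m + 1.0 / out);
      const double diff = min_ - mout;
      double t;
      if (se2 <= 0.0) {
        t = (diff == 0.0) ? 0.0 : 1e12;
      } else {
        t = std::fabs(diff) / std::sqrt(se2);
      }
      if (t > best.t) {
        best.t = t;
        best.i = i;
        best.j = j;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cbs_max_arc")]]
List cbs_max_arc(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  ArcMax b = max_arc_t(v);
  return List::create(_["t"] = b.t, _["i"] = b.i, _["j"] = b.j);
}

// [[Rcpp::export(name = ".cbs_best_split")]]
List cbs_best_split(NumericVector x, int n_perm, double alpha, int seed) {
  std::vector<double> v(x.begin(), x.end());
  const int n = (int)v.size();
  ArcMax obs = max_arc_t(v);
  if (n < 4 || obs.t <= 0.0) {
    return List::create(_["t"] = obs.t, _["i"] = obs.i, _["j"] = obs.j,
                        _["p"] = 1.0, _["n_perm_used"] = 0);
  }
  std::mt19937 rng((uint32_t)seed);
  std::vector<double> perm(v);
  int exceed = 0, done = 0;
  // p > alpha is certain once exceed > alpha * n_perm: stop permuting
  const int stop_at = (int)std::floor(alpha * n_perm) + 1;
  const double thresh = obs.t * (1.0 - 1e-12);
  for (int b = 0; b < n_perm; ++b) {
    for (int k = n - 1; k > 0; --k) {
      std::uniform_int_distribution<int> u(0, k);
      std::swap(perm[k], perm[u(rng)]);
    }
    ++done;
    if (max_arc_t(perm).t >= thresh) {
      ++exceed;
      if (exceed >= stop_at) break;
    }
  }
  double p = (done > 0) ? (double)exceed / (double)done : 1.0;
  return List::create(_["t"] = obs.t, _["i"] = obs.i, _["j"] = obs.j,
                      _["p"] = p, _["n_perm_used"] = done);
}
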