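#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation kernel: max circular two-sample t scan and the
// permutation split test. The series is one chromosome-arm Z (or log-ratio)
// vector; arcs [i, j) are compared against their (circular) complement with a
// pooled-variance t statistic. Scanning non-wrapping arcs suffices: a wrapped
// arc and its complement give the same |t|.

namespace {

struct ScanResult {
  int i, j;       // arc is x[i..j-1]; -1/-1 when no admissible arc
  double t;       // |t| of the best arc
};

// Scan all admissible arcs. Tie-break: first encountered with i ascending,
// then j ascending (strict > comparison). min_width constrains every piece a
// split would create: the arc itself and each non-empty flank.
// If tstop > 0, return early as soon as any arc reaches |t| >= tstop
// (used inside permutations, where only exceedance matters).
ScanResult max_t_scan(const std::vector<double>& x, int min_width, double tstop) {
  const int n = static_cast<int>(x.size());
  ScanResult best = {-1, -1, 0.0};
  if (n < 2 * min_width) return best;

  std::vector<double> S(n + 1, 0.0);
  double Q = 0.0;
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    Q += x[k] * x[k];
  }
  const double T = S[n];
  const double ss_dev = Q - T * T / n;  // total sum of squared deviations

  for (int i = 0; i <= n - min_width; ++i) {
    if (i > 0 && i < min_width) continue;  // left flank too small
    for (int j = i + min_width; j <= n; ++j) {
      const int m = j - i;
      if (n - m < min_width) break;        // complement too small; grows with j
      if (j < n && n - j < min_width) continue;  // right flank too small
      const double sum1 = S[j] - S[i];
      const double mean1 = sum1 / m;
      const double mean2 = (T - sum1) / (n - m);
      const double diff = mean1 - mean2;
      const double between = diff * diff * (static_cast<double>(m) * (n - m) / n);
      double t;
      if (n > 2) {
        double sp2 = (ss_dev - between) / (n - 2);
        if (sp2 < 1e-300) {
          t = (std::fabs(diff) > 0.0) ? 1e300 : 0.0;
        } else {
          t = std::fabs(diff) /
              std::sqrt(sp2 * (1.0 / m + 1.0 / (n - m)));
        }
      } else {
        t = (std::fabs(diff) > 0.0) ? 1e300 : 0.0;
      }
      if (t > best.t) {
        best.t = t;
        best.i = i;
        best.j = j;
        if (tstop > 0.0 && best.t >= tstop) return best;
      }
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  ScanResult r = max_t_scan(v, min_width, -1.0);
  return List::create(_["i"] = r.i, _["j"] = r.j, _["t"] = r.t);
}

// Permutation split test. Uses R's RNG (seed controlled from R). The
// permutation loop stops early once enough exceedances have accrued to
// guarantee p >= alpha, and each permutation's scan stops as soon as it
// exceeds the observed statistic.
// [[Rcpp::export]]
List cbs_split_test(NumericVector x, int min_width, int n_perm, double alpha) {
  std::vector<double> v(x.begin(), x.end());
  ScanResult obs = max_t_scan(v, min_width, -1.0);
  if (obs.i < 0) {
    return List::create(_["i"] = -1, _["j"] = -1, _["t"] = 0.0,
                        _["p"] = 1.0, _["n_perm_used"] = 0);
  }
  const int stop_count = static_cast<int>(std::ceil(alpha * (1.0 + n_perm)));
  int exceed = 0, used = 0;
  RNGScope scope;
  std::vector<double> perm(v);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates using R's RNG
    for (int k = static_cast<int>(perm.size()) - 1; k > 0; --k) {
      int idx = static_cast<int>(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(perm[k], perm[idx]);
    }
    ScanResult pr = max_t_scan(perm, min_width, obs.t);
    ++used;
    if (pr.t >= obs.t) {
      ++exceed;
      if (exceed >= stop_count) break;  // p >= alpha already certain
    }
  }
  const double p = (1.0 + exceed) / (1.0 + used);
  return List::create(_["i"] = obs.i, _["j"] = obs.j, _["t"] = obs.t,
                      _["p"] = p, _["n_perm_used"] = used);
}
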