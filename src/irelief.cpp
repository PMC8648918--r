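#include <Rcpp.h>
using namespace Rcpp;

// Iterated Relief feature weighting.
//
// At each iteration, pairwise distances are the weighted L1 metric under
// the current weight vector. Each sample's nearest-hit / nearest-miss
// assignment is soft: neighbours get kernel weights exp(-d / sigma),
// normalised within the same-class (hit) and opposite-class (miss) sets.
// The per-feature expected margin (miss minus hit absolute differences)
// is averaged over samples; its positive part, renormalised to the
// simplex, is the next weight vector. Iterate to a fixed point.
//
// [[Rcpp::export]]
List irelief_cpp(NumericMatrix X, IntegerVector y, double sigma,
                 int max_iter, double tol) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 1.0 / p), v(p), wnew(p);
  std::vector<double> d(n), kern(n), margin(p);
  bool converged = false, degenerate = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(v.begin(), v.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      // weighted L1 distances from i to everyone
      double dmin_hit = R_PosInf, dmin_miss = R_PosInf;
      for (int j = 0; j < n; ++j) {
        if (j == i) { d[j] = R_PosInf; continue; }
        double s = 0.0;
        for (int f = 0; f < p; ++f) s += w[f] * std::fabs(X(i, f) - X(j, f));
        d[j] = s;
        if (y[j] == y[i]) { if (s < dmin_hit) dmin_hit = s; }
        else              { if (s < dmin_miss) dmin_miss = s; }
      }
      // kernel weights, stabilised by subtracting the per-set minimum
      double sum_hit = 0.0, sum_miss = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) { kern[j] = 0.0; continue; }
        double ref = (y[j] == y[i]) ? dmin_hit : dmin_miss;
        kern[j] = std::exp(-(d[j] - ref) / sigma);
        if (y[j] == y[i]) sum_hit += kern[j]; else sum_miss += kern[j];
      }
      if (sum_hit <= 0.0 || sum_miss <= 0.0) continue;
      std::fill(margin.begin(), margin.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double a = (y[j] == y[i]) ? -kern[j] / sum_hit : kern[j] / sum_miss;
        for (int f = 0; f < p; ++f)
          margin[f] += a * std::fabs(X(i, f) - X(j, f));
      }
      for (int f = 0; f < p; ++f) v[f] += margin[f] / n;
    }
    double pos_sum = 0.0;
    for (int f = 0; f < p; ++f) {
      wnew[f] = v[f] > 0.0 ? v[f] : 0.0;
      pos_sum += wnew[f];
    }
    if (pos_sum <= 0.0) {
      std::fill(wnew.begin(), wnew.end(), 1.0 / p);
      degenerate = true;
    } else {
      for (int f = 0; f < p; ++f) wnew[f] /= pos_sum;
    }
    double delta = 0.0;
    for (int f = 0; f < p; ++f) {
      double e = wnew[f] - w[f];
      delta += e * e;
    }
    w = wnew;
    if (std::sqrt(delta) < tol) { converged = true; break; }
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged,
                      _["degenerate"] = degenerate);
}
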