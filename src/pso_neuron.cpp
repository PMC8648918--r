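#include <Rcpp.h>
using namespace Rcpp;

// Particle swarm fit of one GMDH neuron.
//
// A neuron's score is logistic(B %*% coef) where B is the basis-expansion
// matrix of its two inputs. During fitting the hard label at the fixed
// 0.5 threshold is simply sign(B %*% coef), so the MCC fitness is
// evaluated on the linear predictor directly. Canonical PSO update:
//   vel <- w*vel + c1*r1*(pbest - x) + c2*r2*(gbest - x)
// with positions clipped to [lo, hi]. Deterministic given `seed`
// (self-contained xorshift64* generator; the R session RNG is untouched).

static inline double xorshift_unif(uint64_t &s) {
  s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
  uint64_t x = s * 2685821657736338717ULL;
  return (x >> 11) * (1.0 / 9007199254740992.0);  // 53-bit mantissa in [0,1)
}

static double mcc_from_linpred(const std::vector<double> &eta,
                               const IntegerVector &y) {
  double tp = 0, fp = 0, tn = 0, fn = 0;
  const int n = eta.size();
  for (int i = 0; i < n; ++i) {
    bool pos = eta[i] >= 0.0;
    if (y[i] == 1) { if (pos) tp++; else fn++; }
    else           { if (pos) fp++; else tn++; }
  }
  double den = (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn);
  if (den == 0.0) return 0.0;
  return (tp * tn - fp * fn) / std::sqrt(den);
}

// [[Rcpp::export]]
List pso_fit_neuron_cpp(NumericMatrix B, IntegerVector y,
                        int swarm, int iters, double inertia,
                        double c1, double c2, double lo, double hi,
                        int seed) {
  const int n = B.nrow(), d = B.ncol();
  uint64_t rng = 0x9E3779B97F4A7C15ULL ^ (uint64_t)(uint32_t)seed;
  for (int k = 0; k < 8; ++k) xorshift_unif(rng);  // warm up

  std::vector<std::vector<double>> x(swarm, std::vector<double>(d));
  std::vector<std::vector<double>> vel(swarm, std::vector<double>(d, 0.0));
  std::vector<std::vector<double>> pbest(swarm, std::vector<double>(d));
  std::vector<double> pbest_fit(swarm, -2.0);
  std::vector<double> pbest_norm(swarm, R_PosInf);
  std::vector<double> gbest(d, 0.0);
  double gbest_fit = -2.0, gbest_norm = R_PosInf;
  std::vector<double> eta(n);

  for (int s = 0; s < swarm; ++s)
    for (int k = 0; k < d; ++k)
      x[s][k] = lo + (hi - lo) * xorshift_unif(rng);

  for (int it = 0; it <= iters; ++it) {
    for (int s = 0; s < swarm; ++s) {
      if (it > 0) {
        for (int k = 0; k < d; ++k) {
          double r1 = xorshift_unif(rng), r2 = xorshift_unif(rng);
          vel[s][k] = inertia * vel[s][k]
            + c1 * r1 * (pbest[s][k] - x[s][k])
            + c2 * r2 * (gbest[k] - x[s][k]);
          x[s][k] += vel[s][k];
          if (x[s][k] < lo) x[s][k] = lo;
          if (x[s][k] > hi) x[s][k] = hi;
        }
      }
      std::fill(eta.begin(), eta.end(), 0.0);
      for (int k = 0; k < d; ++k) {          // column-major accumulation
        const double xk = x[s][k];
        const double *col = &B(0, k);
        for (int i = 0; i < n; ++i) eta[i] += col[i] * xk;
      }
      double fit = mcc_from_linpred(eta, y);
      // MCC is a ratio of integer counts, so plateaus are common; among
      // equal-MCC solutions prefer the smallest-norm coefficients (the
      // least saturated neuron), which keeps scores spread out.
      double nrm = 0.0;
      for (int k = 0; k < d; ++k) nrm += x[s][k] * x[s][k];
      if (fit > pbest_fit[s] ||
          (fit == pbest_fit[s] && nrm < pbest_norm[s])) {
        pbest_fit[s] = fit; pbest_norm[s] = nrm; pbest[s] = x[s];
      }
      if (fit > gbest_fit || (fit == gbest_fit && nrm < gbest_norm)) {
        gbest_fit = fit; gbest_norm = nrm; gbest = x[s];
      }
    }
  }
  return List::create(_["coefficients"] = NumericVector(gbest.begin(), gbest.end()),
                      _["fitness"] = gbest_fit);
}
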