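#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic xorshift RNG so layouts are exactly reproducible from the
// seed, independent of R's RNG state.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double clip4(double v) {
  if (v > 4.0) return 4.0;
  if (v < -4.0) return -4.0;
  return v;
}

// Stochastic gradient optimisation of the fuzzy cross-entropy layout
// objective: edges are sampled proportionally to their membership weight
// (epochs-per-sample scheme), each positive sample applies an attractive
// update to both endpoints and `neg_rate` repulsive updates against
// uniformly random nodes. Per-component gradients are clipped to [-4, 4]
// and the learning rate decays linearly to zero.
// [[Rcpp::export(name = ".layout_sgd")]]
NumericMatrix layout_sgd(NumericMatrix init, IntegerVector head,
                         IntegerVector tail, NumericVector weight,
                         int n_epochs, double a, double b, double alpha0,
                         int neg_rate, double seed) {
  const int n = init.nrow();
  const int m = head.size();
  NumericMatrix y = clone(init);

  double wmax = 0.0;
  for (int e = 0; e < m; ++e) wmax = std::max(wmax, weight[e]);
  if (wmax <= 0.0) return y;

  std::vector<double> eps(m), next_sample(m);
  for (int e = 0; e < m; ++e) {
    eps[e] = wmax / weight[e];  // epochs between samples of this edge
    next_sample[e] = eps[e];
  }

  uint64_t rng = (uint64_t)(seed) * 2654435761u + 104729u;
  if (rng == 0) rng = 88172645463325252ull;

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double alpha = alpha0 * (1.0 - (epoch - 1.0) / n_epochs);
    for (int e = 0; e < m; ++e) {
      if (next_sample[e] > epoch) continue;
      const int i = head[e] - 1;
      const int j = tail[e] - 1;
      double dx = y(i, 0) - y(j, 0);
      double dy = y(i, 1) - y(j, 1);
      double r2 = dx * dx + dy * dy;
      if (r2 > 0.0) {
        const double grad = (-2.0 * a * b * std::pow(r2, b - 1.0)) /
                            (1.0 + a * std::pow(r2, b));
        const double gx = clip4(grad * dx), gy = clip4(grad * dy);
        y(i, 0) += alpha * gx;
        y(i, 1) += alpha * gy;
        y(j, 0) -= alpha * gx;
        y(j, 1) -= alpha * gy;
      }
      for (int p = 0; p < neg_rate; ++p) {
        const int k = (int)(xorshift64(rng) % (uint64_t)n);
        if (k == i) continue;
        dx = y(i, 0) - y(k, 0);
        dy = y(i, 1) - y(k, 1);
        r2 = dx * dx + dy * dy;
        const double grad =
            (2.0 * b) / ((0.001 + r2) * (1.0 + a * std::pow(r2, b)));
        y(i, 0) += alpha * clip4(grad * dx);
        y(i, 1) += alpha * clip4(grad * dy);
      }
      next_sample[e] += eps[e];
    }
  }
  return y;
}
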