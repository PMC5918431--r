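#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Self-contained deterministic RNG (splitmix64) so training does not depend
// on, or disturb, R's RNG stream.  Quality is ample for noise sampling.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double uniform() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Walker alias table for O(1) sampling from a discrete distribution.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  explicit AliasTable(const NumericVector& p) {
    int n = p.size();
    prob.resize(n);
    alias.resize(n);
    std::vector<double> scaled(n);
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += p[i];
    for (int i = 0; i < n; ++i) scaled[i] = p[i] * n / total;
    std::vector<int> small, large;
    for (int i = 0; i < n; ++i) {
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }
  int draw(SplitMix64& rng) const {
    int i = (int)(rng.uniform() * prob.size());
    if (i >= (int)prob.size()) i = prob.size() - 1;
    return rng.uniform() < prob[i] ? i : alias[i];
  }
};

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// SGD over (center, context) pairs, `epochs` passes in the given order,
// `k_neg` negatives per pair drawn from `noise` with the positive context
// excluded by rejection.  Linear learning-rate decay across all updates.
// Parameters are repacked entity-major (one contiguous block per entity)
// so the hot loops stream over cache lines instead of striding a
// column-major matrix.
// [[Rcpp::export]]
List sgns_train_cpp(NumericMatrix U_in, NumericMatrix V_in,
                    IntegerVector centers, IntegerVector contexts,
                    int epochs, double lr_initial, double lr_final,
                    int k_neg, NumericVector noise, int seed) {
  const int n_pairs = centers.size();
  const int n = U_in.nrow();
  const int d = U_in.ncol();
  const long long total = (long long)epochs * n_pairs;
  AliasTable alias(noise);
  SplitMix64 rng(0x9E3779B97F4A7C15ULL ^ (uint64_t)(uint32_t)seed);

  std::vector<double> U((size_t)n * d), V((size_t)n * d), grad_u(d);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < d; ++c) {
      U[(size_t)r * d + c] = U_in(r, c);
      V[(size_t)r * d + c] = V_in(r, c);
    }

  long long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int t = 0; t < n_pairs; ++t, ++step) {
      double lr = lr_initial;
      if (total > 1) {
        lr = lr_initial + (lr_final - lr_initial) * ((double)step / (double)(total - 1));
      }
      double* u = &U[(size_t)centers[t] * d];
      const int j = contexts[t];
      std::fill(grad_u.begin(), grad_u.end(), 0.0);

      // positive update
      double* vj = &V[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += u[c] * vj[c];
      double g = sigmoid(s) - 1.0;
      for (int c = 0; c < d; ++c) {
        grad_u[c] += g * vj[c];
        vj[c] -= lr * g * u[c];
      }

      // negatives: i.i.d. draws from the noise distribution, rejecting the
      // positive context (bounded retries guard a degenerate distribution)
      for (int neg = 0; neg < k_neg; ++neg) {
        int l = alias.draw(rng);
        for (int tries = 0; l == j && tries < 1000; ++tries) l = alias.draw(rng);
        if (l == j) continue;
        double* vl = &V[(size_t)l * d];
        double sn = 0.0;
        for (int c = 0; c < d; ++c) sn += u[c] * vl[c];
        double gn = sigmoid(sn);
        for (int c = 0; c < d; ++c) {
          grad_u[c] += gn * vl[c];
          vl[c] -= lr * gn * u[c];
        }
      }
      for (int c = 0; c < d; ++c) u[c] -= lr * grad_u[c];
    }
  }

  NumericMatrix U_out(n, d), V_out(n, d);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < d; ++c) {
      U_out(r, c) = U[(size_t)r * d + c];
      V_out(r, c) = V[(size_t)r * d + c];
    }
  return List::create(_["U"] = U_out, _["V"] = V_out);
}
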