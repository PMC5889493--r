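// Single-threaded skip-gram with negative sampling (word2vec SGNS).
// Uses its own splitmix64 RNG so training is bit-reproducible for a given
// seed regardless of R's RNG state. Sentences arrive as 0-based token-id
// vectors; out-of-vocabulary tokens are pre-filtered on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size,
                         NumericVector noise_cumprob, int dim, int window,
                         int negative, int epochs, double alpha0,
                         double alpha_min, int seed) {
  SplitMix64 rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // total center-word visits, for linear learning-rate decay
  long long total = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total += Rf_length(sentences[s]);
  total *= epochs;
  if (total == 0) return NumericMatrix(vocab_size, dim);

  const double *cum = noise_cumprob.begin();
  int V = vocab_size;
  std::vector<double> grad(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      int n = sent.size();
      for (int i = 0; i < n; ++i, ++processed) {
        double alpha = alpha0 * (1.0 - (double)processed / (double)total);
        if (alpha < alpha_min) alpha = alpha_min;
        int center = sent[i];
        int span = 1 + rng.unif_int(window); // dynamic window, word2vec style
        int lo = i - span < 0 ? 0 : i - span;
        int hi = i + span >= n ? n - 1 : i + span;
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int ctx = sent[j];
          double *v_in = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = ctx;
              label = 1.0;
            } else {
              double u = rng.unif();
              target = (int)(std::lower_bound(cum, cum + V, u) - cum);
              if (target >= V) target = V - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
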