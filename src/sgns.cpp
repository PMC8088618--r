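// Skip-gram with negative sampling over random-walk corpora.
// Single-threaded, own xorshift RNG -> bit-reproducible for a given seed.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(unif() * n); }
};

inline double sigmoid_clip(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sgns_train(List walks, int n_nodes, int dim, int window,
                         int negative, int epochs, double alpha_init,
                         IntegerVector neg_table, int seed) {
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::vector<double> syn0(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.size());
  long long total_tokens = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    corpus.emplace_back(w.begin(), w.end());
    total_tokens += w.size();
  }
  const long long total_steps = total_tokens * std::max(1, epochs);
  long long done = 0;
  const int tbl = neg_table.size();
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t wk = 0; wk < corpus.size(); ++wk) {
      const std::vector<int>& walk = corpus[wk];
      const int len = static_cast<int>(walk.size());
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha_init *
          (1.0 - static_cast<double>(done) / (total_steps + 1));
        if (alpha < alpha_init * 1e-4) alpha = alpha_init * 1e-4;
        ++done;
        const int center = walk[pos];
        const int win = 1 + rng.below(window);  // sampled window size
        for (int off = -win; off <= win; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          const int context = walk[cpos];
          double* v = &syn0[static_cast<size_t>(context) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = center;
              label = 1.0;
            } else {
              target = neg_table[rng.below(tbl)];
              if (target == center) continue;
              label = 0.0;
            }
            double* u = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v[d] * u[d];
            const double g = (label - sigmoid_clip(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * u[d];
              u[d] += g * v[d];
            }
          }
          for (int d = 0; d < dim; ++d) v[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = syn0[static_cast<size_t>(i) * dim + d];
  return out;
}
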