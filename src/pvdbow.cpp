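// Distributed bag-of-words paragraph vectors (PV-DBOW) with negative
// sampling.  Single-threaded, deterministic for a fixed seed.  Each document
// vector is trained to predict the (sub-sampled) tokens of its document via
// a shared output layer, exactly the skip-gram negative-sampling update with
// the document vector playing the role of the context vector.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xorshift128+ style splitmix for reproducible, platform-stable streams
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = "pvdbow_train")]]
NumericMatrix pvdbow_train(List docs, NumericVector counts, int m,
                           int epochs, double alpha, double sample,
                           int negative, int seed) {
  const int ndocs = docs.size();
  const int vocab = counts.size();
  if (ndocs == 0) stop("empty corpus");
  if (m < 1) stop("embedding dimension must be >= 1");

  std::vector<std::vector<int>> dv(ndocs);
  double total = 0.0;
  for (int d = 0; d < ndocs; ++d) {
    IntegerVector w = docs[d];
    dv[d].assign(w.begin(), w.end());
    for (int id : dv[d])
      if (id < 0 || id >= vocab) stop("token id out of range");
    total += w.size();
  }
  double totalCount = 0.0;
  for (int w = 0; w < vocab; ++w) totalCount += counts[w];

  // keep-probability per word under frequency downsampling (word2vec rule)
  std::vector<double> keepProb(vocab, 1.0);
  if (sample > 0) {
    const double thresh = sample * totalCount;
    for (int w = 0; w < vocab; ++w) {
      double p = (std::sqrt(counts[w] / thresh) + 1.0) * thresh / counts[w];
      keepProb[w] = p < 1.0 ? p : 1.0;
    }
  }

  // unigram^0.75 negative-sampling table (word2vec style)
  double acc = 0.0;
  for (int w = 0; w < vocab; ++w) acc += std::pow(counts[w], 0.75);
  const int tableSize = 1 << 20;
  std::vector<int> negTable(tableSize);
  {
    int w = 0;
    double cum = std::pow(counts[0], 0.75);
    for (int i = 0; i < tableSize; ++i) {
      double want = (i + 0.5) / tableSize * acc;
      while (cum < want && w < vocab - 1) cum += std::pow(counts[++w], 0.75);
      negTable[i] = w;
    }
  }

  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> docVec(static_cast<size_t>(ndocs) * m);
  for (auto& x : docVec) x = (rng.unif() - 0.5) / m;
  std::vector<double> out(static_cast<size_t>(vocab) * m, 0.0);
  std::vector<double> grad(m);

  const double minAlpha = 1e-4;
  const double span = static_cast<double>(epochs) * (total > 0 ? total : 1);
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < ndocs; ++d) {
      double* dvp = &docVec[static_cast<size_t>(d) * m];
      for (int target : dv[d]) {
        double lr = alpha * (1.0 - processed / span);
        if (lr < minAlpha) lr = minAlpha;
        processed += 1.0;
        if (keepProb[target] < 1.0 && rng.unif() > keepProb[target])
          continue;
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int n = 0; n <= negative; ++n) {
          int w;
          double label;
          if (n == 0) {
            w = target;
            label = 1.0;
          } else {
            w = negTable[rng.next() & (tableSize - 1)];
            if (w == target) continue;
            label = 0.0;
          }
          double* op = &out[static_cast<size_t>(w) * m];
          double f = 0.0;
          for (int j = 0; j < m; ++j) f += dvp[j] * op[j];
          double g = (label - sigmoid(f)) * lr;
          for (int j = 0; j < m; ++j) grad[j] += g * op[j];
          for (int j = 0; j < m; ++j) op[j] += g * dvp[j];
        }
        for (int j = 0; j < m; ++j) dvp[j] += grad[j];
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix res(ndocs, m);
  for (int d = 0; d < ndocs; ++d)
    for (int j = 0; j < m; ++j)
      res(d, j) = docVec[static_cast<size_t>(d) * m + j];
  return res;
}
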