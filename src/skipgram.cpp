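// Skip-gram with negative sampling over per-patient chronological token
// sequences, used to initialize the event-embedding table.  Single-threaded
// SGD, deterministic under a fixed seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

// [[Rcpp::export(name = ".sg_train_cpp")]]
arma::mat sg_train_cpp(List seqs, arma::mat Win, arma::mat Wout,
                       int window, int negatives, int epochs, double lr,
                       int seed) {
  const int V = Win.n_rows, d = Win.n_cols;
  std::vector<std::vector<int>> corpus;
  corpus.reserve(seqs.size());
  std::vector<double> cnt(V, 0.0);
  for (int s = 0; s < seqs.size(); ++s) {
    Rcpp::IntegerVector v = seqs[s];
    std::vector<int> sq(v.begin(), v.end());
    for (int id : sq) {
      if (id < 0 || id >= V) Rcpp::stop("token id out of range");
      cnt[id] += 1.0;
    }
    corpus.push_back(std::move(sq));
  }
  // unigram^0.75 negative-sampling table (EMPTY, id 0, has count 0 and is
  // therefore never drawn)
  std::vector<double> cdf(V);
  double tot = 0;
  for (int i = 0; i < V; ++i) { tot += std::pow(cnt[i], 0.75); cdf[i] = tot; }
  if (tot <= 0) Rcpp::stop("empty corpus");
  for (int i = 0; i < V; ++i) cdf[i] /= tot;

  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  auto draw_neg = [&]() {
    double u = unif(rng);
    return (int)(std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
  };

  vec vold(d);
  for (int epoch = 0; epoch < epochs; ++epoch) {
    for (const auto& sq : corpus) {
      const int T = sq.size();
      for (int i = 0; i < T; ++i) {
        int b = 1 + (int)(unif(rng) * window);  // reduced window
        if (b > window) b = window;
        for (int j = std::max(0, i - b); j <= std::min(T - 1, i + b); ++j) {
          if (j == i) continue;
          const int w = sq[i];
          // positive pair + negatives share the same center row
          double* vw = Win.memptr() + w;          // row w, column stride V
          for (int k = 0; k <= negatives; ++k) {
            int c; double label;
            if (k == 0) { c = sq[j]; label = 1.0; }
            else {
              c = draw_neg();
              if (c == sq[j]) continue;
              label = 0.0;
            }
            double* uc = Wout.memptr() + c;
            double dotp = 0;
            for (int t = 0; t < d; ++t) dotp += vw[(size_t)t * V] * uc[(size_t)t * V];
            double g = lr * (label - 1.0 / (1.0 + std::exp(-dotp)));
            for (int t = 0; t < d; ++t) {
              double vv = vw[(size_t)t * V];
              vw[(size_t)t * V] += g * uc[(size_t)t * V];
              uc[(size_t)t * V] += g * vv;
            }
          }
        }
      }
    }
  }
  return Win;
}
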