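// Collapsed Gibbs sampling for latent Dirichlet allocation on token
// streams, plus fold-in inference for new documents against frozen
// topic-gene distributions. Randomness goes through R's RNG so results
// are governed by set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// Sample an index proportional to the (unnormalized) weights in p[0..K).
static inline int sample_prop(const std::vector<double>& p, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t k = 0; k < p.size(); ++k) {
    acc += p[k];
    if (u <= acc) return (int)k;
  }
  return (int)p.size() - 1;
}

// doc, word: 0-based token vectors (one entry per token).
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word, int n_docs,
                   int vocab, int K, double alpha, double eta,
                   int iterations) {
  const int N = doc.size();
  std::vector<int> z(N);
  std::vector<int> ndk(n_docs * K, 0), nkw(K * vocab, 0), nk(K, 0),
      nd(n_docs, 0);
  RNGScope scope;

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk[doc[i] * K + k]++;
    nkw[k * vocab + word[i]]++;
    nk[k]++;
    nd[doc[i]]++;
  }

  std::vector<double> p(K);
  NumericVector loglik(iterations);
  const double Veta = vocab * eta;

  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      ndk[d * K + k]--;
      nkw[k * vocab + w]--;
      nk[k]--;
      double total = 0.0;
      for (int s = 0; s < K; ++s) {
        p[s] = (ndk[d * K + s] + alpha) * (nkw[s * vocab + w] + eta) /
               (nk[s] + Veta);
        total += p[s];
      }
      k = sample_prop(p, total);
      z[i] = k;
      ndk[d * K + k]++;
      nkw[k * vocab + w]++;
      nk[k]++;
    }
    // token log-likelihood under the current point estimates; cheap
    // convergence monitor for the collapsed chain
    double ll = 0.0;
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      double pw = 0.0;
      for (int s = 0; s < K; ++s) {
        pw += (ndk[d * K + s] + alpha) / (nd[d] + K * alpha) *
              (nkw[s * vocab + w] + eta) / (nk[s] + Veta);
      }
      ll += std::log(pw);
    }
    loglik[it] = ll;
  }

  NumericMatrix phi(K, vocab), theta(n_docs, K);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < vocab; ++w)
      phi(k, w) = (nkw[k * vocab + w] + eta) / (nk[k] + Veta);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk[d * K + k] + alpha) / (nd[d] + K * alpha);

  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["loglik"] = loglik);
}

// Fold-in: infer document-topic weights for new documents with the
// topic-gene matrix frozen. phi is K x vocab (rows sum to 1 over the
// shared vocabulary).
// [[Rcpp::export]]
NumericMatrix lda_fold_in_cpp(IntegerVector doc, IntegerVector word,
                              int n_docs, NumericMatrix phi, double alpha,
                              int iterations) {
  const int N = doc.size();
  const int K = phi.nrow();
  std::vector<int> z(N);
  std::vector<int> ndk(n_docs * K, 0), nd(n_docs, 0);
  RNGScope scope;

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk[doc[i] * K + k]++;
    nd[doc[i]]++;
  }
  std::vector<double> p(K);
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      ndk[d * K + k]--;
      double total = 0.0;
      for (int s = 0; s < K; ++s) {
        p[s] = (ndk[d * K + s] + alpha) * phi(s, w);
        total += p[s];
      }
      k = sample_prop(p, total);
      z[i] = k;
      ndk[d * K + k]++;
    }
  }
  NumericMatrix theta(n_docs, K);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk[d * K + k] + alpha) / (nd[d] + K * alpha);
  return theta;
}
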