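#include <Rcpp.h>
using namespace Rcpp;

// Zero-order collapsed variational Bayes for Labeled LDA.
//
// Each token i carries a variational distribution gamma_i over the K topics,
// with support restricted to the labels of its document (non-allowed entries
// are exactly zero and are never touched). The update for token i in doc d
// with word w is
//
//   gamma_i(k) <- (N_wk^{-i} + beta) / (N_k^{-i} + V beta) * (N_dk^{-i} + alpha)
//
// normalised over the allowed labels, where the counts N are sums of gamma
// over all other tokens (the zero-order approximation drops the variance
// corrections of full CVB).
//
// gamma: n_tokens x K matrix (rows already restricted + normalised);
// doc_id, word_id: 0-based per token; allowed: list of 0-based label
// index vectors per doc. Updates gamma in place order-sequentially, so the
// result is deterministic given the initial gamma.
// [[Rcpp::export]]
List cvb0_train(NumericMatrix gamma_, IntegerVector doc_id, IntegerVector word_id,
                List allowed, int n_docs, int n_words, int n_topics,
                double alpha, double beta, int n_iter) {
  const int n_tok = gamma_.nrow();
  const int K = n_topics;
  NumericMatrix Nwk(n_words, K);
  NumericVector Nk(K);
  NumericMatrix Ndk(n_docs, K);

  for (int i = 0; i < n_tok; ++i) {
    const int w = word_id[i], d = doc_id[i];
    for (int k = 0; k < K; ++k) {
      const double g = gamma_(i, k);
      Nwk(w, k) += g;
      Nk[k] += g;
      Ndk(d, k) += g;
    }
  }

  std::vector<std::vector<int>> allow(n_docs);
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector a = allowed[d];
    allow[d] = std::vector<int>(a.begin(), a.end());
  }

  const double Vbeta = n_words * beta;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < n_tok; ++i) {
      const int w = word_id[i], d = doc_id[i];
      const std::vector<int> &a = allow[d];
      if (a.size() == 1) continue;  // point mass, nothing to update
      double norm = 0.0;
      std::vector<double> fresh(a.size());
      for (size_t j = 0; j < a.size(); ++j) {
        const int k = a[j];
        const double g = gamma_(i, k);
        const double v = (Nwk(w, k) - g + beta) / (Nk[k] - g + Vbeta) *
                         (Ndk(d, k) - g + alpha);
        fresh[j] = v;
        norm += v;
      }
      for (size_t j = 0; j < a.size(); ++j) {
        const int k = a[j];
        const double g_new = fresh[j] / norm;
        const double delta = g_new - gamma_(i, k);
        gamma_(i, k) = g_new;
        Nwk(w, k) += delta;
        Nk[k] += delta;
        Ndk(d, k) += delta;
      }
    }
  }

  return List::create(_["gamma"] = gamma_, _["Nwk"] = Nwk, _["Nk"] = Nk,
                      _["Ndk"] = Ndk);
}
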