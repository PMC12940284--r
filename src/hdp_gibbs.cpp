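#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for a weak-limit (truncated) hierarchical
// Dirichlet process mixture over category counts. Each sample is a
// "restaurant" whose pseudo-count tokens choose among K shared components;
// a small per-component concentration (alpha / K) approximates the DP's
// rich-get-richer behaviour so unused components empty out and the
// effective number of components is inferred.
//
// counts: n_samples x n_cat integer matrix of pseudo-counts.
// Returns presence counts per component (sweeps, post burn-in, in which the
// component held more than presence_threshold of all tokens), and the
// component-category and sample-component count matrices accumulated over
// the sweeps where the component was present.
// [[Rcpp::export]]
List hdp_gibbs_cpp(IntegerMatrix counts, int k_max, double alpha, double eta,
                   int n_iter, int burn_in, double presence_threshold) {
  const int n = counts.nrow();
  const int C = counts.ncol();

  // expand tokens
  std::vector<int> tok_j, tok_c;
  for (int j = 0; j < n; ++j)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < counts(j, c); ++t) {
        tok_j.push_back(j);
        tok_c.push_back(c);
      }
  const int T = (int) tok_j.size();
  if (T == 0) stop("no pseudo-count tokens; count_scale too small");

  std::vector<int> z(T);
  std::vector< std::vector<int> > njk(n, std::vector<int>(k_max, 0));
  std::vector< std::vector<int> > mkc(k_max, std::vector<int>(C, 0));
  std::vector<int> mk(k_max, 0);

  RNGScope scope;
  for (int t = 0; t < T; ++t) {
    int k = (int) (unif_rand() * k_max);
    if (k >= k_max) k = k_max - 1;
    z[t] = k;
    njk[tok_j[t]][k]++;
    mkc[k][tok_c[t]]++;
    mk[k]++;
  }

  const double a0 = alpha / k_max;
  const double etaC = eta * C;
  std::vector<double> p(k_max);

  IntegerVector presence(k_max, 0);
  NumericMatrix sum_topic(k_max, C);
  NumericMatrix sum_doc(n, k_max);
  int n_post = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int t = 0; t < T; ++t) {
      const int j = tok_j[t], c = tok_c[t], kold = z[t];
      njk[j][kold]--; mkc[kold][c]--; mk[kold]--;
      double tot = 0.0;
      for (int k = 0; k < k_max; ++k) {
        p[k] = (njk[j][k] + a0) * (mkc[k][c] + eta) / (mk[k] + etaC);
        tot += p[k];
      }
      double u = unif_rand() * tot;
      int knew = 0;
      double acc = p[0];
      while (u > acc && knew < k_max - 1) acc += p[++knew];
      z[t] = knew;
      njk[j][knew]++; mkc[knew][c]++; mk[knew]++;
    }
    if (it >= burn_in) {
      n_post++;
      for (int k = 0; k < k_max; ++k) {
        if ((double) mk[k] / T > presence_threshold) {
          presence[k]++;
          for (int c = 0; c < C; ++c) sum_topic(k, c) += mkc[k][c];
          for (int j = 0; j < n; ++j) sum_doc(j, k) += njk[j][k];
        }
      }
    }
  }

  return List::create(_["presence"] = presence,
                      _["n_post"] = n_post,
                      _["sum_topic"] = sum_topic,
                      _["sum_doc"] = sum_doc,
                      _["n_tokens"] = T);
}
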