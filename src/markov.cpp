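#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov sampler over {A,C,G,T}.
// trans: 4x4 row-stochastic transition matrix (rows/cols in A,C,G,T order);
// init: length-4 start distribution.  Draws come from R's RNG, so set.seed()
// on the R side makes output deterministic.
// [[Rcpp::export]]
std::string markov_chain_seq(int n, NumericMatrix trans, NumericVector init) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  if (n <= 0) return std::string();
  double cinit[4];
  double c = 0.0;
  for (int j = 0; j < 4; ++j) { c += init[j]; cinit[j] = c; }
  cinit[3] = 1.0;
  double ctr[4][4];
  for (int i = 0; i < 4; ++i) {
    double s = 0.0;
    for (int j = 0; j < 4; ++j) { s += trans(i, j); ctr[i][j] = s; }
    ctr[i][3] = 1.0;
  }
  std::string out((size_t) n, 'A');
  double u = unif_rand();
  int state = 3;
  for (int j = 0; j < 4; ++j) if (u <= cinit[j]) { state = j; break; }
  out[0] = bases[state];
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int nxt = 3;
    for (int j = 0; j < 4; ++j) if (u <= ctr[state][j]) { nxt = j; break; }
    state = nxt;
    out[(size_t) i] = bases[state];
  }
  return out;
}
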