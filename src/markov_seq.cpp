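#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov chain sampler over {A,C,G,T}.
// init: length-4 start probabilities; trans: 4x4 row-stochastic matrix,
// rows = current base, columns = next base, base order A,C,G,T.
// Uses R's RNG stream, so set.seed() upstream makes output reproducible.
// [[Rcpp::export]]
std::string markov_sequence_cpp(const int n, const NumericVector init,
                                const NumericMatrix trans) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  if (n < 1) stop("n must be positive");
  if (init.size() != 4 || trans.nrow() != 4 || trans.ncol() != 4)
    stop("init must have length 4 and trans must be 4x4");

  // cumulative rows for inverse-CDF draws
  double cinit[4];
  double ctrans[4][4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) { acc += init[j]; cinit[j] = acc; }
  for (int i = 0; i < 4; ++i) {
    acc = 0.0;
    for (int j = 0; j < 4; ++j) { acc += trans(i, j); ctrans[i][j] = acc; }
  }

  std::string out(n, 'A');
  RNGScope scope;
  double u = unif_rand();
  int state = 3;
  for (int j = 0; j < 4; ++j) if (u <= cinit[j]) { state = j; break; }
  out[0] = bases[state];
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int next = 3;
    for (int j = 0; j < 4; ++j) if (u <= ctrans[state][j]) { next = j; break; }
    out[i] = bases[next];
    state = next;
  }
  return out;
}
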