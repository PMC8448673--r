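#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete Markov chain over states 0..(K-1) given a row-stochastic
// transition matrix. Uses R's RNG so set.seed() gives reproducible paths.
// Returns n_steps states, the first being `init`.
// [[Rcpp::export]]
IntegerVector sim_markov_chain(NumericMatrix trans, int init, int n_steps) {
  const int K = trans.nrow();
  if (trans.ncol() != K) stop("transition matrix must be square");
  if (init < 0 || init >= K) stop("initial state out of range");
  if (n_steps < 1) stop("n_steps must be >= 1");

  // precompute cumulative rows
  NumericMatrix cum(K, K);
  for (int i = 0; i < K; ++i) {
    double acc = 0.0;
    for (int j = 0; j < K; ++j) {
      acc += trans(i, j);
      cum(i, j) = acc;
    }
    if (acc < 1.0 - 1e-9 || acc > 1.0 + 1e-9)
      stop("row %d of transition matrix does not sum to 1", i + 1);
    cum(i, K - 1) = 1.0;  // guard against round-off
  }

  IntegerVector out(n_steps);
  int state = init;
  out[0] = state;
  for (int t = 1; t < n_steps; ++t) {
    double u = unif_rand();
    int j = 0;
    while (cum(state, j) < u) ++j;
    state = j;
    out[t] = state;
  }
  return out;
}
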