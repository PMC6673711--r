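#include <Rcpp.h>
using namespace Rcpp;

// Viterbi decoding for a Gaussian-emission HMM with a symmetric transition
// structure: probability `stay` of remaining in the current state and equal
// probability of moving to any other state. With K states the per-window
// update is O(K) because the best move-source is the overall best previous
// state (or the runner-up when that coincides with the target state).
// Ties are broken toward the lower-indexed (smaller copy number) state:
// argmax scans states in ascending order with strict improvement, and a
// self-transition is preferred over an equally likely jump.
//
// [[Rcpp::export]]
IntegerVector viterbi_gaussian(NumericVector x, NumericVector means,
                               NumericVector vars, double log_stay,
                               double log_move) {
  const int T = x.size(), K = means.size();
  IntegerVector path(T);
  if (T == 0) return path;

  std::vector<double> logc(K), inv2v(K);
  for (int k = 0; k < K; ++k) {
    logc[k] = -0.5 * std::log(2.0 * M_PI * vars[k]);
    inv2v[k] = 0.5 / vars[k];
  }

  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) {
    const double d = x[0] - means[k];
    delta(0, k) = logc[k] - d * d * inv2v[k];  // uniform initial distribution
  }

  for (int t = 1; t < T; ++t) {
    // best and second-best previous states (ascending scan: ties -> lower)
    int b1 = 0, b2 = -1;
    for (int j = 1; j < K; ++j) {
      if (delta(t - 1, j) > delta(t - 1, b1)) { b2 = b1; b1 = j; }
      else if (b2 < 0 || delta(t - 1, j) > delta(t - 1, b2)) { b2 = j; }
    }
    for (int k = 0; k < K; ++k) {
      const int mj = (b1 == k) ? b2 : b1;
      const double stay = delta(t - 1, k) + log_stay;
      const double move = (mj >= 0) ? delta(t - 1, mj) + log_move : R_NegInf;
      const double d = x[t] - means[k];
      const double emit = logc[k] - d * d * inv2v[k];
      if (stay >= move) { delta(t, k) = stay + emit; psi(t, k) = k; }
      else              { delta(t, k) = move + emit; psi(t, k) = mj; }
    }
  }

  int best = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > delta(T - 1, best)) best = k;
  path[T - 1] = best;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  return path;
}
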