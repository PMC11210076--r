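#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming ridge extraction.
//
// logamp: time x freq matrix of log coefficient magnitudes.
// penalty: cost of a one-grid-step frequency move per sample, applied
//          quadratically in the number of steps.
// kmax:    largest allowed per-sample move in grid steps.
//
// Maximizes sum_t logamp(t, j_t) - penalty * (j_t - j_{t-1})^2 and
// returns 1-based frequency indices along the optimal path.
// [[Rcpp::export]]
IntegerVector ridge_dp(NumericMatrix logamp, double penalty, int kmax) {
  const int T = logamp.nrow();
  const int F = logamp.ncol();
  if (T < 1 || F < 1) stop("empty amplitude matrix");
  if (kmax < 1) kmax = 1;

  std::vector<double> prev(F), cur(F);
  IntegerMatrix back(T, F);
  for (int j = 0; j < F; ++j) prev[j] = logamp(0, j);

  std::vector<double> stepcost(kmax + 1);
  for (int k = 0; k <= kmax; ++k) stepcost[k] = penalty * double(k) * double(k);

  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < F; ++j) {
      double best = R_NegInf;
      int arg = j;
      int lo = j - kmax < 0 ? 0 : j - kmax;
      int hi = j + kmax >= F ? F - 1 : j + kmax;
      for (int i = lo; i <= hi; ++i) {
        double c = prev[i] - stepcost[std::abs(i - j)];
        if (c > best) { best = c; arg = i; }
      }
      cur[j] = best + logamp(t, j);
      back(t, j) = arg;
    }
    std::swap(prev, cur);
  }

  IntegerVector path(T);
  int j = 0;
  double best = prev[0];
  for (int i = 1; i < F; ++i) if (prev[i] > best) { best = prev[i]; j = i; }
  path[T - 1] = j + 1;
  for (int t = T - 1; t > 0; --t) {
    j = back(t, j);
    path[t - 1] = j + 1;
  }
  return path;
}
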