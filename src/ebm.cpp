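#include <Rcpp.h>
using namespace Rcpp;

// Dataset log-likelihood of an event ordering.
//
// logPE / logPNotE are Z x N (biomarkers x subjects) matrices of
// log densities under the abnormal / normal component. `order` is a
// 1-based permutation of 1..Z, position 1 = earliest event. The stage
// prior is uniform over the Z+1 stages. Everything stays in log space
// with a log-sum-exp over stages per subject; the literal per-stage
// product would underflow at realistic cohort sizes.
// [[Rcpp::export]]
double cppSeqLogLik(const NumericMatrix& logPE,
                    const NumericMatrix& logPNotE,
                    const IntegerVector& order) {
  const int Z = logPE.nrow();
  const int N = logPE.ncol();
  if (logPNotE.nrow() != Z || logPNotE.ncol() != N)
    stop("likelihood matrices must have identical dimensions");
  if (order.size() != Z)
    stop("order length must equal the number of biomarkers");

  std::vector<double> stage(Z + 1);
  const double logPrior = -std::log((double)(Z + 1));
  double total = 0.0;

  for (int j = 0; j < N; ++j) {
    // stage[k] = sum_{i<=k} logPE + sum_{i>k} logPNotE along the order
    double s = 0.0;
    for (int i = 0; i < Z; ++i) s += logPNotE(order[i] - 1, j);
    stage[0] = s;
    for (int k = 1; k <= Z; ++k) {
      const int b = order[k - 1] - 1;
      s += logPE(b, j) - logPNotE(b, j);
      stage[k] = s;
    }
    double m = stage[0];
    for (int k = 1; k <= Z; ++k) if (stage[k] > m) m = stage[k];
    double acc = 0.0;
    for (int k = 0; k <= Z; ++k) acc += std::exp(stage[k] - m);
    total += logPrior + m + std::log(acc);
  }
  return total;
}

// Per-subject stage log-likelihoods (Eq. 2 analogue), K = Z+1 columns for
// stages 0..Z, rows are subjects. Includes the uniform stage prior term.
// [[Rcpp::export]]
NumericMatrix cppStageLogLik(const NumericMatrix& logPE,
                             const NumericMatrix& logPNotE,
                             const IntegerVector& order) {
  const int Z = logPE.nrow();
  const int N = logPE.ncol();
  if (order.size() != Z)
    stop("order length must equal the number of biomarkers");
  NumericMatrix out(N, Z + 1);
  const double logPrior = -std::log((double)(Z + 1));
  for (int j = 0; j < N; ++j) {
    double s = 0.0;
    for (int i = 0; i < Z; ++i) s += logPNotE(order[i] - 1, j);
    out(j, 0) = s + logPrior;
    for (int k = 1; k <= Z; ++k) {
      const int b = order[k - 1] - 1;
      s += logPE(b, j) - logPNotE(b, j);
      out(j, k) = s + logPrior;
    }
  }
  return out;
}
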