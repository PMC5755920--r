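#include <Rcpp.h>
using namespace Rcpp;

// L2-regularized L1-loss (hinge) linear SVM trained by dual coordinate
// descent, with a per-sample upper bound C_i implementing class weights.
// Primal: min_w 1/2 ||w||^2 + sum_i C_i max(0, 1 - y_i w.x_i)
// A bias term, when wanted, is supplied by the caller as an augmented
// constant feature column. Samples are visited in a permutation drawn from
// a private xorshift generator so training is reproducible from `seed`
// regardless of R's RNG state.
// [[Rcpp::export]]
List dcd_svm(const NumericMatrix& X, const NumericVector& y,
             const NumericVector& cost, int max_iter = 1000,
             double eps = 1e-3, int seed = 1) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t state = (uint64_t)seed * 2654435761u + 1442695040888963407ull;
  auto next_u = [&state]() {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    return state;
  };
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(next_u() % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double max_pg = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      if (qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= cost[i]) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / qii[i], 0.0), cost[i]);
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
      }
    }
    if (max_pg < eps) { ++iter; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter);
}
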