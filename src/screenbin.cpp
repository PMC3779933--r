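// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Generate a DNA sequence from a k-th order Markov model.
// cumw: (4^order) x 4 matrix of row-wise cumulative transition probabilities,
// contexts ordered lexicographically (A=0, C=1, G=2, T=3; first base most
// significant). Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
std::string markov_chain_seq(const NumericMatrix& cumw, int order, int len) {
  static const char bases[] = {'A', 'C', 'G', 'T'};
  const int ncontext = cumw.nrow();
  std::string out(len, 'A');
  int ctx = 0;
  const int init = std::min(order, len);
  for (int i = 0; i < init; ++i) {
    int b = static_cast<int>(::unif_rand() * 4.0);
    if (b > 3) b = 3;
    out[i] = bases[b];
    ctx = (ctx * 4 + b) % ncontext;
  }
  for (int i = init; i < len; ++i) {
    const double u = ::unif_rand();
    int b = 0;
    while (b < 3 && u > cumw(ctx, b)) ++b;
    out[i] = bases[b];
    if (order > 0) ctx = (ctx * 4 + b) % ncontext;
  }
  return out;
}

// Online training of a toroidal self-organizing map.
//
// X: data matrix (n x d). Codebook is initialized uniformly within the
// per-feature data range from R's RNG. Per epoch the sample order is
// reshuffled (Fisher-Yates, R RNG); per sample the best-matching unit is the
// Euclidean argmin over all neurons (ties -> lowest row-major index) and all
// neurons within the current radius (toroidal grid Euclidean distance) are
// pulled toward the sample with a Gaussian neighborhood kernel. Radius and
// learning rate decay linearly over epochs.
// Neuron index is row-major: idx = row * grid_cols + col (0-based).
// [[Rcpp::export]]
List esom_train_cpp(const arma::mat& X, int grid_rows, int grid_cols,
                    int epochs, double radius_start, double radius_end,
                    double lr_start, double lr_end) {
  const int n = X.n_rows;
  const int d = X.n_cols;
  const int m = grid_rows * grid_cols;

  arma::rowvec lo = arma::min(X, 0);
  arma::rowvec hi = arma::max(X, 0);
  arma::mat W(m, d);
  for (int j = 0; j < d; ++j) {
    const double span = hi[j] - lo[j];
    for (int i = 0; i < m; ++i) W(i, j) = lo[j] + ::unif_rand() * span;
  }

  arma::vec nrm = arma::sum(arma::square(W), 1);
  NumericVector log_radius(epochs), log_lr(epochs);
  std::vector<int> ord(n);

  for (int e = 0; e < epochs; ++e) {
    const double f = (epochs > 1) ? static_cast<double>(e) / (epochs - 1) : 0.0;
    const double radius = radius_start + f * (radius_end - radius_start);
    const double lr = lr_start + f * (lr_end - lr_start);
    log_radius[e] = radius;
    log_lr[e] = lr;

    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }

    const int R = static_cast<int>(std::ceil(radius));
    const double r2max = radius * radius;
    const double sigma2 = 2.0 * radius * radius;

    for (int s = 0; s < n; ++s) {
      const arma::rowvec x = X.row(ord[s]);
      const arma::vec score = nrm - 2.0 * (W * x.t());
      const arma::uword bmu = score.index_min();
      const int br = static_cast<int>(bmu) / grid_cols;
      const int bc = static_cast<int>(bmu) % grid_cols;
      for (int dr = -R; dr <= R; ++dr) {
        for (int dc = -R; dc <= R; ++dc) {
          const double g2 = static_cast<double>(dr * dr + dc * dc);
          if (g2 > r2max) continue;
          int rr = (br + dr) % grid_rows;
          if (rr < 0) rr += grid_rows;
          int cc = (bc + dc) % grid_cols;
          if (cc < 0) cc += grid_cols;
          const int idx = rr * grid_cols + cc;
          const double h = (sigma2 > 0.0) ? lr * std::exp(-g2 / sigma2) : lr;
          W.row(idx) += h * (x - W.row(idx));
          nrm[idx] = arma::dot(W.row(idx), W.row(idx));
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["codebook"] = W,
                      _["radius"] = log_radius,
                      _["learning_rate"] = log_lr);
}
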