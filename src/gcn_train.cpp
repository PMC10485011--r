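// Full-batch Adam training loop for the graph-convolutional network.
// Mirrors the reference R implementation (see train_gcn_r) operation for
// operation: forward L[k+1] = relu(P L[k] W[k]) with a softmax head, masked
// mean binary cross-entropy plus (l2/2) * sum(W^2), Adam with the standard
// (0.9, 0.999, 1e-8) constants. The propagation matrix is sparse because
// thresholded patient-similarity graphs usually are; the layer-1 product
// P X is hoisted out of the epoch loop since X never changes.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export]]
Rcpp::List gcn_train_cpp(const arma::sp_mat& P, const arma::mat& X,
                         Rcpp::List W_init, const arma::vec& y,
                         const arma::uvec& mask_idx, int epochs, double lr,
                         double l2) {
  const int K = W_init.size();
  std::vector<arma::mat> W(K), M(K), V(K), Z(K), H(K);
  for (int k = 0; k < K; ++k) {
    W[k] = Rcpp::as<arma::mat>(W_init[k]);
    M[k].zeros(arma::size(W[k]));
    V[k].zeros(arma::size(W[k]));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8, clip = 1e-12;
  const int n = X.n_rows;
  const int nlab = mask_idx.n_elem;
  const arma::mat PX = P * X;
  arma::vec trace(epochs > 0 ? epochs : 1, arma::fill::zeros);

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    for (int k = 0; k < K; ++k) {
      Z[k] = (k == 0) ? arma::mat(PX * W[0])
                      : arma::mat(P * (H[k - 1] * W[k]));
      if (k < K - 1)
        H[k] = arma::clamp(Z[k], 0.0, arma::datum::inf);
    }
    // masked loss and softmax residuals on the 2-column head
    double bce = 0.0;
    arma::mat dZ(n, 2, arma::fill::zeros);
    for (int j = 0; j < nlab; ++j) {
      const arma::uword i = mask_idx[j];
      const double z0 = Z[K - 1](i, 0), z1 = Z[K - 1](i, 1);
      const double mx = std::max(z0, z1);
      const double e0 = std::exp(z0 - mx), e1 = std::exp(z1 - mx);
      const double p1 = e1 / (e0 + e1);
      const double pc = std::min(std::max(p1, clip), 1.0 - clip);
      bce -= y[i] * std::log(pc) + (1.0 - y[i]) * std::log(1.0 - pc);
      const double resid = (p1 - y[i]) / nlab;
      dZ(i, 0) = -resid;
      dZ(i, 1) = resid;
    }
    double pen = 0.0;
    for (int k = 0; k < K; ++k) pen += arma::accu(arma::square(W[k]));
    trace[epoch - 1] = bce / nlab + 0.5 * l2 * pen;
    if (!std::isfinite(trace[epoch - 1]))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch);

    for (int k = K - 1; k >= 0; --k) {
      arma::mat grad;
      if (k == 0) {
        grad = PX.t() * dZ + l2 * W[0];
      } else {
        const arma::mat dM = P * dZ;
        grad = H[k - 1].t() * dM + l2 * W[k];
        // residual for the previous layer, using the pre-update weights
        dZ = (dM * W[k].t()) % (Z[k - 1] > 0);
      }
      M[k] = b1 * M[k] + (1.0 - b1) * grad;
      V[k] = b2 * V[k] + (1.0 - b2) * arma::square(grad);
      W[k] -= lr * (M[k] / (1.0 - std::pow(b1, epoch))) /
              (arma::sqrt(V[k] / (1.0 - std::pow(b2, epoch))) + eps);
    }
  }

  Rcpp::List W_out(K);
  for (int k = 0; k < K; ++k) W_out[k] = W[k];
  return Rcpp::List::create(
      Rcpp::_["weights"] = W_out,
      Rcpp::_["trace"] = (epochs > 0)
          ? Rcpp::NumericVector(trace.begin(), trace.end())
          : Rcpp::NumericVector(0));
}
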