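// Compiled kernels: minibatch SGD training of the no-bias 4-layer MLP,
// its forward pass, and the random mutant scan sampler. All randomness is
// driven by integer seeds drawn from R's RNG on the calling side, so whole
// runs are reproducible under set.seed().
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Train a fully connected tanh/tanh/linear network with no bias terms by
// minibatch stochastic gradient descent with momentum on squared error.
// X: N x d design matrix, y: standardized targets. Weights are updated in
// place (copies of the R matrices) and returned.
// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                   arma::mat W1, arma::mat W2, arma::mat W3,
                   int epochs, double lr, double momentum,
                   int batch_size, int seed) {
  const arma::uword N = X.n_rows;
  arma::mat V1(arma::size(W1), arma::fill::zeros);
  arma::mat V2(arma::size(W2), arma::fill::zeros);
  arma::mat V3(arma::size(W3), arma::fill::zeros);

  std::mt19937 gen(static_cast<unsigned>(seed));
  std::vector<arma::uword> ord(N);
  for (arma::uword i = 0; i < N; ++i) ord[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(ord.begin(), ord.end(), gen);
    for (arma::uword start = 0; start < N; start += batch_size) {
      arma::uword stop = std::min<arma::uword>(start + batch_size, N);
      arma::uvec rows(stop - start);
      for (arma::uword i = start; i < stop; ++i) rows[i - start] = ord[i];
      const arma::mat Xb = X.rows(rows);
      const arma::vec yb = y.elem(rows);
      const double B = static_cast<double>(rows.n_elem);

      arma::mat A1 = arma::tanh(Xb * W1);
      arma::mat A2 = arma::tanh(A1 * W2);
      arma::vec yhat = A2 * W3;

      // d(MSE)/d(yhat)
      arma::vec d3 = (2.0 / B) * (yhat - yb);
      arma::mat G3 = A2.t() * d3;
      arma::mat d2 = (d3 * W3.t()) % (1.0 - arma::square(A2));
      arma::mat G2 = A1.t() * d2;
      arma::mat d1 = (d2 * W2.t()) % (1.0 - arma::square(A1));
      arma::mat G1 = Xb.t() * d1;

      V1 = momentum * V1 - lr * G1;  W1 += V1;
      V2 = momentum * V2 - lr * G2;  W2 += V2;
      V3 = momentum * V3 - lr * G3;  W3 += V3;
    }
  }
  return List::create(Named("W1") = W1, Named("W2") = W2, Named("W3") = W3);
}

// Forward pass; returns standardized-score predictions.
// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const arma::mat& X, const arma::mat& W1,
                          const arma::mat& W2, const arma::mat& W3) {
  return arma::tanh(arma::tanh(X * W1) * W2) * W3;
}

// Training-set mean squared error (used for loss monitoring).
// [[Rcpp::export]]
double mlp_mse_cpp(const arma::mat& X, const arma::vec& y,
                   const arma::mat& W1, const arma::mat& W2,
                   const arma::mat& W3) {
  arma::vec r = mlp_predict_cpp(X, W1, W2, W3) - y;
  return arma::dot(r, r) / r.n_elem;
}

// Random mutant scan: each of `count` mutants draws a seed row uniformly
// from seed_idx (1-based residue indices), a mutation count k uniform on
// 1..n, k distinct positions, and for each a uniformly drawn residue that
// differs from the current one.
// [[Rcpp::export]]
IntegerMatrix scan_mutants_cpp(const IntegerMatrix& seed_idx, int count,
                               int n_letters, int seed) {
  const int n = seed_idx.ncol();
  const int E = seed_idx.nrow();
  std::mt19937 gen(static_cast<unsigned>(seed));
  std::uniform_int_distribution<int> pick_seed(0, E - 1);
  std::uniform_int_distribution<int> pick_k(1, n);
  std::uniform_int_distribution<int> pick_sub(1, n_letters - 1);

  IntegerMatrix out(count, n);
  std::vector<int> pos(n);
  for (int c = 0; c < count; ++c) {
    int srow = pick_seed(gen);
    for (int j = 0; j < n; ++j) {
      out(c, j) = seed_idx(srow, j);
      pos[j] = j;
    }
    int k = pick_k(gen);
    // partial Fisher-Yates draw of k distinct positions
    for (int t = 0; t < k; ++t) {
      std::uniform_int_distribution<int> pick_pos(t, n - 1);
      std::swap(pos[t], pos[pick_pos(gen)]);
      int p = pos[t];
      int d = pick_sub(gen);          // 1..19
      int cur = out(c, p);            // 1..20
      out(c, p) = (d >= cur) ? d + 1 : d;
    }
  }
  return out;
}
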