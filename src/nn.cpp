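// Single-hidden-layer feed-forward classifier: full-batch gradient descent
// with momentum on multinomial cross-entropy plus an L2 weight penalty.
// All randomness (weight initialization, data splits) lives in R; given the
// initial weights these routines are fully deterministic, which is what
// makes the repeated cross-validation and ensemble votes reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat forward_hidden(const mat& X, const mat& W1) {
  // X: n x p (already standardized); W1: (p+1) x h, row 0 is the bias.
  mat A = X * W1.rows(1, W1.n_rows - 1);
  A.each_row() += W1.row(0);
  return 1.0 / (1.0 + exp(-A));  // logistic activation
}

static mat forward_output(const mat& H, const mat& W2) {
  mat Z = H * W2.rows(1, W2.n_rows - 1);
  Z.each_row() += W2.row(0);
  // softmax, row-wise, numerically stabilized
  Z.each_col() -= max(Z, 1);
  mat E = exp(Z);
  E.each_col() /= sum(E, 1);
  return E;
}

static void train_core(const mat& X, const mat& Y, mat& W1, mat& W2,
                       double decay, double lr, double momentum,
                       int epochs) {
  const double n = static_cast<double>(X.n_rows);
  mat V1(size(W1), fill::zeros), V2(size(W2), fill::zeros);
  mat H, P, Dout, Dhid, G1(size(W1)), G2(size(W2));

  for (int e = 0; e < epochs; ++e) {
    H = forward_hidden(X, W1);
    P = forward_output(H, W2);

    Dout = (P - Y) / n;                        // n x k
    G2.row(0) = sum(Dout, 0);
    G2.rows(1, G2.n_rows - 1) = H.t() * Dout;

    Dhid = (Dout * W2.rows(1, W2.n_rows - 1).t()) % H % (1.0 - H);
    G1.row(0) = sum(Dhid, 0);
    G1.rows(1, G1.n_rows - 1) = X.t() * Dhid;

    // L2 penalty on connection weights; biases (row 0) are exempt, so the
    // heavy-regularization limit predicts the class frequencies.
    G1.rows(1, G1.n_rows - 1) += 2.0 * decay * W1.rows(1, W1.n_rows - 1);
    G2.rows(1, G2.n_rows - 1) += 2.0 * decay * W2.rows(1, W2.n_rows - 1);

    V1 = momentum * V1 - lr * G1;
    V2 = momentum * V2 - lr * G2;
    W1 += V1;
    W2 += V2;
  }
}

// [[Rcpp::export]]
Rcpp::List nn_fit_cpp(const arma::mat& X, const arma::mat& Y,
                      arma::mat W1, arma::mat W2,
                      double decay, double lr, double momentum,
                      int epochs) {
  train_core(X, Y, W1, W2, decay, lr, momentum, epochs);
  const double n = static_cast<double>(X.n_rows);
  mat P = forward_output(forward_hidden(X, W1), W2);
  double ce = -accu(Y % log(P + 1e-12)) / n +
    decay * (accu(square(W1)) + accu(square(W2)));
  return Rcpp::List::create(Rcpp::Named("W1") = W1,
                            Rcpp::Named("W2") = W2,
                            Rcpp::Named("loss") = ce);
}

// [[Rcpp::export]]
arma::mat nn_predict_cpp(const arma::mat& X, const arma::mat& W1,
                         const arma::mat& W2) {
  return forward_output(forward_hidden(X, W1), W2);
}

// Repeated train/predict over pre-drawn splits: one network per iteration,
// trained on X rows learn(i, .) (standardized by that learner set, sd 0 ->
// scale 1), evaluated on rows test(i, .). Returns the 0-based predicted
// class index per (iteration, test sample). Indices are 0-based; initial
// weights come in cubes with one slice per iteration.
// [[Rcpp::export]]
arma::umat nn_batch_cpp(const arma::mat& X, const arma::uvec& y, int k,
                        const arma::umat& learn, const arma::umat& test,
                        const arma::cube& W1init, const arma::cube& W2init,
                        double decay, double lr, double momentum,
                        int epochs) {
  const uword n_iter = learn.n_rows, n_learn = learn.n_cols,
              n_test = test.n_cols;
  umat pred(n_iter, n_test);
  mat W1, W2;

  for (uword i = 0; i < n_iter; ++i) {
    uvec li = learn.row(i).t();
    mat XL = X.rows(li);
    rowvec center = mean(XL, 0);
    rowvec scale = stddev(XL, 0, 0);  // N-1 denominator, as in R's sd()
    scale.elem(find(scale == 0.0)).ones();
    XL.each_row() -= center;
    XL.each_row() /= scale;

    mat Y(n_learn, static_cast<uword>(k), fill::zeros);
    for (uword j = 0; j < n_learn; ++j) Y(j, y(li(j))) = 1.0;

    W1 = W1init.slice(i);
    W2 = W2init.slice(i);
    train_core(XL, Y, W1, W2, decay, lr, momentum, epochs);

    mat XT = X.rows(test.row(i).t());
    XT.each_row() -= center;
    XT.each_row() /= scale;
    mat P = forward_output(forward_hidden(XT, W1), W2);
    pred.row(i) = index_max(P, 1).t();
  }
  return pred;
}
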