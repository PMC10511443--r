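// Multilayer-perceptron regressor: two ReLU hidden layers with inverted
// dropout, a linear output unit, MSE loss, Adam updates, and early stopping
// on validation loss. Self-contained so training is deterministic given the
// seed (weight init, minibatch shuffling and dropout masks all draw from one
// std::mt19937 stream).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat he_init(int rows, int cols, std::mt19937 &rng) {
  std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / rows));
  mat w(rows, cols);
  for (uword j = 0; j < w.n_cols; ++j)
    for (uword i = 0; i < w.n_rows; ++i) w(i, j) = nd(rng);
  return w;
}

struct Adam {
  mat m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  Adam(int r, int c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat &w, const mat &g, double lr, double bc1, double bc2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
  }
};

static double val_mse(const mat &X, const vec &y, const mat &W1, const rowvec &b1,
                      const mat &W2, const rowvec &b2, const mat &W3,
                      double b3) {
  mat h1 = clamp(X * W1 + repmat(b1, X.n_rows, 1), 0.0, datum::inf);
  mat h2 = clamp(h1 * W2 + repmat(b2, X.n_rows, 1), 0.0, datum::inf);
  vec p = h2 * W3 + b3;
  return mean(square(p - y));
}

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat &X, const arma::vec &y,
                         const arma::mat &Xval, const arma::vec &yval,
                         int h1n, int h2n, double dropout, double lr,
                         int maxEpochs, int batch, int patience,
                         unsigned int seed) {
  std::mt19937 rng(seed);
  const int n = X.n_rows, d = X.n_cols;
  mat W1 = he_init(d, h1n, rng);
  rowvec b1(h1n, fill::zeros);
  mat W2 = he_init(h1n, h2n, rng);
  rowvec b2(h2n, fill::zeros);
  mat W3 = he_init(h2n, 1, rng);
  double b3 = mean(y);

  Adam aW1(d, h1n), aW2(h1n, h2n), aW3(h2n, 1);
  Adam ab1(1, h1n), ab2(1, h2n), ab3(1, 1);
  mat b3m(1, 1, fill::zeros);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double bestVal = datum::inf;
  int bestEpoch = 0, sinceBest = 0;
  mat bW1 = W1, bW2 = W2, bW3 = W3;
  rowvec bb1 = b1, bb2 = b2;
  double bb3 = b3;
  std::vector<double> trainHist, valHist;

  long tstep = 0;
  for (int epoch = 1; epoch <= maxEpochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epochLoss = 0.0;
    int nb = 0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(s + batch, n);
      int m = e - s;
      uvec rows(m);
      for (int i = 0; i < m; ++i) rows[i] = idx[s + i];
      mat Xb = X.rows(rows);
      vec yb = y.elem(rows);

      mat z1 = Xb * W1 + repmat(b1, m, 1);
      mat a1 = clamp(z1, 0.0, datum::inf);
      mat m1(m, h1n);
      if (dropout > 0) {
        for (uword j = 0; j < m1.n_cols; ++j)
          for (uword i = 0; i < m1.n_rows; ++i)
            m1(i, j) = unif(rng) >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
        a1 %= m1;
      }
      mat z2 = a1 * W2 + repmat(b2, m, 1);
      mat a2 = clamp(z2, 0.0, datum::inf);
      mat m2(m, h2n);
      if (dropout > 0) {
        for (uword j = 0; j < m2.n_cols; ++j)
          for (uword i = 0; i < m2.n_rows; ++i)
            m2(i, j) = unif(rng) >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
        a2 %= m2;
      }
      vec pred = a2 * W3 + b3;
      vec err = pred - yb;
      epochLoss += mean(square(err));
      ++nb;

      vec dOut = 2.0 * err / m;                  // d(MSE)/d(pred)
      mat gW3 = a2.t() * dOut;
      double gb3 = accu(dOut);
      mat dA2 = dOut * W3.t();
      if (dropout > 0) dA2 %= m2;
      dA2 %= conv_to<mat>::from(z2 > 0);
      mat gW2 = a1.t() * dA2;
      rowvec gb2 = sum(dA2, 0);
      mat dA1 = dA2 * W2.t();
      if (dropout > 0) dA1 %= m1;
      dA1 %= conv_to<mat>::from(z1 > 0);
      mat gW1 = Xb.t() * dA1;
      rowvec gb1 = sum(dA1, 0);

      ++tstep;
      double bc1 = 1 - std::pow(0.9, (double)tstep);
      double bc2 = 1 - std::pow(0.999, (double)tstep);
      aW1.step(W1, gW1, lr, bc1, bc2);
      aW2.step(W2, gW2, lr, bc1, bc2);
      aW3.step(W3, gW3, lr, bc1, bc2);
      mat gb1m = conv_to<mat>::from(gb1), gb2m = conv_to<mat>::from(gb2);
      mat b1m = conv_to<mat>::from(b1), b2m = conv_to<mat>::from(b2);
      ab1.step(b1m, gb1m, lr, bc1, bc2);
      ab2.step(b2m, gb2m, lr, bc1, bc2);
      b1 = conv_to<rowvec>::from(b1m);
      b2 = conv_to<rowvec>::from(b2m);
      mat gb3m(1, 1); gb3m(0, 0) = gb3;
      b3m(0, 0) = b3;
      ab3.step(b3m, gb3m, lr, bc1, bc2);
      b3 = b3m(0, 0);
    }
    double vloss = val_mse(Xval, yval, W1, b1, W2, b2, W3, b3);
    trainHist.push_back(epochLoss / nb);
    valHist.push_back(vloss);
    if (vloss < bestVal - 1e-12) {
      bestVal = vloss;
      bestEpoch = epoch;
      sinceBest = 0;
      bW1 = W1; bW2 = W2; bW3 = W3; bb1 = b1; bb2 = b2; bb3 = b3;
    } else if (++sinceBest >= patience) {
      break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = bW1, Rcpp::Named("b1") = bb1,
      Rcpp::Named("W2") = bW2, Rcpp::Named("b2") = bb2,
      Rcpp::Named("W3") = bW3, Rcpp::Named("b3") = bb3,
      Rcpp::Named("trainLoss") = trainHist, Rcpp::Named("valLoss") = valHist,
      Rcpp::Named("bestEpoch") = bestEpoch,
      Rcpp::Named("bestValLoss") = bestVal);
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const arma::mat &X, const arma::mat &W1,
                          const arma::rowvec &b1, const arma::mat &W2,
                          const arma::rowvec &b2, const arma::mat &W3,
                          double b3) {
  mat h1 = clamp(X * W1 + repmat(b1, X.n_rows, 1), 0.0, datum::inf);
  mat h2 = clamp(h1 * W2 + repmat(b2, X.n_rows, 1), 0.0, datum::inf);
  return h2 * W3 + b3;
}
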