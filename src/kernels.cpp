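// Hot per-batch kernels of the 1-D CNN. Batches are R arrays of
// dimension (batch, length, channels), which map directly onto
// arma::cube (rows = batch, cols = positions, slices = channels).
// The im2col column layout is tap-fastest within channel
// (column index j + c*k, 0-based), matching the natural flattening of
// the (kernel, channels, filters) weight array on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static mat im2col(const cube& x, int k, int s, int O) {
  const int B = x.n_rows, C = x.n_slices;
  mat cols(B * O, k * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      for (int o = 0; o < O; ++o)
        cols.col(j + c * k).subvec(o * B, o * B + B - 1) =
          x.slice(c).col(o * s + j);
  return cols;
}

// [[Rcpp::export]]
List cpp_conv1d_forward(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int k, int s, bool want_cache) {
  const int B = x.n_rows, L = x.n_cols;
  const int O = (L - k) / s + 1;
  const int F = W.n_cols;
  mat cols = im2col(x, k, s, O);
  mat y = cols * W;
  y.each_row() += b.t();
  cube out(y.memptr(), B, O, F);  // (B*O) x F column-major == (B, O, F)
  if (want_cache)
    return List::create(_["out"] = out, _["cols"] = cols);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
List cpp_conv1d_backward(const arma::cube& dy, const arma::mat& cols,
                         const arma::mat& W, int L, int C, int k, int s) {
  const int B = dy.n_rows, O = dy.n_cols, F = dy.n_slices;
  mat dymat(B * O, F);
  for (int f = 0; f < F; ++f)
    dymat.col(f) = arma::vectorise(dy.slice(f));
  mat dW = cols.t() * dymat;
  vec db = arma::sum(dymat, 0).t();
  mat dcols = dymat * W.t();
  cube dx(B, L, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      for (int o = 0; o < O; ++o)
        dx.slice(c).col(o * s + j) +=
          dcols.col(j + c * k).subvec(o * B, o * B + B - 1);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Max pooling with argmax kept for the backward scatter; ties resolve to
// the earliest window position (deterministic).
// [[Rcpp::export]]
List cpp_maxpool_forward(const arma::cube& x, int l, int r) {
  const int B = x.n_rows, O = x.n_cols, C = x.n_slices;
  const int P = (O - l) / r + 1;
  cube out(B, P, C);
  arma::icube arg(B, P, C);
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < P; ++p)
      for (int b = 0; b < B; ++b) {
        double best = x(b, p * r, c);
        int bj = 0;
        for (int j = 1; j < l; ++j) {
          const double v = x(b, p * r + j, c);
          if (v > best) { best = v; bj = j; }
        }
        out(b, p, c) = best;
        arg(b, p, c) = bj;
      }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& dy, const arma::icube& arg,
                                int O, int r) {
  const int B = dy.n_rows, P = dy.n_cols, C = dy.n_slices;
  cube dx(B, O, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < P; ++p)
      for (int b = 0; b < B; ++b)
        dx(b, p * r + arg(b, p, c), c) += dy(b, p, c);
  return dx;
}

// Group normalization: per-sample statistics over each contiguous block
// of (channels/groups) channels x all positions; biased variance.
// [[Rcpp::export]]
List cpp_groupnorm_forward(const arma::cube& x, const arma::vec& gamma,
                           const arma::vec& beta, int groups, double eps) {
  const int B = x.n_rows, O = x.n_cols, C = x.n_slices;
  const int m = C / groups;
  const double N = static_cast<double>(O) * m;
  cube xhat(B, O, C);
  cube y(B, O, C);
  mat inv_sd(B, groups);
  for (int g = 0; g < groups; ++g) {
    const int c0 = g * m;
    vec sum(B, arma::fill::zeros), sum2(B, arma::fill::zeros);
    for (int c = c0; c < c0 + m; ++c) {
      const mat& s = x.slice(c);
      sum += arma::sum(s, 1);
      sum2 += arma::sum(s % s, 1);
    }
    const vec mu = sum / N;
    const vec isd = 1.0 / arma::sqrt(sum2 / N - mu % mu + eps);
    inv_sd.col(g) = isd;
    for (int c = c0; c < c0 + m; ++c) {
      mat xh = x.slice(c);
      xh.each_col() -= mu;
      xh.each_col() %= isd;
      xhat.slice(c) = xh;
      y.slice(c) = gamma(c) * xh + beta(c);
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List cpp_groupnorm_backward(const arma::cube& dy, const arma::cube& xhat,
                            const arma::mat& inv_sd, const arma::vec& gamma,
                            int groups) {
  const int B = dy.n_rows, O = dy.n_cols, C = dy.n_slices;
  const int m = C / groups;
  const double N = static_cast<double>(O) * m;
  vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    dgamma(c) = arma::accu(dy.slice(c) % xhat.slice(c));
    dbeta(c) = arma::accu(dy.slice(c));
  }
  cube dx(B, O, C);
  for (int g = 0; g < groups; ++g) {
    const int c0 = g * m;
    vec s1(B, arma::fill::zeros), s2(B, arma::fill::zeros);
    for (int c = c0; c < c0 + m; ++c) {
      const mat dxh = dy.slice(c) * gamma(c);
      s1 += arma::sum(dxh, 1);
      s2 += arma::sum(dxh % xhat.slice(c), 1);
    }
    s1 /= N;
    s2 /= N;
    const vec isd = inv_sd.col(g);
    for (int c = c0; c < c0 + m; ++c) {
      mat d = dy.slice(c) * gamma(c);
      d.each_col() -= s1;
      mat xs = xhat.slice(c);
      xs.each_col() %= s2;
      d -= xs;
      d.each_col() %= isd;
      dx.slice(c) = d;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ELU with alpha = 1; the gradient is recovered from the output
// (1 where y > 0, y + 1 where y <= 0), saving an exp in the backward pass.
// [[Rcpp::export]]
NumericVector cpp_elu(NumericVector x) {
  NumericVector y = clone(x);
  for (double& v : y)
    if (v < 0) v = std::exp(v) - 1.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_elu_grad_from_out(NumericVector y) {
  NumericVector g = clone(y);
  for (double& v : g)
    v = (v > 0) ? 1.0 : v + 1.0;
  return g;
}
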