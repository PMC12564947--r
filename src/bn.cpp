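// Fused per-channel batch-normalization kernels. x is viewed as an
// (H*W*N) x C column-major matrix; one column per channel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".bn_fw_train_cpp")]]
List bn_fw_train_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                     int n, int C, double eps) {
  NumericVector y(x.size()), xhat(x.size());
  NumericVector mu(C), var(C), inv(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + static_cast<size_t>(n) * c;
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / n;
    const double v = s2 / n - m * m;
    const double iv = 1.0 / std::sqrt(v + eps);
    mu[c] = m; var[c] = v; inv[c] = iv;
    const double g = gamma[c], b = beta[c];
    double* xh = xhat.begin() + static_cast<size_t>(n) * c;
    double* yc = y.begin() + static_cast<size_t>(n) * c;
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * iv;
      xh[i] = h;
      yc[i] = h * g + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["inv"] = inv);
}

// [[Rcpp::export(name = ".bn_bw_cpp")]]
List bn_bw_cpp(NumericVector dy, NumericVector xhat, NumericVector gamma,
               NumericVector inv, int n, int C) {
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.begin() + static_cast<size_t>(n) * c;
    const double* xh = xhat.begin() + static_cast<size_t>(n) * c;
    const double g = gamma[c], iv = inv[c];
    double s1 = 0, s2 = 0, db = 0, dg = 0;
    for (int i = 0; i < n; ++i) {
      const double dh = dyc[i] * g;
      s1 += dh;
      s2 += dh * xh[i];
      db += dyc[i];
      dg += dyc[i] * xh[i];
    }
    dgamma[c] = dg; dbeta[c] = db;
    const double m1 = s1 / n, m2 = s2 / n;
    double* dxc = dx.begin() + static_cast<size_t>(n) * c;
    for (int i = 0; i < n; ++i) {
      dxc[i] = (dyc[i] * g - m1 - xh[i] * m2) * iv;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// y[, c] = (x[, c] - m[c]) * s[c] + b[c]  (inference-mode normalization)
// [[Rcpp::export(name = ".bn_fw_eval_cpp")]]
NumericVector bn_fw_eval_cpp(NumericVector x, NumericVector m,
                             NumericVector s, NumericVector b, int n, int C) {
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + static_cast<size_t>(n) * c;
    double* yc = y.begin() + static_cast<size_t>(n) * c;
    const double mc = m[c], sc = s[c], bc = b[c];
    for (int i = 0; i < n; ++i) yc[i] = (xc[i] - mc) * sc + bc;
  }
  return y;
}
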