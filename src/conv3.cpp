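// 3x3 convolution (stride 1, zero pad 1) on [H, W, N, C] batch arrays.
// The patch unfolding and fold-back are the hot path of training. Work is
// done per image so the patch matrix stays cache-sized, with the matrix
// products running through BLAS via Armadillo.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Patch matrix for one image: (H*W) x (9*C); column order (kh, kw, c)
// matches reshaping w[3,3,Cin,Cout] to a (9*Cin) x Cout matrix.
// x points at the image's plane; plane stride between channels is H*W*N.
static void unfold_image(const double* x, int H, int W, int N, int C,
                         arma::mat& X) {
  X.zeros();
  const size_t cstride = static_cast<size_t>(H) * W * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        double* dst0 = X.colptr(kh + 3 * kw + 9 * c);
        const double* src0 = x + cstride * c;
        const int dh = kh - 1;
        const int h0 = std::max(0, -dh);
        const int h1 = std::min(H, H - dh);
        for (int w = 0; w < W; ++w) {
          const int ww = w + kw - 1;
          if (ww < 0 || ww >= W) continue;
          const double* src = src0 + static_cast<size_t>(ww) * H + dh;
          double* dst = dst0 + static_cast<size_t>(w) * H;
          std::copy(src + h0, src + h1, dst + h0);
        }
      }
    }
  }
}

// transpose of unfold_image: scatter-add patch-gradient columns back
static void fold_image(const arma::mat& dX, double* dx, int H, int W, int N,
                       int C) {
  const size_t cstride = static_cast<size_t>(H) * W * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const double* src0 = dX.colptr(kh + 3 * kw + 9 * c);
        double* dst0 = dx + cstride * c;
        const int dh = kh - 1;
        const int h0 = std::max(0, -dh);
        const int h1 = std::min(H, H - dh);
        for (int w = 0; w < W; ++w) {
          const int ww = w + kw - 1;
          if (ww < 0 || ww >= W) continue;
          double* dst = dst0 + static_cast<size_t>(ww) * H + dh;
          const double* src = src0 + static_cast<size_t>(w) * H;
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_forward_cpp")]]
NumericVector conv3_forward_cpp(NumericVector x, NumericVector w,
                                NumericVector b) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], N = dx[2], C = dx[3];
  const int Cout = dw[3];
  const size_t HW = static_cast<size_t>(H) * W;
  arma::mat Wm(w.begin(), 9 * C, Cout, false);
  arma::mat X(HW, 9 * C);
  NumericVector out(static_cast<R_xlen_t>(HW) * N * Cout);
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    unfold_image(x.begin() + HW * n, H, W, N, C, X);
    arma::mat Y = X * Wm;  // HW x Cout
    for (int co = 0; co < Cout; ++co) {
      const double* src = Y.colptr(co);
      double* dst = op + HW * n + HW * static_cast<size_t>(N) * co;
      const double bc = b[co];
      for (size_t i = 0; i < HW; ++i) dst[i] = src[i] + bc;
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv3_backward_cpp")]]
List conv3_backward_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = x.attr("dim");
  IntegerVector dw_ = w.attr("dim");
  const int H = dx_[0], W = dx_[1], N = dx_[2], C = dx_[3];
  const int Cout = dw_[3];
  const size_t HW = static_cast<size_t>(H) * W;
  arma::mat Wm(w.begin(), 9 * C, Cout, false);

  arma::mat X(HW, 9 * C);
  arma::mat dYi(HW, Cout);
  arma::mat dW(9 * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dxv(static_cast<R_xlen_t>(HW) * N * C);

  for (int n = 0; n < N; ++n) {
    // gather this image's dy (HW x Cout)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + HW * n + HW * static_cast<size_t>(N) * co;
      std::copy(src, src + HW, dYi.colptr(co));
    }
    unfold_image(x.begin() + HW * n, H, W, N, C, X);
    dW += X.t() * dYi;
    db += arma::sum(dYi, 0);
    arma::mat dXi = dYi * Wm.t();  // HW x 9C
    fold_image(dXi, dxv.begin() + HW * n, H, W, N, C);
  }
  dxv.attr("dim") = IntegerVector::create(H, W, N, C);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  return List::create(_["dx"] = dxv, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
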