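// Low-level convolution kernels for the multitask segmentation network.
// Tensors are R arrays with dim c(H, W, C, N), column-major, so the
// element (h, w, c, n) sits at h + H*(w + W*(c + C*n)) and one sample's
// channel planes form an (H*W x C) matrix in memory.
//
// Convolution weights are matrices of shape Cout x (Cin*K*K); the column
// index r encodes (cin, kh, kw) as r = (cin*K + kh)*K + kw.  Same-padding
// is used throughout, with pad = dil*(K-1)/2, so K must be odd.
//
// im2col uses an (H*W x Cin*K*K) layout: each tap/channel is one column,
// filled by contiguous runs over h, so building it is mostly memcpy and the
// per-sample convolution is a single GEMM writing straight into the output
// sample's (H*W x Cout) memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col_hw(const double* x, int H, int W, int Cin, int K, int dil,
                      arma::mat& col) {
  const int pad = dil * (K - 1) / 2;
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kh = 0; kh < K; ++kh) {
      const int dh = dil * kh - pad;
      const int h_lo = std::max(0, -dh), h_hi = std::min(H, H - dh);
      if (h_lo >= h_hi) continue;
      for (int kw = 0; kw < K; ++kw) {
        const int dw = dil * kw - pad;
        double* cj = col.colptr((c * K + kh) * K + kw);
        const int w_lo = std::max(0, -dw), w_hi = std::min(W, W - dw);
        for (int w = w_lo; w < w_hi; ++w) {
          std::memcpy(cj + (size_t)H * w + h_lo,
                      xc + (size_t)H * (w + dw) + h_lo + dh,
                      sizeof(double) * (h_hi - h_lo));
        }
      }
    }
  }
}

static void col2im_hw(const arma::mat& col, double* dx, int H, int W,
                      int Cin, int K, int dil) {
  const int pad = dil * (K - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kh = 0; kh < K; ++kh) {
      const int dh = dil * kh - pad;
      const int h_lo = std::max(0, -dh), h_hi = std::min(H, H - dh);
      if (h_lo >= h_hi) continue;
      for (int kw = 0; kw < K; ++kw) {
        const int dw = dil * kw - pad;
        const double* cj = col.colptr((c * K + kh) * K + kw);
        const int w_lo = std::max(0, -dw), w_hi = std::min(W, W - dw);
        for (int w = w_lo; w < w_hi; ++w) {
          const double* src = cj + (size_t)H * w + h_lo;
          double* dst = xc + (size_t)H * (w + dw) + h_lo + dh;
          for (int h = 0; h < h_hi - h_lo; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix Wm,
                             NumericVector b, int K, int dil) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  const int Cout = Wm.nrow();
  const arma::uword HW = (arma::uword)H * W;
  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wmat(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat Wt = Wmat.t();  // (Cin*K*K) x Cout
  arma::vec bv(b.begin(), Cout, false);
  arma::mat col;
  if (K != 1) col.set_size(HW, (arma::uword)Cin * K * K);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(&y[HW * Cout * n], HW, Cout, false, true);
    if (K == 1) {
      arma::mat X(const_cast<double*>(&x[HW * Cin * n]), HW, Cin, false);
      Y = X * Wt;
    } else {
      im2col_hw(&x[HW * Cin * n], H, W, Cin, K, dil, col);
      Y = col * Wt;
    }
    Y.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix Wm, NumericVector dy,
                    int K, int dil) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  const int Cout = Wm.nrow();
  const arma::uword HW = (arma::uword)H * W;
  arma::mat Wmat(Wm.begin(), Cout, Wm.ncol(), false);
  NumericVector dx(HW * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dWt(Wm.ncol(), Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat col, dcol;
  if (K != 1) {
    col.set_size(HW, (arma::uword)Cin * K * K);
    dcol.set_size(HW, (arma::uword)Cin * K * K);
  }
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(&dy[HW * Cout * n]), HW, Cout, false);
    db += arma::sum(dY, 0);
    if (K == 1) {
      arma::mat X(const_cast<double*>(&x[HW * Cin * n]), HW, Cin, false);
      arma::mat dX(&dx[HW * Cin * n], HW, Cin, false, true);
      dX = dY * Wmat;
      dWt += X.t() * dY;
    } else {
      im2col_hw(&x[HW * Cin * n], H, W, Cin, K, dil, col);
      dWt += col.t() * dY;
      dcol = dY * Wmat;
      col2im_hw(dcol, &dx[HW * Cin * n], H, W, Cin, K, dil);
    }
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(wrap(dWt.t())),
                      _["db"] = NumericVector(wrap(db.t())));
}

// 2x2 max pooling, stride 2.  Returns pooled values and the linear index
// (1-based, within the full input array) of each maximum for the backward
// pass.  Ties go to the first element in column-major scan order.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      const size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t i = base + (2 * ho + dh) + (size_t)H * (2 * wo + dw);
              if (x[i] > best) { best = x[i]; besti = i; }
            }
          y[obase + ho + (size_t)Ho * wo] = best;
          idx[obase + ho + (size_t)Ho * wo] = (int)(besti + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int C = d[2], N = d[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t M = dy.size();
  for (size_t i = 0; i < M; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// Transpose convolution, kernel 2x2, stride 2 (doubles H and W).
// Weight matrix shape: (Cout*4) x Cin with row index r = co*4 + dh*2 + dw.
// [[Rcpp::export]]
NumericVector cpp_upconv_fwd(NumericVector x, NumericMatrix Wm,
                             NumericVector b) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  const int Cout = Wm.nrow() / 4;
  const int Ho = 2 * H, Wo = 2 * W;
  const arma::uword HW = (arma::uword)H * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wmat(Wm.begin(), Wm.nrow(), Cin, false);
  arma::mat Wt = Wmat.t();  // Cin x (Cout*4)
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(&x[HW * Cin * n]), HW, Cin, false);
    arma::mat T = X * Wt;  // HW x (Cout*4)
    double* yp = &y[(size_t)Ho * Wo * Cout * n];
    for (int co = 0; co < Cout; ++co) {
      double* yc = yp + (size_t)Ho * Wo * co;
      const double bco = b[co];
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh) {
          const double* tc = T.colptr(co * 4 + dh * 2 + dw);
          for (int w = 0; w < W; ++w) {
            const double* src = tc + (size_t)H * w;
            double* dst = yc + dh + (size_t)Ho * (2 * w + dw);
            for (int h = 0; h < H; ++h) dst[2 * h] = src[h] + bco;
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv_bwd(NumericVector x, NumericMatrix Wm, NumericVector dy) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  const int Cout = Wm.nrow() / 4;
  const int Ho = 2 * H, Wo = 2 * W;
  const arma::uword HW = (arma::uword)H * W;
  arma::mat Wmat(Wm.begin(), Wm.nrow(), Cin, false);
  NumericVector dx(HW * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dW(Wm.nrow(), Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dT(HW, Wm.nrow());
  for (int n = 0; n < N; ++n) {
    const double* dyp = &dy[(size_t)Ho * Wo * Cout * n];
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyp + (size_t)Ho * Wo * co;
      double s = 0.0;
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh) {
          double* tc = dT.colptr(co * 4 + dh * 2 + dw);
          for (int w = 0; w < W; ++w) {
            const double* src = dyc + dh + (size_t)Ho * (2 * w + dw);
            double* dst = tc + (size_t)H * w;
            for (int h = 0; h < H; ++h) { dst[h] = src[2 * h]; s += src[2 * h]; }
          }
        }
      db(co) += s;
    }
    arma::mat X(const_cast<double*>(&x[HW * Cin * n]), HW, Cin, false);
    dW += dT.t() * X;
    arma::mat dX(&dx[HW * Cin * n], HW, Cin, false, true);
    dX = dT * Wmat;
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
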