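// Numeric kernels for the convolutional phase classifier.
// Layout: activations are R arrays [H, W, C, N] (column-major), conv weights
// [kh, kw, C, OC]. Convolution is im2col + GEMM per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col for one sample: K is (kh*kw*C) x (OH*OW)
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad_h, int pad_w,
                   int OH, int OW, arma::mat& K) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      int col = oh + OH * ow;
      double* dst = K.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          int w = ow * stride - pad_w + kj;
          for (int ki = 0; ki < kh; ++ki) {
            int h = oh * stride - pad_h + ki;
            int row = ki + kh * (kj + kw * c);
            dst[row] = (h >= 0 && h < H && w >= 0 && w < W)
              ? x[h + H * (w + W * c)] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& K, int H, int W, int C,
                       int kh, int kw, int stride, int pad_h, int pad_w,
                       int OH, int OW, double* dx) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      int col = oh + OH * ow;
      const double* src = K.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          int w = ow * stride - pad_w + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int h = oh * stride - pad_h + ki;
            if (h < 0 || h >= H) continue;
            dx[h + H * (w + W * c)] += src[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride,
                                 int pad_h, int pad_w) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], OC = wd[3];
  if (wd[2] != C) stop("conv: channel mismatch");
  int OH = out_size(H, kh, stride, pad_h), OW = out_size(W, kw, stride, pad_w);
  if (OH < 1 || OW < 1) stop("conv: output size collapsed");
  NumericVector y(OH * OW * OC * N);
  y.attr("dim") = IntegerVector::create(OH, OW, OC, N);
  // weights reshaped to (kh*kw*C) x OC
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, OC, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), OC, false, true);
  arma::mat K(kh * kw * C, OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
           pad_h, pad_w, OH, OW, K);
    arma::mat Ym(y.begin() + (size_t)n * OH * OW * OC, OH * OW, OC,
                 false, true);
    Ym = K.t() * Wm;
    Ym.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad_h, int pad_w) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], OC = wd[3];
  int OH = yd[0], OW = yd[1];
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(OC);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, OC, false, true);
  arma::mat dWm(dw.begin(), kh * kw * C, OC, false, true);
  arma::vec dbv(db.begin(), OC, false, true);
  arma::mat K(kh * kw * C, OH * OW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
           pad_h, pad_w, OH, OW, K);
    arma::mat dYm(dy.begin() + (size_t)n * OH * OW * OC, OH * OW, OC,
                  false, true);
    dWm += K * dYm;
    dbv += arma::sum(dYm, 0).t();
    arma::mat dK = Wm * dYm.t();                   // (khkwC) x (OH*OW)
    col2im_add(dK, H, W, C, kh, kw, stride, pad_h, pad_w, OH, OW,
               dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int kh, int kw, int stride,
                         int pad_h, int pad_w) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = out_size(H, kh, stride, pad_h), OW = out_size(W, kw, stride, pad_w);
  if (OH < 1 || OW < 1) stop("maxpool: output size collapsed");
  NumericVector y((size_t)OH * OW * C * N);
  IntegerVector idx((size_t)OH * OW * C * N);   // linear index into sample
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* ys = y.begin() + (size_t)n * OH * OW * C;
    int* is = idx.begin() + (size_t)n * OH * OW * C;
    for (int c = 0; c < C; ++c) {
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < kw; ++kj) {
            int w = ow * stride - pad_w + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int h = oh * stride - pad_h + ki;
              if (h < 0 || h >= H) continue;
              double v = xs[h + H * (w + W * c)];
              if (v > best) { best = v; besti = h + H * (w + W * c); }
            }
          }
          ys[oh + OH * (ow + OW * c)] = best;
          is[oh + OH * (ow + OW * c)] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  size_t per_out = (size_t)yd[0] * yd[1] * yd[2];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const double* ds = dy.begin() + (size_t)n * per_out;
    const int* is = idx.begin() + (size_t)n * per_out;
    double* xs = dx.begin() + (size_t)n * H * W * C;
    for (size_t i = 0; i < per_out; ++i)
      if (is[i] >= 0) xs[is[i]] += ds[i];
  }
  return dx;
}

// average pooling, zero padding counted in the divisor (kh*kw)
// [[Rcpp::export]]
NumericVector avgpool_forward_cpp(NumericVector x, int kh, int kw, int stride,
                                  int pad_h, int pad_w) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = out_size(H, kh, stride, pad_h), OW = out_size(W, kw, stride, pad_w);
  if (OH < 1 || OW < 1) stop("avgpool: output size collapsed");
  NumericVector y((size_t)OH * OW * C * N);
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  double inv = 1.0 / (kh * kw);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* ys = y.begin() + (size_t)n * OH * OW * C;
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double s = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            int w = ow * stride - pad_w + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int h = oh * stride - pad_h + ki;
              if (h < 0 || h >= H) continue;
              s += xs[h + H * (w + W * c)];
            }
          }
          ys[oh + OH * (ow + OW * c)] = s * inv;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_backward_cpp(NumericVector dy, IntegerVector xdim,
                                   int kh, int kw, int stride,
                                   int pad_h, int pad_w) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  int OH = yd[0], OW = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double inv = 1.0 / (kh * kw);
  for (int n = 0; n < N; ++n) {
    const double* ds = dy.begin() + (size_t)n * OH * OW * C;
    double* xs = dx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double g = ds[oh + OH * (ow + OW * c)] * inv;
          for (int kj = 0; kj < kw; ++kj) {
            int w = ow * stride - pad_w + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int h = oh * stride - pad_h + ki;
              if (h < 0 || h >= H) continue;
              xs[h + H * (w + W * c)] += g;
            }
          }
        }
  }
  return dx;
}

// bilinear warp of an H x W x C image; A is a 2x3 matrix mapping output
// (row, col) to input (row, col): sr = A(0,0)*r + A(0,1)*c + A(0,2), etc.
// out-of-range samples take value `fill`.
// [[Rcpp::export]]
NumericVector affine_warp_cpp(NumericVector img, NumericMatrix A,
                              double fill) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = d;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double sr = A(0, 0) * r + A(0, 1) * c + A(0, 2);
      double sc = A(1, 0) * r + A(1, 1) * c + A(1, 2);
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      double fr = sr - r0, fc = sc - c0;
      for (int ch = 0; ch < C; ++ch) {
        const double* p = img.begin() + (size_t)ch * H * W;
        auto at = [&](int rr, int cc) -> double {
          return (rr >= 0 && rr < H && cc >= 0 && cc < W)
            ? p[rr + H * cc] : fill;
        };
        double v = (1 - fr) * (1 - fc) * at(r0, c0)
                 + (1 - fr) * fc * at(r0, c0 + 1)
                 + fr * (1 - fc) * at(r0 + 1, c0)
                 + fr * fc * at(r0 + 1, c0 + 1);
        out[r + H * (c + (size_t)W * ch)] = v;
      }
    }
  }
  return out;
}
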