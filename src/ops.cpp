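// Low-level numerical kernels for the GAN engine and image resampling.
//
// Feature-map tensors are stored channel-fastest, (C, H, W, B) column-major,
// so that im2col can copy whole channel slices contiguously and the heavy
// lifting reduces to one BLAS dgemm per layer per direction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int H, int k, int s, int p) {
  return (H + 2 * p - k) / s + 1;
}

// col matrix: (C*k*k) x (Ho*Wo*B); row = c + C*(dh + k*dw),
// column = ho + Ho*(wo + Wo*b); input pixel h = ho*s - p + dh (0-based).
static void im2col_cpu(const double* x, int C, int H, int W, int B,
                       int k, int s, int p, int Ho, int Wo, double* col) {
  const size_t K = (size_t)C * k * k;
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (size_t)C * H * W * b;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* cp = col + K * ((size_t)ho + (size_t)Ho * (wo + (size_t)Wo * b));
        for (int dw = 0; dw < k; ++dw) {
          const int w = wo * s - p + dw;
          for (int dh = 0; dh < k; ++dh) {
            const int h = ho * s - p + dh;
            double* dst = cp + (size_t)C * (dh + k * dw);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              std::memcpy(dst, xb + (size_t)C * (h + (size_t)H * w),
                          C * sizeof(double));
            } else {
              std::memset(dst, 0, C * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add col entries back into the image.
static void col2im_cpu(const double* col, int C, int H, int W, int B,
                       int k, int s, int p, int Ho, int Wo, double* x) {
  const size_t K = (size_t)C * k * k;
  std::memset(x, 0, (size_t)C * H * W * B * sizeof(double));
  for (int b = 0; b < B; ++b) {
    double* xb = x + (size_t)C * H * W * b;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double* cp = col + K * ((size_t)ho + (size_t)Ho * (wo + (size_t)Wo * b));
        for (int dw = 0; dw < k; ++dw) {
          const int w = wo * s - p + dw;
          if (w < 0 || w >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            const int h = ho * s - p + dh;
            if (h < 0 || h >= H) continue;
            const double* src = cp + (size_t)C * (dh + k * dw);
            double* dst = xb + (size_t)C * (h + (size_t)H * w);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

static NumericVector with_dims(arma::mat& m, int d1, int d2, int d3, int d4) {
  NumericVector out(m.memptr(), m.memptr() + m.n_elem);
  out.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return out;
}

// Strided convolution: x (Cin,H,W,B), Wm (Cout x Cin*k*k), bias (Cout).
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(const NumericVector& x, const IntegerVector& dims,
                           const arma::mat& Wm, const arma::vec& bias,
                           int k, int s, int p) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Ho = conv_out_dim(H, k, s, p), Wo = conv_out_dim(W, k, s, p);
  arma::mat col((size_t)C * k * k, (size_t)Ho * Wo * B);
  im2col_cpu(x.begin(), C, H, W, B, k, s, p, Ho, Wo, col.memptr());
  arma::mat Y = Wm * col;
  Y.each_col() += bias;
  return with_dims(Y, Wm.n_rows, Ho, Wo, B);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const NumericVector& x, const IntegerVector& dims,
                  const arma::mat& Wm, const NumericVector& gy,
                  int k, int s, int p) {
  const int C = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Ho = conv_out_dim(H, k, s, p), Wo = conv_out_dim(W, k, s, p);
  const int Cout = Wm.n_rows;
  arma::mat col((size_t)C * k * k, (size_t)Ho * Wo * B);
  im2col_cpu(x.begin(), C, H, W, B, k, s, p, Ho, Wo, col.memptr());
  const arma::mat G(const_cast<double*>(gy.begin()), Cout,
                    (size_t)Ho * Wo * B, false, true);
  arma::mat gW = G * col.t();
  arma::vec gb = arma::sum(G, 1);
  arma::mat gcol = Wm.t() * G;
  arma::mat gx(C, (size_t)H * W * B);
  col2im_cpu(gcol.memptr(), C, H, W, B, k, s, p, Ho, Wo, gx.memptr());
  return List::create(_["gx"] = with_dims(gx, C, H, W, B),
                      _["gW"] = gW, _["gb"] = gb);
}

// Transposed convolution: x (Cin,H,W,B), Wt (Cin x Cout*k*k), bias (Cout).
// Output (Cout, (H-1)*s - 2p + k, ..., B); implemented as the adjoint of
// the strided convolution with the same geometry.
// [[Rcpp::export]]
NumericVector cpp_convt_fwd(const NumericVector& x, const IntegerVector& dims,
                            const arma::mat& Wt, const arma::vec& bias,
                            int k, int s, int p) {
  const int Cin = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Cout = Wt.n_cols / (k * k);
  const int Ho = (H - 1) * s - 2 * p + k, Wo = (W - 1) * s - 2 * p + k;
  const arma::mat X(const_cast<double*>(x.begin()), Cin,
                    (size_t)H * W * B, false, true);
  arma::mat cols = Wt.t() * X;  // (Cout*k*k) x (H*W*B)
  arma::mat y(Cout, (size_t)Ho * Wo * B);
  // conv geometry: convolving y (Ho,Wo) with (k,s,p) yields (H,W)
  col2im_cpu(cols.memptr(), Cout, Ho, Wo, B, k, s, p, H, W, y.memptr());
  y.each_col() += bias;
  return with_dims(y, Cout, Ho, Wo, B);
}

// [[Rcpp::export]]
List cpp_convt_bwd(const NumericVector& x, const IntegerVector& dims,
                   const arma::mat& Wt, const NumericVector& gy,
                   int k, int s, int p) {
  const int Cin = dims[0], H = dims[1], W = dims[2], B = dims[3];
  const int Cout = Wt.n_cols / (k * k);
  const int Ho = (H - 1) * s - 2 * p + k, Wo = (W - 1) * s - 2 * p + k;
  arma::mat colg((size_t)Cout * k * k, (size_t)H * W * B);
  im2col_cpu(gy.begin(), Cout, Ho, Wo, B, k, s, p, H, W, colg.memptr());
  const arma::mat X(const_cast<double*>(x.begin()), Cin,
                    (size_t)H * W * B, false, true);
  arma::mat gx = Wt * colg;
  arma::mat gW = X * colg.t();
  const arma::mat G(const_cast<double*>(gy.begin()), Cout,
                    (size_t)Ho * Wo * B, false, true);
  arma::vec gb = arma::sum(G, 1);
  return List::create(_["gx"] = with_dims(gx, Cin, H, W, B),
                      _["gW"] = gW, _["gb"] = gb);
}

// Catmull-Rom cubic kernel (a = -0.5), the common bicubic convention.
static inline double cubic_w(double d) {
  const double a = -0.5;
  d = std::fabs(d);
  if (d <= 1.0) return ((a + 2.0) * d - (a + 3.0)) * d * d + 1.0;
  if (d < 2.0)  return (((d - 5.0) * d + 8.0) * d - 4.0) * a;
  return 0.0;
}

static void bicubic_taps(int n_in, int n_out, arma::imat& idx, arma::mat& wt) {
  idx.set_size(4, n_out);
  wt.set_size(4, n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    const double src = (i + 0.5) * scale - 0.5;
    const int i0 = (int)std::floor(src);
    for (int t = 0; t < 4; ++t) {
      int j = i0 - 1 + t;
      wt(t, i) = cubic_w(src - j);
      idx(t, i) = std::min(std::max(j, 0), n_in - 1);  // clamp at borders
    }
    const double sw = arma::accu(wt.col(i));
    wt.col(i) /= sw;
  }
}

// Bicubic resize of a single-channel image (values untouched otherwise).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bicubic(const NumericMatrix& img, int h_out, int w_out) {
  const int H = img.nrow(), W = img.ncol();
  arma::imat ri, ci;
  arma::mat rw, cw;
  bicubic_taps(H, h_out, ri, rw);
  bicubic_taps(W, w_out, ci, cw);
  // rows first
  arma::mat tmp(h_out, W);
  for (int w = 0; w < W; ++w)
    for (int i = 0; i < h_out; ++i) {
      double v = 0.0;
      for (int t = 0; t < 4; ++t) v += rw(t, i) * img(ri(t, i), w);
      tmp(i, w) = v;
    }
  NumericMatrix out(h_out, w_out);
  for (int j = 0; j < w_out; ++j)
    for (int i = 0; i < h_out; ++i) {
      double v = 0.0;
      for (int t = 0; t < 4; ++t) v += cw(t, j) * tmp(i, ci(t, j));
      out(i, j) = v;
    }
  return out;
}
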