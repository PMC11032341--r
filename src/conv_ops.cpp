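// Convolution and max-pooling primitives for the stream networks.
// Array layouts follow R column-major conventions:
//   images / activations: (H, W, C, B)
//   conv weights:         (k, k, C, F)
// im2col + BLAS gemm per image; backward reuses the same patch geometry.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &d1, int &d2,
                             int &d3, int &d4) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D array");
  d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
}

// Fill the im2col matrix (k*k*C x Ho*Wo) for image `xb` (H,W,C column-major).
static void im2col(const double *xb, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo, arma::mat &col) {
  for (int c = 0; c < C; ++c) {
    const double *xc = xb + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int p = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          bool win = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            int n = ho + Ho * wo;
            col(p, n) = (win && hi >= 0 && hi < H) ? xc[hi + (size_t)H * wi]
                                                   : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward_cpp")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector bias, int stride, int pad) {
  int H, W, C, B, k, k2, Cw, F;
  get_dims4(x, H, W, C, B);
  get_dims4(w, k, k2, Cw, F);
  if (k != k2) stop("kernels must be square");
  if (Cw != C) stop("channel mismatch between input and weights");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than (padded) input");

  arma::mat Wmat(const_cast<double *>(w.begin()), (size_t)k * k * C, F, false);
  arma::rowvec brow(const_cast<double *>(bias.begin()), F, false);
  NumericVector out((size_t)Ho * Wo * F * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, B);

  arma::mat col((size_t)k * k * C, (size_t)Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (size_t)b * H * W * C;
    im2col(xb, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat outb(out.begin() + (size_t)b * Ho * Wo * F, (size_t)Ho * Wo, F,
                   false, true);
    outb = col.t() * Wmat;
    outb.each_row() += brow;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward_cpp")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w,
                         NumericVector grad_out, int stride, int pad) {
  int H, W, C, B, k, k2, Cw, F, Ho, Wo, Fg, Bg;
  get_dims4(x, H, W, C, B);
  get_dims4(w, k, k2, Cw, F);
  get_dims4(grad_out, Ho, Wo, Fg, Bg);
  if (Fg != F || Bg != B) stop("grad_out dims inconsistent with x/w");

  arma::mat Wmat(const_cast<double *>(w.begin()), (size_t)k * k * C, F, false);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector dw((size_t)k * k * C * F);
  dw.attr("dim") = IntegerVector::create(k, k, C, F);
  NumericVector db(F);
  arma::mat dWmat(dw.begin(), (size_t)k * k * C, F, false, true);
  arma::vec dbv(db.begin(), F, false, true);

  arma::mat col((size_t)k * k * C, (size_t)Ho * Wo);
  arma::mat dcol((size_t)k * k * C, (size_t)Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (size_t)b * H * W * C;
    double *dxb = dx.begin() + (size_t)b * H * W * C;
    im2col(xb, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat goutb(const_cast<double *>(grad_out.begin()) +
                        (size_t)b * Ho * Wo * F,
                    (size_t)Ho * Wo, F, false);
    dWmat += col * goutb;
    dbv += arma::sum(goutb, 0).t();
    dcol = Wmat * goutb.t();
    // col2im: scatter-add patches back into dx
    for (int c = 0; c < C; ++c) {
      double *dxc = dxb + (size_t)c * H * W;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int p = ki + k * kj + k * k * c;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              dxc[hi + (size_t)H * wi] += dcol(p, ho + Ho * wo);
            }
          }
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool_forward_cpp")]]
List maxpool_forward_cpp(NumericVector x, int size, int stride) {
  int H, W, C, B;
  get_dims4(x, H, W, C, B);
  int Ho = (H - size) / stride + 1;
  int Wo = (W - size) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("pooling window larger than input");
  NumericVector out((size_t)Ho * Wo * C * B);
  IntegerVector idx((size_t)Ho * Wo * C * B);  // 0-based linear index into x
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);

  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double *xc = x.begin() + (size_t)(b * C + c) * H * W;
      size_t base = (size_t)(b * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = ho * stride, w0 = wo * stride;
          double best = xc[h0 + (size_t)H * w0];
          size_t besti = h0 + (size_t)H * w0;
          for (int dj = 0; dj < size; ++dj) {
            for (int di = 0; di < size; ++di) {
              size_t ii = (h0 + di) + (size_t)H * (w0 + dj);
              if (xc[ii] > best) { best = xc[ii]; besti = ii; }
            }
          }
          // out is (Ho,Wo,C,B): element (ho,wo,c,b)
          o = (size_t)ho + Ho * ((size_t)wo + Wo * ((size_t)c + (size_t)C * b));
          out[o] = best;
          idx[o] = (int)(base + besti);
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool_backward_cpp")]]
NumericVector maxpool_backward_cpp(IntegerVector idx, NumericVector grad_out,
                                   IntegerVector x_dim) {
  size_t n = 1;
  for (int i = 0; i < x_dim.size(); ++i) n *= (size_t)x_dim[i];
  NumericVector dx(n);
  dx.attr("dim") = x_dim;
  for (R_xlen_t i = 0; i < grad_out.size(); ++i) dx[idx[i]] += grad_out[i];
  return dx;
}
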