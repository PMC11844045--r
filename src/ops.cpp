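// Low-level kernels for the feature-map engine.
// Feature maps are R arrays laid out [H, W, C, N] (column-major), so each
// sample n occupies a contiguous H*W*C slab and each channel a contiguous
// H*W block. Convolutions are stride-1, same-padding (pad = dilation*(k-1)/2).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill `col` ((kh*kw*C) x (H*W)) with patches of one sample slab `xs`.
// Row index r = i + kh*(j + kw*c); column index q = ho + H*wo.
static void im2col(const double* xs, int H, int W, int C,
                   int kh, int kw, int dil, arma::mat& col) {
  const int ph = dil * (kh - 1) / 2, pw = dil * (kw - 1) / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < W; ++wo) {
          const int wi = wo + dil * j - pw;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)wi * H;
          double* dst = col.colptr(0) + r; // stride n_rows between columns
          const int nr = col.n_rows;
          for (int ho = 0; ho < H; ++ho) {
            const int hi = ho + dil * i - ph;
            if (hi < 0 || hi >= H) continue;
            dst[(size_t)(ho + H * wo) * nr] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add columns of `col` back into one gradient slab.
static void col2im(const arma::mat& col, double* gxs, int H, int W, int C,
                   int kh, int kw, int dil) {
  const int ph = dil * (kh - 1) / 2, pw = dil * (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* gc = gxs + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < W; ++wo) {
          const int wi = wo + dil * j - pw;
          if (wi < 0 || wi >= W) continue;
          double* gcol = gc + (size_t)wi * H;
          const double* src = col.colptr(0) + r;
          const int nr = col.n_rows;
          for (int ho = 0; ho < H; ++ho) {
            const int hi = ho + dil * i - ph;
            if (hi < 0 || hi >= H) continue;
            gcol[hi] += src[(size_t)(ho + H * wo) * nr];
          }
        }
      }
    }
  }
}

// x [H,W,IC,N], w [kh,kw,IC,OC], b length OC -> y [H,W,OC,N]
// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int dil) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], OC = dw[3];
  if (dw[2] != C) stop("channel mismatch: input has %d, kernel expects %d", C, dw[2]);
  const int R = kh * kw * C, Q = H * W;
  NumericVector y(Q * (size_t)OC * N);
  y.attr("dim") = IntegerVector::create(H, W, OC, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), R, OC, false, true);
  arma::mat col(R, Q);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * Q * C, H, W, C, kh, kw, dil, col);
    arma::mat Y(y.begin() + (size_t)n * Q * OC, Q, OC, false, true);
    Y = col.t() * Wmat;
    for (int o = 0; o < OC; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int dil) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], OC = dw[3];
  const int R = kh * kw * C, Q = H * W;
  NumericVector gx(x.size()); gx.attr("dim") = dx;
  NumericVector gw(w.size()); gw.attr("dim") = dw;
  NumericVector gb(OC);
  arma::mat Wmat(const_cast<double*>(w.begin()), R, OC, false, true);
  arma::mat GW(gw.begin(), R, OC, false, true);
  arma::vec GB(gb.begin(), OC, false, true);
  arma::mat col(R, Q);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * Q * C, H, W, C, kh, kw, dil, col);
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * Q * OC, Q, OC,
                 false, true);
    GW += col * GY;
    GB += arma::sum(GY, 0).t();
    arma::mat gcol = Wmat * GY.t();
    col2im(gcol, gx.begin() + (size_t)n * Q * C, H, W, C, kh, kw, dil);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled map and
// 0-based argmax offsets into each sample slab (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial size");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++p) {
          double best = -INFINITY; int barg = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int off = (2 * ho + di) + H * (2 * wo + dj) + H * W * c;
              if (xs[off] > best) { best = xs[off]; barg = off; }
            }
          }
          y[p] = best; idx[p] = barg;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gy, IntegerVector idx,
                                    IntegerVector dimx) {
  const int H = dimx[0], W = dimx[1], C = dimx[2], N = dimx[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = dimx;
  const size_t slab = (size_t)H * W * C;
  const size_t per = (size_t)idx.size() / N;
  for (int n = 0; n < N; ++n) {
    double* gs = gx.begin() + n * slab;
    const size_t base = n * per;
    for (size_t p = 0; p < per; ++p) gs[idx[base + p]] += gy[base + p];
  }
  return gx;
}

static inline void lin_weights(int dst, int src_len, int dst_len,
                               int& i0, int& i1, double& w1) {
  // align_corners = FALSE convention
  double s = (dst + 0.5) * ((double)src_len / dst_len) - 0.5;
  if (s < 0) s = 0;
  if (s > src_len - 1) s = src_len - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, src_len - 1);
  w1 = s - i0;
}

// Bilinear resize [H,W,C,N] -> [Ho,Wo,C,N]
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        int j0, j1; double wj;
        lin_weights(wo, W, Wo, j0, j1, wj);
        for (int ho = 0; ho < Ho; ++ho, ++p) {
          int i0, i1; double wi;
          lin_weights(ho, H, Ho, i0, i1, wi);
          y[p] = (1 - wi) * (1 - wj) * xc[i0 + H * j0]
               + wi * (1 - wj) * xc[i1 + H * j0]
               + (1 - wi) * wj * xc[i0 + H * j1]
               + wi * wj * xc[i1 + H * j1];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_backward(NumericVector gy, int H, int W) {
  IntegerVector dg = gy.attr("dim");
  const int Ho = dg[0], Wo = dg[1], C = dg[2], N = dg[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t p = 0;
  for (int n = 0; n < N; ++n) {
    double* gs = gx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* gc = gs + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        int j0, j1; double wj;
        lin_weights(wo, W, Wo, j0, j1, wj);
        for (int ho = 0; ho < Ho; ++ho, ++p) {
          int i0, i1; double wi;
          lin_weights(ho, H, Ho, i0, i1, wi);
          const double g = gy[p];
          gc[i0 + H * j0] += (1 - wi) * (1 - wj) * g;
          gc[i1 + H * j0] += wi * (1 - wj) * g;
          gc[i0 + H * j1] += (1 - wi) * wj * g;
          gc[i1 + H * j1] += wi * wj * g;
        }
      }
    }
  }
  return gx;
}
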