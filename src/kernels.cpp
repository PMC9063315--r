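#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are column-major R arrays of dim (H, W, C, N): row index
// fastest, batch slowest. im2col lays a (kh*kw*C) x (Ho*Wo*N) patch matrix
// so that a conv is one GEMM against a (kh*kw*C) x Cout weight matrix whose
// rows are ordered ki (kernel row) fastest, then kj, then input channel --
// exactly matrix(array(kh, kw, Cin, Cout)).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& x, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int nrow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * H * W * C;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double* col = op + (size_t)nrow * (oh + (size_t)Ho * (ow + (size_t)Wo * n));
        const int h0 = oh * sh - ph;
        const int w0 = ow * sw - pw;
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)c * H * W;
          for (int kj = 0; kj < kw; ++kj) {
            const int w = w0 + kj;
            const bool win = (w >= 0 && w < W);
            for (int ki = 0; ki < kh; ++ki) {
              const int h = h0 + ki;
              const int r = ki + kh * (kj + kw * c);
              col[r] = (win && h >= 0 && h < H) ? xc[h + (size_t)H * w] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: accumulates patch columns back into an (H, W, C, N) array.
// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& cols, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  const double* op = cols.begin();
  const int nrow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    double* xn = xp + (size_t)n * H * W * C;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const double* col = op + (size_t)nrow * (oh + (size_t)Ho * (ow + (size_t)Wo * n));
        const int h0 = oh * sh - ph;
        const int w0 = ow * sw - pw;
        for (int c = 0; c < C; ++c) {
          double* xc = xn + (size_t)c * H * W;
          for (int kj = 0; kj < kw; ++kj) {
            const int w = w0 + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int h = h0 + ki;
              if (h < 0 || h >= H) continue;
              xc[h + (size_t)H * w] += col[ki + kh * (kj + kw * c)];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Max pooling; returns pooled values and 1-based argmax linear indices into x.
// [[Rcpp::export]]
List maxpool_fwd_cpp(const NumericVector& x, int H, int W, int C, int N,
                     int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf;
          size_t bi = 0;
          for (int kj = 0; kj < k; ++kj) {
            const int w = ow * s - p + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h = oh * s - p + ki;
              if (h < 0 || h >= H) continue;
              const double v = xc[h + (size_t)H * w];
              if (v > best) { best = v; bi = h + (size_t)H * w; }
            }
          }
          const size_t o = oh + (size_t)Ho * (ow + (size_t)Wo * (c + (size_t)C * n));
          y[o] = best;
          idx[o] = (int)(base + bi) + 1;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(const NumericVector& dy, const IntegerVector& idx,
                              R_xlen_t len) {
  NumericVector dx(len);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

static inline void lerp_coeff(int od, int in, int out, int& i0, int& i1, double& w1) {
  // half-pixel centers, clamped to the border
  double src = (od + 0.5) * (double)in / (double)out - 0.5;
  if (src < 0) src = 0;
  if (src > in - 1) src = in - 1;
  i0 = (int)std::floor(src);
  i1 = i0 + 1 < in ? i0 + 1 : i0;
  w1 = src - i0;
}

// [[Rcpp::export]]
NumericVector bilinear_resize_cpp(const NumericVector& x, int H, int W, int C, int N,
                                  int Ho, int Wo) {
  NumericVector y((size_t)Ho * Wo * C * N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> wh(Ho), ww(Wo);
  for (int i = 0; i < Ho; ++i) lerp_coeff(i, H, Ho, h0[i], h1[i], wh[i]);
  for (int j = 0; j < Wo; ++j) lerp_coeff(j, W, Wo, w0[j], w1[j], ww[j]);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + cn * H * W;
    double* yc = yp + cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double a = xc[h0[i] + (size_t)H * w0[j]];
        const double b = xc[h1[i] + (size_t)H * w0[j]];
        const double c = xc[h0[i] + (size_t)H * w1[j]];
        const double d = xc[h1[i] + (size_t)H * w1[j]];
        const double top = a * (1 - wh[i]) + b * wh[i];
        const double bot = c * (1 - wh[i]) + d * wh[i];
        yc[i + (size_t)Ho * j] = top * (1 - ww[j]) + bot * ww[j];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// Adjoint of bilinear_resize_cpp (scatter with the same coefficients).
// [[Rcpp::export]]
NumericVector bilinear_resize_bwd_cpp(const NumericVector& dy, int H, int W, int C, int N,
                                      int Ho, int Wo) {
  NumericVector dx((size_t)H * W * C * N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> wh(Ho), ww(Wo);
  for (int i = 0; i < Ho; ++i) lerp_coeff(i, H, Ho, h0[i], h1[i], wh[i]);
  for (int j = 0; j < Wo; ++j) lerp_coeff(j, W, Wo, w0[j], w1[j], ww[j]);
  const double* gp = dy.begin();
  double* xp = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    double* xc = xp + cn * H * W;
    const double* gc = gp + cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double g = gc[i + (size_t)Ho * j];
        xc[h0[i] + (size_t)H * w0[j]] += g * (1 - wh[i]) * (1 - ww[j]);
        xc[h1[i] + (size_t)H * w0[j]] += g * wh[i] * (1 - ww[j]);
        xc[h0[i] + (size_t)H * w1[j]] += g * (1 - wh[i]) * ww[j];
        xc[h1[i] + (size_t)H * w1[j]] += g * wh[i] * ww[j];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// [[Rcpp::export]]
NumericVector nearest_resize_cpp(const NumericVector& x, int H, int W, int C, int N,
                                 int Ho, int Wo) {
  NumericVector y((size_t)Ho * Wo * C * N);
  std::vector<int> hm(Ho), wm(Wo);
  for (int i = 0; i < Ho; ++i) {
    int v = (int)std::floor((i + 0.5) * (double)H / (double)Ho);
    hm[i] = v < H ? v : H - 1;
  }
  for (int j = 0; j < Wo; ++j) {
    int v = (int)std::floor((j + 0.5) * (double)W / (double)Wo);
    wm[j] = v < W ? v : W - 1;
  }
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + cn * H * W;
    double* yc = yp + cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        yc[i + (size_t)Ho * j] = xc[hm[i] + (size_t)H * wm[j]];
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}
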