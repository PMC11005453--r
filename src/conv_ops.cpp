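#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays in (batch, channel, row, col) order, i.e. dim
// c(N, C, H, W) with the batch index fastest (column-major). Convolution
// is implemented as an im2col gather feeding BLAS matrix products on the
// R side; col2im is the adjoint scatter-add. All kernels are
// single-threaded and deterministic.

// Patch matrix: rows indexed r = n + N*(ho + Ho*wo), columns
// c = ci + C*(kh + K*kw); out-of-range taps are zero.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int N, int C, int H, int W,
                         int K, int stride, int pad) {
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const int rows = N * Ho * Wo;
  NumericMatrix out(rows, C * K * K);
  const double *xp = REAL(x);
  double *op = REAL(out);
  for (int kw = 0; kw < K; ++kw)
    for (int kh = 0; kh < K; ++kh)
      for (int ci = 0; ci < C; ++ci) {
        double *col = op + (size_t)rows * (ci + C * (kh + K * kw));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pad;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pad;
            double *dst = col + (size_t)N * (ho + Ho * wo);
            if (wi < 0 || wi >= W || hi < 0 || hi >= H) {
              for (int n = 0; n < N; ++n) dst[n] = 0.0;
            } else {
              const double *src = xp + (size_t)N * (ci + C * (hi + H * wi));
              for (int n = 0; n < N; ++n) dst[n] = src[n];
            }
          }
        }
      }
  return out;
}

// Adjoint of im2col: scatter-add patch-matrix gradients back to the
// input layout.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix g, int N, int C, int H, int W,
                         int K, int stride, int pad) {
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const int rows = N * Ho * Wo;
  NumericVector out(N * C * H * W);
  const double *gp = REAL(g);
  double *op = REAL(out);
  for (int kw = 0; kw < K; ++kw)
    for (int kh = 0; kh < K; ++kh)
      for (int ci = 0; ci < C; ++ci) {
        const double *col = gp + (size_t)rows * (ci + C * (kh + K * kw));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + kh - pad;
            if (hi < 0 || hi >= H) continue;
            const double *src = col + (size_t)N * (ho + Ho * wo);
            double *dst = op + (size_t)N * (ci + C * (hi + H * wi));
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
  out.attr("dim") = IntegerVector::create(N, C, H, W);
  return out;
}

// Depthwise convolution, stride 1, 'same' zero padding. wt: dim c(C, K, K).
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector wt,
                             NumericVector bias, int N, int C, int H, int W,
                             int K) {
  const int pad = (K - 1) / 2;
  NumericVector y(N * C * H * W);
  const double *xp = REAL(x), *wp = REAL(wt), *bp = REAL(bias);
  double *yp = REAL(y);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        double *dst = yp + (size_t)N * (c + C * (h + H * w));
        for (int n = 0; n < N; ++n) dst[n] = bp[c];
      }
  for (int kw = 0; kw < K; ++kw)
    for (int kh = 0; kh < K; ++kh)
      for (int w = 0; w < W; ++w) {
        int wi = w + kw - pad;
        if (wi < 0 || wi >= W) continue;
        for (int h = 0; h < H; ++h) {
          int hi = h + kh - pad;
          if (hi < 0 || hi >= H) continue;
          for (int c = 0; c < C; ++c) {
            const double wv = wp[c + C * (kh + K * kw)];
            const double *src = xp + (size_t)N * (c + C * (hi + H * wi));
            double *dst = yp + (size_t)N * (c + C * (h + H * w));
            for (int n = 0; n < N; ++n) dst[n] += wv * src[n];
          }
        }
      }
  y.attr("dim") = IntegerVector::create(N, C, H, W);
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector wt, NumericVector gy,
                    int N, int C, int H, int W, int K) {
  const int pad = (K - 1) / 2;
  NumericVector gx(N * C * H * W), gw(C * K * K), gb(C);
  const double *xp = REAL(x), *wp = REAL(wt), *gp = REAL(gy);
  double *gxp = REAL(gx), *gwp = REAL(gw), *gbp = REAL(gb);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const double *g0 = gp + (size_t)N * (c + C * (h + H * w));
        double acc = 0.0;
        for (int n = 0; n < N; ++n) acc += g0[n];
        gbp[c] += acc;
      }
  for (int kw = 0; kw < K; ++kw)
    for (int kh = 0; kh < K; ++kh)
      for (int w = 0; w < W; ++w) {
        int wi = w + kw - pad;
        if (wi < 0 || wi >= W) continue;
        for (int h = 0; h < H; ++h) {
          int hi = h + kh - pad;
          if (hi < 0 || hi >= H) continue;
          for (int c = 0; c < C; ++c) {
            const int wix = c + C * (kh + K * kw);
            const double wv = wp[wix];
            const double *g0 = gp + (size_t)N * (c + C * (h + H * w));
            const double *x0 = xp + (size_t)N * (c + C * (hi + H * wi));
            double *gx0 = gxp + (size_t)N * (c + C * (hi + H * wi));
            double acc = 0.0;
            for (int n = 0; n < N; ++n) {
              gx0[n] += wv * g0[n];
              acc += x0[n] * g0[n];
            }
            gwp[wix] += acc;
          }
        }
      }
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  gw.attr("dim") = IntegerVector::create(C, K, K);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
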