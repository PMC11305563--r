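#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as R arrays with dim = c(C, H, W, N): channel
// fastest, then rows (y), columns (x), sample. im2col unrolls k x k patches
// so a convolution becomes one matrix product; row order of the patch
// matrix is (c, kh, kw) with c fastest, matching matrix(kernel, Cout) for a
// kernel array of dim c(Cout, Cin, k, k).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo * N);
  double *xo = REAL(x);
  double *po = REAL(out);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double *dst = po + col * (R_xlen_t)(C * k * k);
        for (int kw = 0; kw < k; ++kw) {
          int wi = wo * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            int hi = ho * stride - pad + kh;
            double *d = dst + (R_xlen_t)(kw * k + kh) * C;
            if (wi < 0 || wi >= W || hi < 0 || hi >= H) {
              for (int c = 0; c < C; ++c) d[c] = 0.0;
            } else {
              double *src = xo + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
              for (int c = 0; c < C; ++c) d[c] = src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add of a patch matrix back onto the input grid (gradient of
// im2col); `cols` has the same layout as cpp_im2col output.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W * N);
  double *xo = REAL(x);
  double *po = REAL(cols);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double *src = po + col * (R_xlen_t)(C * k * k);
        for (int kw = 0; kw < k; ++kw) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            double *s = src + (R_xlen_t)(kw * k + kh) * C;
            double *dst = xo + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) dst[c] += s[c];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling with argmax bookkeeping (1-based linear index into the input
// vector) so the backward pass is a plain scatter.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int C, int H, int W, int N,
                 int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  IntegerVector arg((R_xlen_t)C * Ho * Wo * N);
  double *xo = REAL(x);
  double *po = REAL(out);
  int *ao = INTEGER(arg);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              R_xlen_t idx = c + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
              if (xo[idx] > best) { best = xo[idx]; besti = idx; }
            }
          }
          R_xlen_t o = c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
          po[o] = best;
          ao[o] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["value"] = out, _["argmax"] = arg);
}
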