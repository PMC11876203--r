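#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, C, N), column-major.
// im2col lays each receptive-field patch out as a column with row index
// ki + kh*(kj + kw*c) (0-based), so that matrix(Warray, kh*kw*Cin, Cout)
// lines up without any permutation. Column index is
// ho + Ho*(wo + Wo*n): spatial position fastest, image last.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int kh, int kw, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int L = kh * kw * C;
  NumericMatrix out(L, Ho * Wo * N);
  const double *xp = x.begin();
  double *op = out.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double *dst = op + col * L;
        const int i0 = ho * stride - pad;
        const int j0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *src = xp + ((R_xlen_t)n * C + c) * planeHW;
          for (int kj = 0; kj < kw; ++kj) {
            const int j = j0 + kj;
            for (int ki = 0; ki < kh; ++ki) {
              const int i = i0 + ki;
              double v = 0.0;
              if (i >= 0 && i < H && j >= 0 && j < W)
                v = src[(R_xlen_t)j * H + i];
              dst[ki + kh * (kj + kw * c)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch columns back into an image tensor.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int L = kh * kw * C;
  if (cols.nrow() != L || cols.ncol() != (R_xlen_t)Ho * Wo * N)
    stop("col2im_cpp: column matrix shape inconsistent with target dims");
  NumericVector x((R_xlen_t)H * W * C * N);
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  double *xp = x.begin();
  const double *cp = cols.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        const double *src = cp + col * L;
        const int i0 = ho * stride - pad;
        const int j0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double *dst = xp + ((R_xlen_t)n * C + c) * planeHW;
          for (int kj = 0; kj < kw; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              dst[(R_xlen_t)j * H + i] += src[ki + kh * (kj + kw * c)];
            }
          }
        }
      }
    }
  }
  return x;
}
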