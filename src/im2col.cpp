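#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Assemble the im2col matrix of a same-padded stride-1 convolution from a
// zero-padded input of layout (Hp, Wp, N, C). Output rows are ordered
// (i, j, n); columns ((dj*k + di)*C + c), matching the kernel-row order
// (cin fastest, then di, then dj). Copies are contiguous runs of length H.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector xp, int Hp, int Wp, int N, int C,
                         int H, int W, int k) {
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  const R_xlen_t ncol = (R_xlen_t)k * k * C;
  NumericVector buf(no_init(nrow * ncol));
  const double *src = xp.begin();
  double *dst = buf.begin();
  const R_xlen_t planeHp = (R_xlen_t)Hp * Wp;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const R_xlen_t colidx = ((R_xlen_t)dj * k + di) * C + c;
        double *d0 = dst + colidx * nrow;
        for (int n = 0; n < N; ++n) {
          const double *s0 = src + (R_xlen_t)c * planeHp * N +
                             (R_xlen_t)n * planeHp;
          for (int j = 0; j < W; ++j) {
            const double *sp = s0 + (R_xlen_t)(j + dj) * Hp + di;
            std::memcpy(d0 + ((R_xlen_t)n * W + j) * H, sp,
                        sizeof(double) * H);
          }
        }
      }
    }
  }
  buf.attr("dim") = IntegerVector::create(nrow, ncol);
  return NumericMatrix(buf);
}

// Zero-pad an (H, W, N, C) array by p voxels on each in-plane side.
// [[Rcpp::export]]
NumericVector pad_hw_cpp(NumericVector x, int H, int W, int N, int C, int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  NumericVector out(no_init((R_xlen_t)Hp * Wp * N * C));
  const double *src = x.begin();
  double *dst = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double *s0 = src + ((R_xlen_t)c * N + n) * H * W;
      double *d0 = dst + ((R_xlen_t)c * N + n) * Hp * Wp;
      // left and right border columns
      std::memset(d0, 0, sizeof(double) * (R_xlen_t)p * Hp);
      std::memset(d0 + (R_xlen_t)(W + p) * Hp, 0,
                  sizeof(double) * (R_xlen_t)p * Hp);
      for (int j = 0; j < W; ++j) {
        double *dc = d0 + (R_xlen_t)(j + p) * Hp;
        std::memset(dc, 0, sizeof(double) * p);
        std::memcpy(dc + p, s0 + (R_xlen_t)j * H, sizeof(double) * H);
        std::memset(dc + p + H, 0, sizeof(double) * p);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Hp, Wp, N, C);
  return out;
}

// elu (alpha = 1) forward: y and the derivative factor in one pass.
// [[Rcpp::export]]
List elu_fwd_cpp(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(no_init(n));
  NumericVector d(no_init(n));
  const double *xs = x.begin();
  double *ys = y.begin();
  double *ds = d.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (xs[i] > 0) {
      ys[i] = xs[i];
      ds[i] = 1.0;
    } else {
      double e = std::expm1(xs[i]);
      ys[i] = e;
      ds[i] = e + 1.0;
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["out"] = y, _["deriv"] = d);
}
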