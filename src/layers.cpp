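#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Batch-norm forward over an (M, C) view: per-channel mean/var, normalized
// output and xhat in one pass. Returns list(out, xhat, mean, var, invstd).
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, int M, int C, NumericVector gamma,
                NumericVector beta, double eps) {
  NumericVector out(no_init(x.size()));
  NumericVector xhat(no_init(x.size()));
  NumericVector mean_(C), var_(C), invstd(C);
  const double *xs = x.begin();
  double *os = out.begin();
  double *hs = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double *col = xs + (R_xlen_t)c * M;
    double s = 0, s2 = 0;
    for (int i = 0; i < M; ++i) {
      s += col[i];
      s2 += col[i] * col[i];
    }
    double mu = s / M;
    double v = s2 / M - mu * mu;
    if (v < 0) v = 0;
    double is = 1.0 / std::sqrt(v + eps);
    mean_[c] = mu; var_[c] = v; invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double *oc = os + (R_xlen_t)c * M;
    double *hc = hs + (R_xlen_t)c * M;
    for (int i = 0; i < M; ++i) {
      double h = (col[i] - mu) * is;
      hc[i] = h;
      oc[i] = g * h + b;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mean"] = mean_,
                      _["var"] = var_, _["invstd"] = invstd);
}

// Batch-norm backward (training mode): returns dx, dgamma, dbeta.
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, int M, int C,
                NumericVector gamma, NumericVector invstd) {
  NumericVector dx(no_init(dy.size()));
  NumericVector dgamma(C), dbeta(C);
  const double *ds = dy.begin();
  const double *hs = xhat.begin();
  double *xs = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double *dc = ds + (R_xlen_t)c * M;
    const double *hc = hs + (R_xlen_t)c * M;
    double sg = 0, sb = 0;
    for (int i = 0; i < M; ++i) {
      sg += dc[i] * hc[i];
      sb += dc[i];
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double k = gamma[c] * invstd[c];
    const double mb = sb / M, mg = sg / M;
    double *xc = xs + (R_xlen_t)c * M;
    for (int i = 0; i < M; ++i) {
      xc[i] = k * (dc[i] - mb - hc[i] * mg);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 2x2 max pooling on (H, W, N, C); returns pooled values and the within-
// window argmax code (0..3, first-wins ties) for the backward scatter.
// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x, int H, int W, int NC) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(no_init((R_xlen_t)Ho * Wo * NC));
  IntegerVector am(no_init((R_xlen_t)Ho * Wo * NC));
  const double *xs = x.begin();
  double *ys = y.begin();
  int *as = am.begin();
  for (int p = 0; p < NC; ++p) {
    const double *xp = xs + (R_xlen_t)p * H * W;
    double *yp = ys + (R_xlen_t)p * Ho * Wo;
    int *ap = as + (R_xlen_t)p * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double *w0 = xp + (R_xlen_t)(2 * j) * H + 2 * i;
        const double *w1 = w0 + H;
        double v[4] = { w0[0], w0[1], w1[0], w1[1] };
        int best = 0;
        for (int q = 1; q < 4; ++q) if (v[q] > v[best]) best = q;
        yp[j * Ho + i] = v[best];
        ap[j * Ho + i] = best;
      }
    }
  }
  return List::create(_["out"] = y, _["argmax"] = am);
}

// backward of 2x2 max pooling: scatter dy to the recorded argmax positions
// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector am, int H,
                               int W, int NC) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * NC);
  const double *ds = dy.begin();
  const int *as = am.begin();
  double *xs = dx.begin();
  for (int p = 0; p < NC; ++p) {
    const double *dp = ds + (R_xlen_t)p * Ho * Wo;
    const int *ap = as + (R_xlen_t)p * Ho * Wo;
    double *xp = xs + (R_xlen_t)p * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int code = ap[j * Ho + i];
        int di = code & 1, dj = code >> 1;
        xp[(R_xlen_t)(2 * j + dj) * H + 2 * i + di] += dp[j * Ho + i];
      }
    }
  }
  return dx;
}

// nearest-neighbour 2x upsampling on (H, W, N, C)
// [[Rcpp::export]]
NumericVector upsample2_cpp(NumericVector x, int H, int W, int NC) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(no_init((R_xlen_t)Ho * Wo * NC));
  const double *xs = x.begin();
  double *ys = y.begin();
  for (int p = 0; p < NC; ++p) {
    const double *xp = xs + (R_xlen_t)p * H * W;
    double *yp = ys + (R_xlen_t)p * Ho * Wo;
    for (int j = 0; j < W; ++j) {
      double *c0 = yp + (R_xlen_t)(2 * j) * Ho;
      double *c1 = c0 + Ho;
      const double *sc = xp + (R_xlen_t)j * H;
      for (int i = 0; i < H; ++i) {
        c0[2 * i] = sc[i]; c0[2 * i + 1] = sc[i];
        c1[2 * i] = sc[i]; c1[2 * i + 1] = sc[i];
      }
    }
  }
  return y;
}

// backward of nearest 2x upsampling: sum each 2x2 block
// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dy, int Ho, int Wo, int NC) {
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx(no_init((R_xlen_t)H * W * NC));
  const double *ds = dy.begin();
  double *xs = dx.begin();
  for (int p = 0; p < NC; ++p) {
    const double *dp = ds + (R_xlen_t)p * Ho * Wo;
    double *xp = xs + (R_xlen_t)p * H * W;
    for (int j = 0; j < W; ++j) {
      const double *c0 = dp + (R_xlen_t)(2 * j) * Ho;
      const double *c1 = c0 + Ho;
      double *sc = xp + (R_xlen_t)j * H;
      for (int i = 0; i < H; ++i) {
        sc[i] = c0[2 * i] + c0[2 * i + 1] + c1[2 * i] + c1[2 * i + 1];
      }
    }
  }
  return dx;
}

// softmax over the trailing class axis of a (V, C) view
// [[Rcpp::export]]
NumericVector softmax_cpp(NumericVector z, int V, int C) {
  NumericVector p(no_init(z.size()));
  const double *zs = z.begin();
  double *ps = p.begin();
  for (int i = 0; i < V; ++i) {
    double m = zs[i];
    for (int c = 1; c < C; ++c) {
      double v = zs[(R_xlen_t)c * V + i];
      if (v > m) m = v;
    }
    double s = 0;
    for (int c = 0; c < C; ++c) {
      double e = std::exp(zs[(R_xlen_t)c * V + i] - m);
      ps[(R_xlen_t)c * V + i] = e;
      s += e;
    }
    for (int c = 0; c < C; ++c) ps[(R_xlen_t)c * V + i] /= s;
  }
  return p;
}

// chain rule through softmax: dz = p * (dp - sum_c dp*p)
// [[Rcpp::export]]
NumericVector softmax_bwd_cpp(NumericVector p, NumericVector dp, int V,
                              int C) {
  NumericVector dz(no_init(p.size()));
  const double *ps = p.begin();
  const double *ds = dp.begin();
  double *zs = dz.begin();
  for (int i = 0; i < V; ++i) {
    double s = 0;
    for (int c = 0; c < C; ++c) {
      s += ds[(R_xlen_t)c * V + i] * ps[(R_xlen_t)c * V + i];
    }
    for (int c = 0; c < C; ++c) {
      R_xlen_t k = (R_xlen_t)c * V + i;
      zs[k] = ps[k] * (ds[k] - s);
    }
  }
  return dz;
}

// in-place column-wise bias add on a (M, C) matrix freshly produced by GEMM
// [[Rcpp::export]]
NumericMatrix add_bias_cpp(NumericMatrix y, NumericVector b) {
  const int M = y.nrow(), C = y.ncol();
  double *ys = y.begin();
  for (int c = 0; c < C; ++c) {
    const double bc = b[c];
    if (bc == 0) continue;
    double *col = ys + (R_xlen_t)c * M;
    for (int i = 0; i < M; ++i) col[i] += bc;
  }
  return y;
}
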