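// Fused batch-norm (+ optional rectifier) kernels. Activations are
// [H, W, C, N] numeric arrays; all per-channel reductions and affine maps
// happen in one or two passes without R-level temporaries.

#include <Rcpp.h>

using namespace Rcpp;

static inline void dims4(const NumericVector &x, R_xlen_t &HW, int &C,
                         int &N) {
  IntegerVector d = x.attr("dim");
  HW = (R_xlen_t)d[0] * d[1];
  C = d[2];
  N = d[3];
}

// Per-channel mean and (biased) variance over H, W and N.
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x) {
  R_xlen_t HW; int C, N;
  dims4(x, HW, C, N);
  NumericVector mean(C), var(C);
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = xp + ((R_xlen_t)n * C + c) * HW;
      double s = 0, s2 = 0;
      for (R_xlen_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mean[c] += s;
      var[c] += s2;
    }
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    mean[c] /= m;
    var[c] = var[c] / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = gamma * (x - mu) * inv + beta, with optional rectifier; also returns
// the normalised activations xhat needed by the backward pass.
// [[Rcpp::export(name = ".bn_act_fwd")]]
List bn_act_fwd(NumericVector x, NumericVector mu, NumericVector inv,
                NumericVector gamma, NumericVector beta, bool relu,
                bool want_xhat) {
  R_xlen_t HW; int C, N;
  dims4(x, HW, C, N);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector xhat;
  if (want_xhat) {
    xhat = NumericVector(x.size());
    xhat.attr("dim") = x.attr("dim");
  }
  const double *xp = x.begin();
  double *yp = y.begin();
  double *hp = want_xhat ? xhat.begin() : (double *)0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double mc = mu[c], ic = inv[c], gc = gamma[c], bc = beta[c];
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double h = (xp[off + i] - mc) * ic;
        double v = gc * h + bc;
        if (relu && v < 0) v = 0;
        yp[off + i] = v;
        if (hp) hp[off + i] = h;
      }
    }
  if (want_xhat) return List::create(_["y"] = y, _["xhat"] = xhat);
  return List::create(_["y"] = y);
}

// Backward through (optional rectifier +) batch norm in training mode.
// `y` is the forward output (its zeros encode the rectifier mask).
// [[Rcpp::export(name = ".bn_act_bwd")]]
List bn_act_bwd(NumericVector dy, NumericVector y, NumericVector xhat,
                NumericVector gamma, NumericVector inv, bool relu) {
  R_xlen_t HW; int C, N;
  dims4(dy, HW, C, N);
  NumericVector dgamma(C), dbeta(C);
  const double *dyp = dy.begin(), *ypv = y.begin(), *hp = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      double sg = 0, sb = 0;
      for (R_xlen_t i = 0; i < HW; ++i) {
        double g = dyp[off + i];
        if (relu && ypv[off + i] <= 0) g = 0;
        sb += g;
        sg += g * hp[off + i];
      }
      dgamma[c] += sg;
      dbeta[c] += sb;
    }
  const double m = (double)HW * N;
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  double *dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double gc = gamma[c], ic = inv[c];
      const double mb = dbeta[c] / m, mg = dgamma[c] / m;
      for (R_xlen_t i = 0; i < HW; ++i) {
        double g = dyp[off + i];
        if (relu && ypv[off + i] <= 0) g = 0;
        dxp[off + i] = ic * gc * (g - mb - hp[off + i] * mg);
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Backward through (optional rectifier +) eval-mode batch norm: a fixed
// per-channel scale.
// [[Rcpp::export(name = ".bn_eval_bwd")]]
NumericVector bn_eval_bwd(NumericVector dy, NumericVector y,
                          NumericVector scale, bool relu) {
  R_xlen_t HW; int C, N;
  dims4(dy, HW, C, N);
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double *dyp = dy.begin(), *ypv = y.begin();
  double *dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double sc = scale[c];
      for (R_xlen_t i = 0; i < HW; ++i) {
        double g = dyp[off + i];
        if (relu && ypv[off + i] <= 0) g = 0;
        dxp[off + i] = sc * g;
      }
    }
  return dx;
}
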