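// Convolution primitives for the MFCN, implemented as im2col + GEMM on
// Armadillo matrices. Tensors cross the R boundary as numeric arrays in
// [H, W, C, N] layout (column-major, so h is the fastest index).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword out_size(arma::uword in, arma::uword k,
                                   arma::uword stride, arma::uword pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one sample into the im2col matrix: rows index (ki, kj, ci),
// columns index output pixels (oh fastest). Out-of-range taps read 0.
static void im2col(const double *x, arma::uword H, arma::uword W, arma::uword C,
                   arma::uword kh, arma::uword kw, arma::uword stride,
                   arma::uword pad, arma::mat &col) {
  const arma::uword Ho = out_size(H, kh, stride, pad);
  const arma::uword Wo = out_size(W, kw, stride, pad);
  col.zeros(kh * kw * C, Ho * Wo);
  for (arma::uword ci = 0; ci < C; ++ci) {
    const double *xc = x + ci * H * W;
    for (arma::uword kj = 0; kj < kw; ++kj) {
      for (arma::uword ki = 0; ki < kh; ++ki) {
        const arma::uword r = ki + kh * (kj + kw * ci);
        for (arma::uword ow = 0; ow < Wo; ++ow) {
          const long wj = (long)(ow * stride + kj) - (long)pad;
          if (wj < 0 || wj >= (long)W) continue;
          for (arma::uword oh = 0; oh < Ho; ++oh) {
            const long hi = (long)(oh * stride + ki) - (long)pad;
            if (hi < 0 || hi >= (long)H) continue;
            col(r, oh + Ho * ow) = xc[hi + H * wj];
          }
        }
      }
    }
  }
}

// Scatter-add the im2col gradient back onto the input raster.
static void col2im(const arma::mat &col, arma::uword H, arma::uword W,
                   arma::uword C, arma::uword kh, arma::uword kw,
                   arma::uword stride, arma::uword pad, double *dx) {
  const arma::uword Ho = out_size(H, kh, stride, pad);
  const arma::uword Wo = out_size(W, kw, stride, pad);
  for (arma::uword ci = 0; ci < C; ++ci) {
    double *dxc = dx + ci * H * W;
    for (arma::uword kj = 0; kj < kw; ++kj) {
      for (arma::uword ki = 0; ki < kh; ++ki) {
        const arma::uword r = ki + kh * (kj + kw * ci);
        for (arma::uword ow = 0; ow < Wo; ++ow) {
          const long wj = (long)(ow * stride + kj) - (long)pad;
          if (wj < 0 || wj >= (long)W) continue;
          for (arma::uword oh = 0; oh < Ho; ++oh) {
            const long hi = (long)(oh * stride + ki) - (long)pad;
            if (hi < 0 || hi >= (long)H) continue;
            dxc[hi + H * wj] += col(r, oh + Ho * ow);
          }
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector &w, arma::uword kh,
                               arma::uword kw, arma::uword Cin,
                               arma::uword Cout) {
  // W2 is Cout x (kh*kw*Cin); w is [kh, kw, Cin, Cout] column-major.
  arma::mat W2(Cout, kh * kw * Cin);
  const double *wp = w.begin();
  for (arma::uword co = 0; co < Cout; ++co)
    for (arma::uword r = 0; r < kh * kw * Cin; ++r)
      W2(co, r) = wp[r + kh * kw * Cin * co];
  return W2;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword kh = wd[0], kw = wd[1], Cout = wd[3];
  if ((arma::uword)wd[2] != C) stop("channel mismatch");
  const arma::uword Ho = out_size(H, kh, stride, pad);
  const arma::uword Wo = out_size(W, kw, stride, pad);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat W2 = weight_matrix(w, kh, kw, C, Cout);
  arma::vec bv(b.begin(), Cout);
  arma::mat col;
  for (arma::uword n = 0; n < N; ++n) {
    im2col(x.begin() + n * H * W * C, H, W, C, kh, kw, stride, pad, col);
    arma::mat Y = W2 * col;          // Cout x (Ho*Wo)
    Y.each_col() += bv;
    double *yp = y.begin() + n * Ho * Wo * Cout;
    for (arma::uword co = 0; co < Cout; ++co)
      for (arma::uword p = 0; p < Ho * Wo; ++p)
        yp[p + Ho * Wo * co] = Y(co, p);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword kh = wd[0], kw = wd[1], Cout = wd[3];
  const arma::uword Ho = yd[0], Wo = yd[1];
  arma::mat W2 = weight_matrix(w, kh, kw, C, Cout);
  arma::mat dW2(Cout, kh * kw * C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat col;
  for (arma::uword n = 0; n < N; ++n) {
    const double *dyp = dy.begin() + n * Ho * Wo * Cout;
    arma::mat dY(Cout, Ho * Wo);
    for (arma::uword co = 0; co < Cout; ++co)
      for (arma::uword p = 0; p < Ho * Wo; ++p)
        dY(co, p) = dyp[p + Ho * Wo * co];
    im2col(x.begin() + n * H * W * C, H, W, C, kh, kw, stride, pad, col);
    dW2 += dY * col.t();
    db += arma::sum(dY, 1);
    arma::mat dcol = W2.t() * dY;
    col2im(dcol, H, W, C, kh, kw, stride, pad,
           dx.begin() + n * H * W * C);
  }
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  for (arma::uword co = 0; co < Cout; ++co)
    for (arma::uword r = 0; r < kh * kw * C; ++r)
      dw[r + kh * kw * C * co] = dW2(co, r);
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution, kernel 2, stride 2: each input pixel expands to a
// 2x2 output block, so the output blocks partition the raster exactly.
// y(2i+di, 2j+dj, co) = b(co) + sum_ci w(di, dj, ci, co) * x(i, j, ci)

// [[Rcpp::export(name = ".tconv2_fwd")]]
NumericVector tconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword Cout = wd[3];
  NumericVector y(4 * H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  // Wm rows index (di, dj, co), columns index ci.
  arma::mat Wm(4 * Cout, C);
  for (arma::uword co = 0; co < Cout; ++co)
    for (arma::uword ci = 0; ci < C; ++ci)
      for (arma::uword dj = 0; dj < 2; ++dj)
        for (arma::uword di = 0; di < 2; ++di)
          Wm(di + 2 * dj + 4 * co, ci) = w[di + 2 * (dj + 2 * (ci + C * co))];
  for (arma::uword n = 0; n < N; ++n) {
    arma::mat X((double *)x.begin() + n * H * W * C, H * W, C, false);
    arma::mat Y = Wm * X.t();        // (4*Cout) x (H*W)
    double *yp = y.begin() + n * 4 * H * W * Cout;
    for (arma::uword co = 0; co < Cout; ++co) {
      double *yc = yp + co * 4 * H * W;
      const double bias = b[co];
      for (arma::uword j = 0; j < W; ++j)
        for (arma::uword i = 0; i < H; ++i) {
          const arma::uword p = i + H * j;
          yc[(2 * i) + 2 * H * (2 * j)] = Y(0 + 4 * co, p) + bias;
          yc[(2 * i + 1) + 2 * H * (2 * j)] = Y(1 + 4 * co, p) + bias;
          yc[(2 * i) + 2 * H * (2 * j + 1)] = Y(2 + 4 * co, p) + bias;
          yc[(2 * i + 1) + 2 * H * (2 * j + 1)] = Y(3 + 4 * co, p) + bias;
        }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv2_bwd")]]
List tconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword Cout = wd[3];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat Wm(4 * Cout, C);
  for (arma::uword co = 0; co < Cout; ++co)
    for (arma::uword ci = 0; ci < C; ++ci)
      for (arma::uword dj = 0; dj < 2; ++dj)
        for (arma::uword di = 0; di < 2; ++di)
          Wm(di + 2 * dj + 4 * co, ci) = w[di + 2 * (dj + 2 * (ci + C * co))];
  arma::mat dWm(4 * Cout, C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n) {
    const double *dyp = dy.begin() + n * 4 * H * W * Cout;
    arma::mat dYm(4 * Cout, H * W);
    for (arma::uword co = 0; co < Cout; ++co) {
      const double *dyc = dyp + co * 4 * H * W;
      double s = 0.0;
      for (arma::uword j = 0; j < W; ++j)
        for (arma::uword i = 0; i < H; ++i) {
          const arma::uword p = i + H * j;
          dYm(0 + 4 * co, p) = dyc[(2 * i) + 2 * H * (2 * j)];
          dYm(1 + 4 * co, p) = dyc[(2 * i + 1) + 2 * H * (2 * j)];
          dYm(2 + 4 * co, p) = dyc[(2 * i) + 2 * H * (2 * j + 1)];
          dYm(3 + 4 * co, p) = dyc[(2 * i + 1) + 2 * H * (2 * j + 1)];
          s += dYm(0 + 4 * co, p) + dYm(1 + 4 * co, p) +
               dYm(2 + 4 * co, p) + dYm(3 + 4 * co, p);
        }
      db(co) += s;
    }
    arma::mat X((double *)x.begin() + n * H * W * C, H * W, C, false);
    dWm += dYm * X;                  // (4*Cout) x C
    // dx(i,j,ci) = sum_{di,dj,co} w(di,dj,ci,co) dy(2i+di, 2j+dj, co)
    //            = sum_r Wm(r, ci) dYm(r, p)
    arma::mat dXm = Wm.t() * dYm;    // C x (H*W)
    double *dxp = dx.begin() + n * H * W * C;
    for (arma::uword ci = 0; ci < C; ++ci)
      for (arma::uword p = 0; p < H * W; ++p)
        dxp[p + H * W * ci] += dXm(ci, p);
  }
  for (arma::uword co = 0; co < Cout; ++co)
    for (arma::uword ci = 0; ci < C; ++ci)
      for (arma::uword dj = 0; dj < 2; ++dj)
        for (arma::uword di = 0; di < 2; ++di)
          dw[di + 2 * (dj + 2 * (ci + C * co))] = dWm(di + 2 * dj + 4 * co, ci);
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
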