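// Batched 2-D convolution via im2col + GEMM, with the matching backward
// pass (col2im).  Tensors cross the R/C++ boundary as dense double arrays
// with dim = c(H, W, C, N); kernels as c(kh, kw, Cin, Cout).  Zero padding,
// arbitrary stride.  The patch matrix is kept transposed — (Ho*Wo*N) x K —
// so both the scatter/gather loops and the GEMM outputs walk contiguous
// memory.  These two kernels carry essentially all of the training FLOPs;
// everything else in the network is cheap elementwise R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Shape {
  int H, W, C, N, KH, KW, Cout, Ho, Wo;
};

Shape infer_shape(const Rcpp::NumericVector &x, const Rcpp::NumericVector &w,
                  int stride, int pad) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 4) Rcpp::stop("input must be a 4-d array (H, W, C, N)");
  if (wd.size() != 4) Rcpp::stop("kernel must be a 4-d array (kh, kw, cin, cout)");
  Shape s;
  s.H = xd[0]; s.W = xd[1]; s.C = xd[2]; s.N = xd[3];
  s.KH = wd[0]; s.KW = wd[1]; s.Cout = wd[3];
  if (wd[2] != s.C) Rcpp::stop("kernel expects %d input channels, got %d", wd[2], s.C);
  s.Ho = (s.H + 2 * pad - s.KH) / stride + 1;
  s.Wo = (s.W + 2 * pad - s.KW) / stride + 1;
  if (s.Ho < 1 || s.Wo < 1) Rcpp::stop("kernel larger than padded input");
  return s;
}

// colsT(j, r): row j = ho + Ho*(wo + Wo*n), column r = ki + KH*(kj + KW*c)
void im2colT(const double *x, const Shape &s, int stride, int pad, mat &colsT) {
  const uword J = (uword)s.Ho * s.Wo * s.N;
  colsT.zeros(J, (uword)s.KH * s.KW * s.C);
  for (int c = 0; c < s.C; ++c)
    for (int kj = 0; kj < s.KW; ++kj)
      for (int ki = 0; ki < s.KH; ++ki) {
        double *col = colsT.colptr(ki + s.KH * (kj + s.KW * c));
        for (int n = 0; n < s.N; ++n) {
          const double *xc = x + s.H * ((size_t)s.W * (c + (size_t)s.C * n));
          for (int wo = 0; wo < s.Wo; ++wo) {
            const int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= s.W) continue;
            const double *src = xc + (size_t)wi * s.H;
            double *dst = col + (uword)s.Ho * (wo + (uword)s.Wo * n);
            for (int ho = 0; ho < s.Ho; ++ho) {
              const int hi = ho * stride + ki - pad;
              if (hi >= 0 && hi < s.H) dst[ho] = src[hi];
            }
          }
        }
      }
}

void col2imT(const mat &colsT, const Shape &s, int stride, int pad, double *dx) {
  for (int c = 0; c < s.C; ++c)
    for (int kj = 0; kj < s.KW; ++kj)
      for (int ki = 0; ki < s.KH; ++ki) {
        const double *col = colsT.colptr(ki + s.KH * (kj + s.KW * c));
        for (int n = 0; n < s.N; ++n) {
          double *xc = dx + s.H * ((size_t)s.W * (c + (size_t)s.C * n));
          for (int wo = 0; wo < s.Wo; ++wo) {
            const int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= s.W) continue;
            const double *src = col + (uword)s.Ho * (wo + (uword)s.Wo * n);
            double *dst = xc + (size_t)wi * s.H;
            for (int ho = 0; ho < s.Ho; ++ho) {
              const int hi = ho * stride + ki - pad;
              if (hi >= 0 && hi < s.H) dst[hi] += src[ho];
            }
          }
        }
      }
}

// kernel array (kh, kw, cin, cout) -> (K x Cout) GEMM matrix whose row
// order matches colsT's column order
mat kernel_matrixT(const Rcpp::NumericVector &w, const Shape &s) {
  const uword K = (uword)s.KH * s.KW * s.C;
  mat wmT(K, s.Cout);
  const double *wp = w.begin();
  for (int co = 0; co < s.Cout; ++co)
    for (int c = 0; c < s.C; ++c)
      for (int kj = 0; kj < s.KW; ++kj)
        for (int ki = 0; ki < s.KH; ++ki)
          wmT(ki + s.KH * (kj + s.KW * c), co) =
              wp[ki + (size_t)s.KH * (kj + (size_t)s.KW * (c + (size_t)s.C * co))];
  return wmT;
}

} // namespace

// [[Rcpp::export(name = ".conv2d_fw_cpp")]]
Rcpp::NumericVector conv2d_fw_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                  Rcpp::NumericVector bias, int stride, int pad) {
  Shape s = infer_shape(x, w, stride, pad);
  if (bias.size() != s.Cout) Rcpp::stop("bias length must equal output channels");
  mat colsT;
  im2colT(x.begin(), s, stride, pad, colsT);
  mat wmT = kernel_matrixT(w, s);
  mat y2T = colsT * wmT; // (Ho*Wo*N x Cout)

  Rcpp::NumericVector y((R_xlen_t)s.Ho * s.Wo * s.Cout * s.N);
  y.attr("dim") = Rcpp::IntegerVector::create(s.Ho, s.Wo, s.Cout, s.N);
  double *yp = y.begin();
  const uword plane = (uword)s.Ho * s.Wo;
  for (int co = 0; co < s.Cout; ++co) {
    const double b = bias[co];
    const double *src = y2T.colptr(co);
    for (int n = 0; n < s.N; ++n) {
      double *dst = yp + plane * (co + (uword)s.Cout * n);
      const double *sp = src + plane * n;
      for (uword p = 0; p < plane; ++p) dst[p] = sp[p] + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw_cpp")]]
Rcpp::List conv2d_bw_cpp(Rcpp::NumericVector x, Rcpp::NumericVector w,
                         Rcpp::NumericVector dy, int stride, int pad) {
  Shape s = infer_shape(x, w, stride, pad);
  Rcpp::IntegerVector dyd = dy.attr("dim");
  if (dyd.size() != 4 || dyd[0] != s.Ho || dyd[1] != s.Wo ||
      dyd[2] != s.Cout || dyd[3] != s.N)
    Rcpp::stop("gradient shape does not match convolution output");

  const uword plane = (uword)s.Ho * s.Wo;
  const uword J = plane * s.N;
  mat dy2T(J, s.Cout);
  const double *dyp = dy.begin();
  for (int co = 0; co < s.Cout; ++co) {
    double *dst = dy2T.colptr(co);
    for (int n = 0; n < s.N; ++n) {
      const double *src = dyp + plane * (co + (uword)s.Cout * n);
      double *dp = dst + plane * n;
      for (uword p = 0; p < plane; ++p) dp[p] = src[p];
    }
  }

  mat colsT;
  im2colT(x.begin(), s, stride, pad, colsT);
  mat wmT = kernel_matrixT(w, s);

  mat dwmT = colsT.t() * dy2T;   // (K x Cout)
  rowvec db = sum(dy2T, 0);      // (Cout)
  mat dcolsT = dy2T * wmT.t();   // (J x K)

  Rcpp::NumericVector dx((R_xlen_t)s.H * s.W * s.C * s.N);
  dx.attr("dim") = Rcpp::IntegerVector::create(s.H, s.W, s.C, s.N);
  col2imT(dcolsT, s, stride, pad, dx.begin());

  Rcpp::NumericVector dw((R_xlen_t)s.KH * s.KW * s.C * s.Cout);
  dw.attr("dim") = Rcpp::IntegerVector::create(s.KH, s.KW, s.C, s.Cout);
  double *dwp = dw.begin();
  for (int co = 0; co < s.Cout; ++co)
    for (int c = 0; c < s.C; ++c)
      for (int kj = 0; kj < s.KW; ++kj)
        for (int ki = 0; ki < s.KH; ++ki)
          dwp[ki + (size_t)s.KH * (kj + (size_t)s.KW * (c + (size_t)s.C * co))] =
              dwmT(ki + s.KH * (kj + s.KW * c), co);

  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}
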