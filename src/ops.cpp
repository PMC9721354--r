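// Low-level numeric kernels: 2-D convolution (im2col + BLAS gemm), transposed
// convolution, separable image/volume resampling. Tensor layout throughout is
// the R column-major array [H, W, C, N]; convolution weights are [kh, kw, Cin,
// Cout] and transposed-convolution weights [kh, kw, Cout, Cin], so that the
// natural R reshape of each weight array is already the gemm operand.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims_of(const NumericVector& x) {
  RObject d = x.attr("dim");
  if (d.isNULL()) stop("input must be a dim-ed array");
  return as<IntegerVector>(d);
}

// colsT is (L x K), L = Ho*Wo, K = kh*kw*Ci; column r = (ki, kj, ci) holds the
// input values seen by kernel tap (ki,kj) of channel ci at every output site.
// Templated over the scalar type: training convolutions run in single
// precision (the gemm dominates), metric/filter convolutions in double.
template <typename T, typename S>
static void im2col_T(const S* xs, int H, int W, int Ci,
                     int kh, int kw, int stride, int pad,
                     int Ho, int Wo, arma::Mat<T>& colsT,
                     size_t row_off = 0) {
  for (int ci = 0; ci < Ci; ++ci) {
    const S* xc = xs + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        T* col = colsT.colptr(r) + row_off;
        // valid output rows: 0 <= ho*stride - pad + ki < H (care: C++
        // integer division truncates toward zero, so guard negatives)
        int ho_lo = pad - ki <= 0 ? 0 : (pad - ki + stride - 1) / stride;
        int ho_hi = H - 1 + pad - ki < 0 ? -1 : (H - 1 + pad - ki) / stride;
        if (ho_hi > Ho - 1) ho_hi = Ho - 1;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          T* dst = col + (size_t)wo * Ho;
          if (w < 0 || w >= W) {
            std::fill(dst, dst + Ho, (T)0);
            continue;
          }
          const S* src = xc + (size_t)w * H;
          for (int ho = 0; ho < ho_lo; ++ho) dst[ho] = (T)0;
          if (stride == 1) {
            const S* s0 = src + ho_lo - pad + ki;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) dst[ho] = (T)s0[ho - ho_lo];
          } else {
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              dst[ho] = (T)src[ho * stride - pad + ki];
          }
          for (int ho = ho_hi + 1; ho < Ho; ++ho) dst[ho] = (T)0;
        }
      }
    }
  }
}

// adjoint of im2col_T: scatter-add columns back into the (H,W,Ci) image
template <typename T, typename S>
static void col2im_add(const arma::Mat<T>& colsT, int H, int W, int Ci,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, S* xs, size_t row_off = 0) {
  for (int ci = 0; ci < Ci; ++ci) {
    S* xc = xs + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        const T* col = colsT.colptr(r) + row_off;
        int ho_lo = pad - ki <= 0 ? 0 : (pad - ki + stride - 1) / stride;
        int ho_hi = H - 1 + pad - ki < 0 ? -1 : (H - 1 + pad - ki) / stride;
        if (ho_hi > Ho - 1) ho_hi = Ho - 1;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          S* dst = xc + (size_t)w * H;
          const T* src = col + (size_t)wo * Ho;
          if (stride == 1) {
            S* d0 = dst + ho_lo - pad + ki;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) d0[ho - ho_lo] += (S)src[ho];
          } else {
            for (int ho = ho_lo; ho <= ho_hi; ++ho)
              dst[ho * stride - pad + ki] += (S)src[ho];
          }
        }
      }
    }
  }
}

template <typename T>
static arma::Mat<T> load_mat(const double* p, int nr, int nc) {
  arma::Mat<T> m(nr, nc);
  T* dst = m.memptr();
  const size_t n = (size_t)nr * nc;
  for (size_t i = 0; i < n; ++i) dst[i] = (T)p[i];
  return m;
}

template <typename T>
static void conv2d_fw_impl(const double* x, const double* w, const double* b,
                           int stride, int pad, int H, int W, int Ci, int N,
                           int kh, int kw, int Co, int Ho, int Wo, double* y,
                           double act_slope) {
  const int L = Ho * Wo, K = kh * kw * Ci;
  const bool one_by_one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::Mat<T> Wm = load_mat<T>(w, K, Co);
  // one im2col block per sample stacked into a single (L*N x K) gemm operand
  arma::Mat<T> colsT((size_t)L * N, K), Ym;
  if (one_by_one) {
    for (int n = 0; n < N; ++n)
      for (int ci = 0; ci < Ci; ++ci) {
        const double* src = x + (size_t)n * L * Ci + (size_t)ci * L;
        T* dst = colsT.colptr(ci) + (size_t)n * L;
        for (int i = 0; i < L; ++i) dst[i] = (T)src[i];
      }
  } else {
    for (int n = 0; n < N; ++n)
      im2col_T<T>(x + (size_t)n * H * W * Ci, H, W, Ci, kh, kw, stride, pad,
                  Ho, Wo, colsT, (size_t)n * L);
  }
  Ym = colsT * Wm;                       // (L*N x Co)
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const T* src = Ym.colptr(co) + (size_t)n * L;
      double* dst = y + (size_t)n * L * Co + (size_t)co * L;
      const double add = b[co];
      if (ISNA(act_slope)) {
        for (int i = 0; i < L; ++i) dst[i] = (double)src[i] + add;
      } else {
        for (int i = 0; i < L; ++i) {
          const double v = (double)src[i] + add;
          dst[i] = v > 0 ? v : act_slope * v;
        }
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, bool single = false,
                            double act_slope = NA_REAL) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[3];
  if (dw[2] != Ci) stop("channel mismatch: input has %d, kernel expects %d", Ci, dw[2]);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  if (single)
    conv2d_fw_impl<float>(x.begin(), w.begin(), b.begin(), stride, pad,
                          H, W, Ci, N, kh, kw, Co, Ho, Wo, y.begin(),
                          act_slope);
  else
    conv2d_fw_impl<double>(x.begin(), w.begin(), b.begin(), stride, pad,
                           H, W, Ci, N, kh, kw, Co, Ho, Wo, y.begin(),
                           act_slope);
  return y;
}

template <typename T>
static void conv2d_bw_impl(const double* x, const double* w, const double* gy,
                           int stride, int pad, int H, int W, int Ci, int N,
                           int kh, int kw, int Co, int Ho, int Wo,
                           double* gx, double* gw, double* gb,
                           double act_slope, const double* yact) {
  const int L = Ho * Wo, K = kh * kw * Ci;
  const bool one_by_one = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::Mat<T> Wm = load_mat<T>(w, K, Co);
  arma::Mat<T> colsT((size_t)L * N, K), Gym((size_t)L * N, Co);
  for (int n = 0; n < N; ++n) {
    if (one_by_one) {
      for (int ci = 0; ci < Ci; ++ci) {
        const double* src = x + (size_t)n * L * Ci + (size_t)ci * L;
        T* dst = colsT.colptr(ci) + (size_t)n * L;
        for (int i = 0; i < L; ++i) dst[i] = (T)src[i];
      }
    } else {
      im2col_T<T>(x + (size_t)n * H * W * Ci, H, W, Ci, kh, kw, stride, pad,
                  Ho, Wo, colsT, (size_t)n * L);
    }
    for (int co = 0; co < Co; ++co) {
      const size_t off = (size_t)n * L * Co + (size_t)co * L;
      const double* src = gy + off;
      T* dst = Gym.colptr(co) + (size_t)n * L;
      if (yact == nullptr) {
        for (int i = 0; i < L; ++i) dst[i] = (T)src[i];
      } else {
        const double* ya = yact + off;
        for (int i = 0; i < L; ++i)
          dst[i] = (T)(ya[i] > 0 ? src[i] : act_slope * src[i]);
      }
    }
  }
  arma::Mat<T> gWm = colsT.t() * Gym;
  arma::Mat<T> gcols = Gym * Wm.t();     // (L*N x K)
  if (one_by_one) {
    for (int n = 0; n < N; ++n)
      for (int ci = 0; ci < Ci; ++ci) {
        const T* src = gcols.colptr(ci) + (size_t)n * L;
        double* dst = gx + (size_t)n * L * Ci + (size_t)ci * L;
        for (int i = 0; i < L; ++i) dst[i] = (double)src[i];
      }
  } else {
    for (int n = 0; n < N; ++n)
      col2im_add<T>(gcols, H, W, Ci, kh, kw, stride, pad, Ho, Wo,
                    gx + (size_t)n * H * W * Ci, (size_t)n * L);
  }
  const T* p = gWm.memptr();
  for (size_t i = 0; i < (size_t)K * Co; ++i) gw[i] = (double)p[i];
  arma::Row<T> gB = arma::sum(Gym, 0);
  for (int c = 0; c < Co; ++c) gb[c] = (double)gB[c];
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad, bool single = false,
                   double act_slope = NA_REAL,
                   Nullable<NumericVector> y_out = R_NilValue) {
  IntegerVector dx = dims_of(x), dw = dims_of(w), dg = dims_of(gy);
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[3];
  const int Ho = dg[0], Wo = dg[1];
  NumericVector gx((size_t)H * W * Ci * N), gw(w.size()), gb(Co);
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  const double* yact = nullptr;
  NumericVector yv;
  if (y_out.isNotNull() && !ISNA(act_slope)) {
    yv = NumericVector(y_out);
    yact = yv.begin();
  }
  if (single)
    conv2d_bw_impl<float>(x.begin(), w.begin(), gy.begin(), stride, pad,
                          H, W, Ci, N, kh, kw, Co, Ho, Wo,
                          gx.begin(), gw.begin(), gb.begin(), act_slope, yact);
  else
    conv2d_bw_impl<double>(x.begin(), w.begin(), gy.begin(), stride, pad,
                           H, W, Ci, N, kh, kw, Co, Ho, Wo,
                           gx.begin(), gw.begin(), gb.begin(), act_slope, yact);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

template <typename T>
static void convt2d_fw_impl(const double* x, const double* w, const double* b,
                            int stride, int H, int W, int Ci, int N,
                            int kh, int kw, int Co, int Ho, int Wo, double* y) {
  const int L0 = H * W, K = kh * kw * Co;
  arma::Mat<T> Wm = load_mat<T>(w, K, Ci);
  arma::Mat<T> Xm((size_t)L0 * N, Ci);
  for (int n = 0; n < N; ++n)
    for (int ci = 0; ci < Ci; ++ci) {
      const double* src = x + (size_t)n * L0 * Ci + (size_t)ci * L0;
      T* dst = Xm.colptr(ci) + (size_t)n * L0;
      for (int i = 0; i < L0; ++i) dst[i] = (T)src[i];
    }
  arma::Mat<T> colsT = Xm * Wm.t();      // (L0*N x K)
  std::vector<T> ybuf((size_t)Ho * Wo * Co);
  for (int n = 0; n < N; ++n) {
    std::fill(ybuf.begin(), ybuf.end(), (T)0);
    col2im_add<T>(colsT, Ho, Wo, Co, kh, kw, stride, 0, H, W, ybuf.data(),
                  (size_t)n * L0);
    double* ys = y + (size_t)n * Ho * Wo * Co;
    for (int co = 0; co < Co; ++co) {
      const double add = b[co];
      const T* src = ybuf.data() + (size_t)co * Ho * Wo;
      double* dst = ys + (size_t)co * Ho * Wo;
      for (int i = 0; i < Ho * Wo; ++i) dst[i] = (double)src[i] + add;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_convt2d_fw(NumericVector x, NumericVector w, NumericVector b,
                             int stride, bool single = false) {
  IntegerVector dx = dims_of(x), dw = dims_of(w);
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[2];
  if (dw[3] != Ci) stop("channel mismatch in transposed convolution");
  const int Ho = (H - 1) * stride + kh;
  const int Wo = (W - 1) * stride + kw;
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  if (single)
    convt2d_fw_impl<float>(x.begin(), w.begin(), b.begin(), stride,
                           H, W, Ci, N, kh, kw, Co, Ho, Wo, y.begin());
  else
    convt2d_fw_impl<double>(x.begin(), w.begin(), b.begin(), stride,
                            H, W, Ci, N, kh, kw, Co, Ho, Wo, y.begin());
  return y;
}

template <typename T>
static void convt2d_bw_impl(const double* x, const double* w, const double* gy,
                            int stride, int H, int W, int Ci, int N,
                            int kh, int kw, int Co, int Ho, int Wo,
                            double* gx, double* gw, double* gb) {
  const int L0 = H * W, K = kh * kw * Co;
  arma::Mat<T> Wm = load_mat<T>(w, K, Ci);
  arma::Mat<T> colsT((size_t)L0 * N, K), Xm((size_t)L0 * N, Ci);
  for (int n = 0; n < N; ++n) {
    const double* gys = gy + (size_t)n * Ho * Wo * Co;
    im2col_T<T>(gys, Ho, Wo, Co, kh, kw, stride, 0, H, W, colsT,
                (size_t)n * L0);
    for (int ci = 0; ci < Ci; ++ci) {
      const double* src = x + (size_t)n * L0 * Ci + (size_t)ci * L0;
      T* dst = Xm.colptr(ci) + (size_t)n * L0;
      for (int i = 0; i < L0; ++i) dst[i] = (T)src[i];
    }
    for (int co = 0; co < Co; ++co) {
      const double* gc = gys + (size_t)co * Ho * Wo;
      double s = 0.0;
      for (int i = 0; i < Ho * Wo; ++i) s += gc[i];
      gb[co] += s;
    }
  }
  arma::Mat<T> Gxm = colsT * Wm;         // (L0*N x Ci)
  arma::Mat<T> gWm = colsT.t() * Xm;
  for (int n = 0; n < N; ++n)
    for (int ci = 0; ci < Ci; ++ci) {
      const T* src = Gxm.colptr(ci) + (size_t)n * L0;
      double* dst = gx + (size_t)n * L0 * Ci + (size_t)ci * L0;
      for (int i = 0; i < L0; ++i) dst[i] = (double)src[i];
    }
  const T* p = gWm.memptr();
  for (size_t i = 0; i < (size_t)K * Ci; ++i) gw[i] = (double)p[i];
}

// [[Rcpp::export]]
List cpp_convt2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, bool single = false) {
  IntegerVector dx = dims_of(x), dw = dims_of(w), dg = dims_of(gy);
  const int H = dx[0], W = dx[1], Ci = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[2];
  const int Ho = dg[0], Wo = dg[1];
  NumericVector gx((size_t)H * W * Ci * N), gw(w.size()), gb(Co);
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  if (single)
    convt2d_bw_impl<float>(x.begin(), w.begin(), gy.begin(), stride,
                           H, W, Ci, N, kh, kw, Co, Ho, Wo,
                           gx.begin(), gw.begin(), gb.begin());
  else
    convt2d_bw_impl<double>(x.begin(), w.begin(), gy.begin(), stride,
                            H, W, Ci, N, kh, kw, Co, Ho, Wo,
                            gx.begin(), gw.begin(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// leaky rectifier forward; slope = 0 gives a plain rectifier
// [[Rcpp::export]]
NumericVector cpp_leaky_fw(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  return y;
}

// backward through the rectifier given its output y (y > 0 iff x > 0)
// [[Rcpp::export]]
NumericVector cpp_leaky_bw(NumericVector y, NumericVector g, double slope) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  const double* yp = y.begin();
  const double* gp = g.begin();
  double* op = gx.begin();
  const size_t n = g.size();
  for (size_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? gp[i] : slope * gp[i];
  return gx;
}

// batched matrix multiply with optional operand transposes (applied to the
// stored [rows, cols, N] slabs): op(A) [M,K] x op(B) [K,P] -> [M,P,N]
// [[Rcpp::export]]
NumericVector cpp_bmm(NumericVector a, NumericVector b,
                      bool ta = false, bool tb = false) {
  IntegerVector da = dims_of(a), db = dims_of(b);
  const int N = da[2];
  const int M = ta ? da[1] : da[0];
  const int K = ta ? da[0] : da[1];
  const int P = tb ? db[0] : db[1];
  if ((tb ? db[1] : db[0]) != K || db[2] != N) stop("bmm shape mismatch");
  NumericVector y((size_t)M * P * N);
  y.attr("dim") = IntegerVector::create(M, P, N);
  arma::fmat Af(da[0], da[1]), Bf(db[0], db[1]), Yf;
  for (int n = 0; n < N; ++n) {
    const double* ap = a.begin() + (size_t)n * da[0] * da[1];
    const double* bp = b.begin() + (size_t)n * db[0] * db[1];
    float* afp = Af.memptr();
    for (size_t i = 0; i < (size_t)da[0] * da[1]; ++i) afp[i] = (float)ap[i];
    float* bfp = Bf.memptr();
    for (size_t i = 0; i < (size_t)db[0] * db[1]; ++i) bfp[i] = (float)bp[i];
    if (ta && tb) Yf = Af.t() * Bf.t();
    else if (ta) Yf = Af.t() * Bf;
    else if (tb) Yf = Af * Bf.t();
    else Yf = Af * Bf;
    double* yp = y.begin() + (size_t)n * M * P;
    const float* sp = Yf.memptr();
    for (size_t i = 0; i < (size_t)M * P; ++i) yp[i] = (double)sp[i];
  }
  return y;
}

// channel concatenation of [H,W,Ca,N] and [H,W,Cb,N]
// [[Rcpp::export]]
NumericVector cpp_concat_ch(NumericVector a, NumericVector b) {
  IntegerVector da = dims_of(a), db = dims_of(b);
  const size_t hw = (size_t)da[0] * da[1];
  const int Ca = da[2], Cb = db[2], N = da[3];
  NumericVector y(hw * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(da[0], da[1], Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + hw * Ca * n, a.begin() + hw * Ca * (n + 1),
              y.begin() + hw * (Ca + Cb) * n);
    std::copy(b.begin() + hw * Cb * n, b.begin() + hw * Cb * (n + 1),
              y.begin() + hw * (Ca + Cb) * n + hw * Ca);
  }
  return y;
}

// split gradient of a channel concatenation back into the two parts
// [[Rcpp::export]]
List cpp_split_ch(NumericVector g, int Ca, int Cb) {
  IntegerVector d = dims_of(g);
  const size_t hw = (size_t)d[0] * d[1];
  const int N = d[3];
  NumericVector ga(hw * Ca * N), gb(hw * Cb * N);
  ga.attr("dim") = IntegerVector::create(d[0], d[1], Ca, N);
  gb.attr("dim") = IntegerVector::create(d[0], d[1], Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(g.begin() + hw * (Ca + Cb) * n,
              g.begin() + hw * (Ca + Cb) * n + hw * Ca,
              ga.begin() + hw * Ca * n);
    std::copy(g.begin() + hw * (Ca + Cb) * n + hw * Ca,
              g.begin() + hw * (Ca + Cb) * (n + 1),
              gb.begin() + hw * Cb * n);
  }
  return List::create(_["ga"] = ga, _["gb"] = gb);
}

// row-wise softmax over the second dimension of [M,P,N]
// [[Rcpp::export]]
NumericVector cpp_softmax_rows(NumericVector x) {
  IntegerVector d = dims_of(x);
  const int M = d[0], P = d[1], N = d[2];
  NumericVector y(x.size());
  y.attr("dim") = d;
  std::vector<double> mx(M), sm(M);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * M * P;
    double* yp = y.begin() + (size_t)n * M * P;
    std::fill(mx.begin(), mx.end(), -1e300);
    for (int p = 0; p < P; ++p)
      for (int m = 0; m < M; ++m) {
        const double v = xp[(size_t)p * M + m];
        if (v > mx[m]) mx[m] = v;
      }
    std::fill(sm.begin(), sm.end(), 0.0);
    for (int p = 0; p < P; ++p)
      for (int m = 0; m < M; ++m) {
        const double e = std::exp(xp[(size_t)p * M + m] - mx[m]);
        yp[(size_t)p * M + m] = e;
        sm[m] += e;
      }
    for (int p = 0; p < P; ++p)
      for (int m = 0; m < M; ++m) yp[(size_t)p * M + m] /= sm[m];
  }
  return y;
}

// y[h,w,c,n] = x[h,w,c,n] * a[c] + b[c]  (channel-wise affine)
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector d = dims_of(x);
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const size_t off = hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) yp[off + i] = xp[off + i] * ac + bc;
    }
  return y;
}

// per-channel sum of x*y (y may be R_NilValue for plain sums)
// [[Rcpp::export]]
NumericVector cpp_chan_dot(NumericVector x, Nullable<NumericVector> y) {
  IntegerVector d = dims_of(x);
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(C);
  const double* xp = x.begin();
  if (y.isNotNull()) {
    NumericVector yy(y);
    const double* yp = yy.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const size_t off = hw * (c + (size_t)C * n);
        double s = 0.0;
        for (size_t i = 0; i < hw; ++i) s += xp[off + i] * yp[off + i];
        out[c] += s;
      }
  } else {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        const size_t off = hw * (c + (size_t)C * n);
        double s = 0.0;
        for (size_t i = 0; i < hw; ++i) s += xp[off + i];
        out[c] += s;
      }
  }
  return out;
}

// Keys cubic-convolution kernel (a = -0.5): interpolating, reproduces
// constants and linear ramps exactly.
static inline double keys(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

struct Taps {
  std::vector<int> idx;     // 4 (cubic), 2 (linear) or 1 (nearest) per output
  std::vector<double> wgt;
  int ntap;
};

// voxel-center aligned source coordinates; border indices clamped
static Taps axis_taps(int n_in, int n_out, double scale, const std::string& method) {
  Taps t;
  t.ntap = method == "cubic" ? 4 : (method == "linear" ? 2 : 1);
  t.idx.resize((size_t)n_out * t.ntap);
  t.wgt.resize((size_t)n_out * t.ntap);
  for (int i = 0; i < n_out; ++i) {
    double u = (i + 0.5) * scale - 0.5;  // continuous source index
    if (t.ntap == 1) {
      int j = (int)std::lround(u);
      t.idx[i] = std::min(std::max(j, 0), n_in - 1);
      t.wgt[i] = 1.0;
      continue;
    }
    int base = (int)std::floor(u);
    double f = u - base;
    if (t.ntap == 2) {
      int j0 = std::min(std::max(base, 0), n_in - 1);
      int j1 = std::min(std::max(base + 1, 0), n_in - 1);
      t.idx[(size_t)i * 2] = j0;     t.wgt[(size_t)i * 2] = 1.0 - f;
      t.idx[(size_t)i * 2 + 1] = j1; t.wgt[(size_t)i * 2 + 1] = f;
    } else {
      for (int k = 0; k < 4; ++k) {
        int j = base - 1 + k;
        t.idx[(size_t)i * 4 + k] = std::min(std::max(j, 0), n_in - 1);
        t.wgt[(size_t)i * 4 + k] = keys(f - (k - 1));
      }
    }
  }
  return t;
}

// resample one axis (the first) of a conceptually 2-D view (n_in x rest)
static std::vector<double> pass1d(const std::vector<double>& v, int n_in,
                                  size_t rest, const Taps& t, int n_out) {
  std::vector<double> out((size_t)n_out * rest);
  for (size_t r = 0; r < rest; ++r) {
    const double* src = v.data() + r * n_in;
    double* dst = out.data() + r * n_out;
    for (int i = 0; i < n_out; ++i) {
      double acc = 0.0;
      for (int k = 0; k < t.ntap; ++k)
        acc += t.wgt[(size_t)i * t.ntap + k] * src[t.idx[(size_t)i * t.ntap + k]];
      dst[i] = acc;
    }
  }
  return out;
}

// cyclic transpose (a,b,c) -> (b,c,a) so each pass works on the leading axis
static std::vector<double> rot3(const std::vector<double>& v, int a, int b, int c) {
  std::vector<double> out(v.size());
  for (int k = 0; k < c; ++k)
    for (int j = 0; j < b; ++j)
      for (int i = 0; i < a; ++i)
        out[(size_t)j + (size_t)b * (k + (size_t)c * i)] =
            v[(size_t)i + (size_t)a * (j + (size_t)b * k)];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, NumericVector spacing,
                             double target, std::string method) {
  IntegerVector d = dims_of(vol);
  int n1 = d[0], n2 = d[1], n3 = d[2];
  int o1 = std::max(1, (int)std::lround(n1 * spacing[0] / target));
  int o2 = std::max(1, (int)std::lround(n2 * spacing[1] / target));
  int o3 = std::max(1, (int)std::lround(n3 * spacing[2] / target));
  std::vector<double> buf(vol.begin(), vol.end());
  // pass along axis 1, then rotate so axes 2 and 3 take the lead in turn
  buf = pass1d(buf, n1, (size_t)n2 * n3,
               axis_taps(n1, o1, (double)n1 / o1, method), o1);
  buf = rot3(buf, o1, n2, n3);
  buf = pass1d(buf, n2, (size_t)n3 * o1,
               axis_taps(n2, o2, (double)n2 / o2, method), o2);
  buf = rot3(buf, o2, n3, o1);
  buf = pass1d(buf, n3, (size_t)o1 * o2,
               axis_taps(n3, o3, (double)n3 / o3, method), o3);
  buf = rot3(buf, o3, o1, o2);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = IntegerVector::create(o1, o2, o3);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize2d(NumericMatrix img, int Ho, int Wo, std::string method) {
  const int H = img.nrow(), W = img.ncol();
  Taps th = axis_taps(H, Ho, (double)H / Ho, method);
  Taps tw = axis_taps(W, Wo, (double)W / Wo, method);
  std::vector<double> tmp((size_t)Ho * W);
  for (int w = 0; w < W; ++w)
    for (int i = 0; i < Ho; ++i) {
      double acc = 0.0;
      for (int k = 0; k < th.ntap; ++k)
        acc += th.wgt[(size_t)i * th.ntap + k] * img(th.idx[(size_t)i * th.ntap + k], w);
      tmp[(size_t)w * Ho + i] = acc;
    }
  NumericMatrix out(Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i) {
      double acc = 0.0;
      for (int k = 0; k < tw.ntap; ++k)
        acc += tw.wgt[(size_t)j * tw.ntap + k] * tmp[(size_t)tw.idx[(size_t)j * tw.ntap + k] * Ho + i];
      out(i, j) = acc;
    }
  return out;
}
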