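// Low-level numerical kernels for 3D convolutional networks and volume
// resampling. Tensors are R numeric arrays with dim (C, D, H, W) stored
// column-major, so the channel index is contiguous; voxel v = d + D*(h + H*w).
// Convolutions are stride-1 "same" (k = 1 or 3); spatial reduction is done by
// 2x2x2 max-pooling and expansion by strided transpose convolutions.
// Heavy lifting goes through im2col + BLAS gemm (Armadillo), chunked over
// voxels to bound memory.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void dims4(const NumericVector &x, int &C, int &D, int &H, int &W) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D (C,D,H,W) array");
  C = d[0]; D = d[1]; H = d[2]; W = d[3];
}

static int chunk_cols(int K) {
  double n = 6e6 / (double)K;
  if (n < 512.0) n = 512.0;
  if (n > 65536.0) n = 65536.0;
  return (int)n;
}

// Gather im2col patches for output voxels [v0, v1) into P (K x n).
static void gather_patches(const double *x, int C, int D, int H, int W,
                           int k, int pad, int v0, int v1, arma::mat &P) {
  const int n = v1 - v0;
  P.zeros();
  for (int j = 0; j < n; ++j) {
    int v = v0 + j;
    int d = v % D, rem = v / D;
    int h = rem % H, w = rem / H;
    double *col = P.colptr(j);
    for (int kw = 0; kw < k; ++kw) {
      int sw = w + kw - pad;
      if (sw < 0 || sw >= W) continue;
      for (int kh = 0; kh < k; ++kh) {
        int sh = h + kh - pad;
        if (sh < 0 || sh >= H) continue;
        for (int kd = 0; kd < k; ++kd) {
          int sd = d + kd - pad;
          if (sd < 0 || sd >= D) continue;
          int row0 = C * (kd + k * (kh + k * kw));
          const double *src = x + (size_t)C * (sd + (size_t)D * (sh + (size_t)H * sw));
          std::memcpy(col + row0, src, C * sizeof(double));
        }
      }
    }
  }
}

// Scatter-add of patch gradients back into gx (reverse of gather_patches).
static void scatter_patches(double *gx, int C, int D, int H, int W,
                            int k, int pad, int v0, int v1, const arma::mat &P) {
  const int n = v1 - v0;
  for (int j = 0; j < n; ++j) {
    int v = v0 + j;
    int d = v % D, rem = v / D;
    int h = rem % H, w = rem / H;
    const double *col = P.colptr(j);
    for (int kw = 0; kw < k; ++kw) {
      int sw = w + kw - pad;
      if (sw < 0 || sw >= W) continue;
      for (int kh = 0; kh < k; ++kh) {
        int sh = h + kh - pad;
        if (sh < 0 || sh >= H) continue;
        for (int kd = 0; kd < k; ++kd) {
          int sd = d + kd - pad;
          if (sd < 0 || sd >= D) continue;
          int row0 = C * (kd + k * (kh + k * kw));
          double *dst = gx + (size_t)C * (sd + (size_t)D * (sh + (size_t)H * sw));
          for (int c = 0; c < C; ++c) dst[c] += col[row0 + c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv3d_fw(NumericVector x, NumericMatrix w, NumericVector b,
                           int k, int pad) {
  int C, D, H, W; dims4(x, C, D, H, W);
  const int K = C * k * k * k;
  if (w.nrow() != K) stop("weight rows do not match C*k^3");
  const int Cout = w.ncol();
  const int Vn = D * H * W; // stride-1 same padding keeps the spatial grid
  if (2 * pad != k - 1) stop("conv3d requires same padding");
  NumericVector y(Cout * (R_xlen_t)Vn);
  y.attr("dim") = IntegerVector::create(Cout, D, H, W);
  arma::mat WA(w.begin(), K, Cout, false);
  arma::vec BA(b.begin(), Cout, false);
  const int nc = chunk_cols(K);
  arma::mat P(K, nc);
  for (int v0 = 0; v0 < Vn; v0 += nc) {
    int v1 = std::min(v0 + nc, Vn);
    int n = v1 - v0;
    arma::mat Pv = P.cols(0, n - 1);
    gather_patches(x.begin(), C, D, H, W, k, pad, v0, v1, Pv);
    arma::mat O = WA.t() * Pv;       // Cout x n
    O.each_col() += BA;
    std::memcpy(y.begin() + (size_t)Cout * v0, O.memptr(),
                (size_t)Cout * n * sizeof(double));
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv3d_bw(NumericVector x, NumericMatrix w, NumericVector gy,
                  int k, int pad) {
  int C, D, H, W; dims4(x, C, D, H, W);
  const int K = C * k * k * k;
  const int Cout = w.ncol();
  const int Vn = D * H * W;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  arma::mat WA(w.begin(), K, Cout, false);
  arma::mat GW(K, Cout, arma::fill::zeros);
  arma::vec GB(Cout, arma::fill::zeros);
  const int nc = chunk_cols(K);
  arma::mat P(K, nc);
  for (int v0 = 0; v0 < Vn; v0 += nc) {
    int v1 = std::min(v0 + nc, Vn);
    int n = v1 - v0;
    arma::mat GYc(gy.begin() + (size_t)Cout * v0, Cout, n, false);
    arma::mat Pv = P.cols(0, n - 1);
    gather_patches(x.begin(), C, D, H, W, k, pad, v0, v1, Pv);
    GW += Pv * GYc.t();
    GB += arma::sum(GYc, 1);
    arma::mat GP = WA * GYc;         // K x n
    scatter_patches(gx.begin(), C, D, H, W, k, pad, v0, v1, GP);
  }
  NumericMatrix gwR(K, Cout);
  std::memcpy(gwR.begin(), GW.memptr(), GW.n_elem * sizeof(double));
  NumericVector gbR(Cout);
  std::memcpy(gbR.begin(), GB.memptr(), Cout * sizeof(double));
  return List::create(_["gx"] = gx, _["gw"] = gwR, _["gb"] = gbR);
}

// Transpose convolution: weights are (Cin x Cout*k^3); output spatial size is
// (D-1)*stride - 2*pad + k + opad per axis.
// [[Rcpp::export]]
NumericVector nn_convt3d_fw(NumericVector x, NumericMatrix w, NumericVector b,
                            int k, int stride, int pad, int opad) {
  int C, D, H, W; dims4(x, C, D, H, W);
  if (w.nrow() != C) stop("weight rows do not match Cin");
  const int K2 = w.ncol();
  if (K2 % (k * k * k) != 0) stop("weight cols not divisible by k^3");
  const int Cout = K2 / (k * k * k);
  const int Do = (D - 1) * stride - 2 * pad + k + opad;
  const int Ho = (H - 1) * stride - 2 * pad + k + opad;
  const int Wo = (W - 1) * stride - 2 * pad + k + opad;
  const int Vin = D * H * W;
  const R_xlen_t Vo = (R_xlen_t)Do * Ho * Wo;
  NumericVector y(Cout * Vo);
  y.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo);
  double *yp = y.begin();
  for (R_xlen_t v = 0; v < Vo; ++v)
    for (int c = 0; c < Cout; ++c) yp[c + (size_t)Cout * v] = b[c];
  arma::mat WA(w.begin(), C, K2, false);
  arma::mat XA(x.begin(), C, Vin, false);
  const int nc = chunk_cols(K2);
  for (int v0 = 0; v0 < Vin; v0 += nc) {
    int v1 = std::min(v0 + nc, Vin);
    int n = v1 - v0;
    arma::mat cols = WA.t() * XA.cols(v0, v1 - 1); // K2 x n
    for (int j = 0; j < n; ++j) {
      int v = v0 + j;
      int d = v % D, rem = v / D;
      int h = rem % H, wv = rem / H;
      const double *col = cols.colptr(j);
      for (int kw = 0; kw < k; ++kw) {
        int ow = wv * stride - pad + kw;
        if (ow < 0 || ow >= Wo) continue;
        for (int kh = 0; kh < k; ++kh) {
          int oh = h * stride - pad + kh;
          if (oh < 0 || oh >= Ho) continue;
          for (int kd = 0; kd < k; ++kd) {
            int od = d * stride - pad + kd;
            if (od < 0 || od >= Do) continue;
            int row0 = Cout * (kd + k * (kh + k * kw));
            double *dst = yp + (size_t)Cout * (od + (size_t)Do * (oh + (size_t)Ho * ow));
            for (int c = 0; c < Cout; ++c) dst[c] += col[row0 + c];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_convt3d_bw(NumericVector x, NumericMatrix w, NumericVector gy,
                   int k, int stride, int pad, int opad) {
  int C, D, H, W; dims4(x, C, D, H, W);
  int Cg, Do, Ho, Wo; dims4(gy, Cg, Do, Ho, Wo);
  const int K2 = w.ncol();
  const int Cout = K2 / (k * k * k);
  if (Cg != Cout) stop("gradient channels mismatch");
  const int Vin = D * H * W;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  arma::mat WA(w.begin(), C, K2, false);
  arma::mat XA(x.begin(), C, Vin, false);
  arma::mat GW(C, K2, arma::fill::zeros);
  NumericVector gb(Cout);
  const double *gyp = gy.begin();
  { // bias gradient: per-channel sum over output voxels
    R_xlen_t Vo = (R_xlen_t)Do * Ho * Wo;
    for (R_xlen_t v = 0; v < Vo; ++v)
      for (int c = 0; c < Cout; ++c) gb[c] += gyp[c + (size_t)Cout * v];
  }
  const int nc = chunk_cols(K2);
  arma::mat gcols(K2, nc);
  for (int v0 = 0; v0 < Vin; v0 += nc) {
    int v1 = std::min(v0 + nc, Vin);
    int n = v1 - v0;
    arma::mat G = gcols.cols(0, n - 1);
    G.zeros();
    for (int j = 0; j < n; ++j) {
      int v = v0 + j;
      int d = v % D, rem = v / D;
      int h = rem % H, wv = rem / H;
      double *col = G.colptr(j);
      for (int kw = 0; kw < k; ++kw) {
        int ow = wv * stride - pad + kw;
        if (ow < 0 || ow >= Wo) continue;
        for (int kh = 0; kh < k; ++kh) {
          int oh = h * stride - pad + kh;
          if (oh < 0 || oh >= Ho) continue;
          for (int kd = 0; kd < k; ++kd) {
            int od = d * stride - pad + kd;
            if (od < 0 || od >= Do) continue;
            int row0 = Cout * (kd + k * (kh + k * kw));
            const double *src = gyp + (size_t)Cout * (od + (size_t)Do * (oh + (size_t)Ho * ow));
            for (int c = 0; c < Cout; ++c) col[row0 + c] = src[c];
          }
        }
      }
    }
    arma::mat GX = WA * G;                   // C x n
    std::memcpy(gx.begin() + (size_t)C * v0, GX.memptr(),
                (size_t)C * n * sizeof(double));
    GW += XA.cols(v0, v1 - 1) * G.t();
  }
  NumericMatrix gwR(C, K2);
  std::memcpy(gwR.begin(), GW.memptr(), GW.n_elem * sizeof(double));
  return List::create(_["gx"] = gx, _["gw"] = gwR, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2; also returns the flat argmax index into x
// (0-based) for the backward pass.
// [[Rcpp::export]]
List nn_maxpool3d_fw(NumericVector x) {
  int C, D, H, W; dims4(x, C, D, H, W);
  if (D % 2 || H % 2 || W % 2) stop("max-pool requires even spatial dims");
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const R_xlen_t Vo = (R_xlen_t)Do * Ho * Wo;
  NumericVector y(C * Vo);
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  IntegerVector idx(C * Vo);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        R_xlen_t outv = od + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow);
        for (int c = 0; c < C; ++c) {
          double best = -HUGE_VAL; R_xlen_t bi = -1;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                R_xlen_t xi = c + (R_xlen_t)C *
                  ((od * 2 + kd) + (R_xlen_t)D * ((oh * 2 + kh) + (R_xlen_t)H * (ow * 2 + kw)));
                if (xp[xi] > best) { best = xp[xi]; bi = xi; }
              }
          yp[c + (size_t)C * outv] = best;
          ip[c + (size_t)C * outv] = (int)bi;
        }
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool3d_bw(NumericVector gy, IntegerVector idx,
                              IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  const double *gp = gy.begin();
  double *xp = gx.begin();
  const int *ip = idx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) xp[ip[i]] += gp[i];
  return gx;
}

// Resample a 3D (D,H,W) volume to a new grid with pixel-centre alignment.
// mode 0 = trilinear, 1 = nearest neighbour. Identity when sizes match.
// [[Rcpp::export]]
NumericVector resample3d(NumericVector x, IntegerVector outdim, int mode) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3D (D,H,W) array");
  const int D = d[0], H = d[1], W = d[2];
  const int Do = outdim[0], Ho = outdim[1], Wo = outdim[2];
  NumericVector y((R_xlen_t)Do * Ho * Wo);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  const double *xp = x.begin();
  double *yp = y.begin();
  const double sd = (double)D / Do, sh = (double)H / Ho, sw = (double)W / Wo;
  for (int ow = 0; ow < Wo; ++ow) {
    double cw = (ow + 0.5) * sw - 0.5;
    for (int oh = 0; oh < Ho; ++oh) {
      double ch = (oh + 0.5) * sh - 0.5;
      for (int od = 0; od < Do; ++od) {
        double cd = (od + 0.5) * sd - 0.5;
        double val;
        if (mode == 1) {
          int id = (int)std::lround(cd), ih = (int)std::lround(ch), iw = (int)std::lround(cw);
          id = std::min(std::max(id, 0), D - 1);
          ih = std::min(std::max(ih, 0), H - 1);
          iw = std::min(std::max(iw, 0), W - 1);
          val = xp[id + (size_t)D * (ih + (size_t)H * iw)];
        } else {
          double fd = std::floor(cd), fh = std::floor(ch), fw = std::floor(cw);
          double td = cd - fd, th = ch - fh, tw = cw - fw;
          int d0 = std::min(std::max((int)fd, 0), D - 1);
          int d1 = std::min(d0 + 1, D - 1);
          if (fd < 0) { d0 = d1 = 0; td = 0; }
          int h0 = std::min(std::max((int)fh, 0), H - 1);
          int h1 = std::min(h0 + 1, H - 1);
          if (fh < 0) { h0 = h1 = 0; th = 0; }
          int w0 = std::min(std::max((int)fw, 0), W - 1);
          int w1 = std::min(w0 + 1, W - 1);
          if (fw < 0) { w0 = w1 = 0; tw = 0; }
          if ((int)fd >= D - 1) td = 0;
          if ((int)fh >= H - 1) th = 0;
          if ((int)fw >= W - 1) tw = 0;
          #define XV(a,b,c) xp[(a) + (size_t)D * ((b) + (size_t)H * (c))]
          double c00 = XV(d0,h0,w0) * (1-td) + XV(d1,h0,w0) * td;
          double c10 = XV(d0,h1,w0) * (1-td) + XV(d1,h1,w0) * td;
          double c01 = XV(d0,h0,w1) * (1-td) + XV(d1,h0,w1) * td;
          double c11 = XV(d0,h1,w1) * (1-td) + XV(d1,h1,w1) * td;
          #undef XV
          double c0 = c00 * (1-th) + c10 * th;
          double c1 = c01 * (1-th) + c11 * th;
          val = c0 * (1-tw) + c1 * tw;
        }
        yp[od + (size_t)Do * (oh + (size_t)Ho * ow)] = val;
      }
    }
  }
  return y;
}
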