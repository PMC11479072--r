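// Numeric kernels for the spatio-temporal estimator and ROI stage.
//
// Array layout convention (matches R column-major arrays):
//   video stack          : dim (H, W, T)
//   feature volume       : dim (H, W, T, C), linear index h + H*(w + W*(t + T*c))
// 3-D convolutions are "same" (3x3x3, zero pad 1) and are computed as
// im2col followed by a BLAS GEMM; backward rebuilds the patch matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& T, int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) { H = d[0]; W = d[1]; T = d[2]; C = 1; }
  else { H = d[0]; W = d[1]; T = d[2]; C = d[3]; }
}

// patch matrix: rows = voxels (h,w,t col-major), cols = 27*C offsets
static arma::mat im2col3(const double* x, int H, int W, int T, int C) {
  const int N = H * W * T;
  arma::mat M(N, 27 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * N;
    for (int kt = -1; kt <= 1; ++kt)
      for (int kw = -1; kw <= 1; ++kw)
        for (int kh = -1; kh <= 1; ++kh) {
          int j = ((c * 3 + (kt + 1)) * 3 + (kw + 1)) * 3 + (kh + 1);
          double* col = M.colptr(j);
          for (int t = 0; t < T; ++t) {
            int ts = t + kt;
            if (ts < 0 || ts >= T) continue;
            for (int w = 0; w < W; ++w) {
              int ws = w + kw;
              if (ws < 0 || ws >= W) continue;
              const double* src = xc + (size_t)(ts * W + ws) * H;
              double* dst = col + (size_t)(t * W + w) * H;
              int h0 = std::max(0, -kh), h1 = std::min(H, H - kh);
              for (int h = h0; h < h1; ++h) dst[h] = src[h + kh];
            }
          }
        }
  }
  return M;
}

// scatter-add transpose of im2col3
static void col2im3(const arma::mat& M, double* dx, int H, int W, int T, int C) {
  const int N = H * W * T;
  std::fill(dx, dx + (size_t)N * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * N;
    for (int kt = -1; kt <= 1; ++kt)
      for (int kw = -1; kw <= 1; ++kw)
        for (int kh = -1; kh <= 1; ++kh) {
          int j = ((c * 3 + (kt + 1)) * 3 + (kw + 1)) * 3 + (kh + 1);
          const double* col = M.colptr(j);
          for (int t = 0; t < T; ++t) {
            int ts = t + kt;
            if (ts < 0 || ts >= T) continue;
            for (int w = 0; w < W; ++w) {
              int ws = w + kw;
              if (ws < 0 || ws >= W) continue;
              double* dst = xc + (size_t)(ts * W + ws) * H;
              const double* src = col + (size_t)(t * W + w) * H;
              int h0 = std::max(0, -kh), h1 = std::min(H, H - kh);
              for (int h = h0; h < h1; ++h) dst[h + kh] += src[h];
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, const arma::mat& K,
                             const arma::vec& bias) {
  int H, W, T, C;
  get_dims4(x, H, W, T, C);
  if ((int)K.n_rows != 27 * C) stop("kernel rows != 27 * in_channels");
  const int Cout = K.n_cols;
  arma::mat M = im2col3(x.begin(), H, W, T, C);
  arma::mat Y = M * K;
  Y.each_row() += bias.t();
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, T, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, const arma::mat& K, NumericVector dy,
                    bool want_dx = true) {
  int H, W, T, C;
  get_dims4(x, H, W, T, C);
  const int N = H * W * T;
  const int Cout = K.n_cols;
  arma::mat dY(dy.begin(), N, Cout, false, true);
  arma::mat M = im2col3(x.begin(), H, W, T, C);
  arma::mat dK = M.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  if (!want_dx)
    return List::create(_["dx"] = R_NilValue, _["dK"] = dK, _["db"] = db);
  arma::mat dXc = dY * K.t();
  NumericVector dx(x.size());
  col2im3(dXc, dx.begin(), H, W, T, C);
  dx.attr("dim") = x.attr("dim");
  return List::create(_["dx"] = dx, _["dK"] = dK, _["db"] = db);
}

// non-overlapping average pooling, window == stride (sh, sw, st)
// [[Rcpp::export]]
NumericVector cpp_avgpool3d_fwd(NumericVector x, int sh, int sw, int st) {
  int H, W, T, C;
  get_dims4(x, H, W, T, C);
  int Ho = H / sh, Wo = W / sw, To = T / st;
  if (Ho < 1 || Wo < 1 || To < 1) stop("pooling window larger than input");
  NumericVector y((size_t)Ho * Wo * To * C);
  const double inv = 1.0 / (sh * sw * st);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < To; ++t)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double s = 0;
          for (int dt = 0; dt < st; ++dt)
            for (int dw = 0; dw < sw; ++dw)
              for (int dh = 0; dh < sh; ++dh)
                s += xp[(size_t)(h * sh + dh) +
                        (size_t)H * ((w * sw + dw) +
                        (size_t)W * ((t * st + dt) + (size_t)T * c))];
          yp[(size_t)h + (size_t)Ho * (w + (size_t)Wo * (t + (size_t)To * c))] = s * inv;
        }
  y.attr("dim") = IntegerVector::create(Ho, Wo, To, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool3d_bwd(NumericVector dy, int H, int W, int T,
                                int sh, int sw, int st) {
  int Ho, Wo, To, C;
  get_dims4(dy, Ho, Wo, To, C);
  NumericVector dx((size_t)H * W * T * C);
  const double inv = 1.0 / (sh * sw * st);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < To; ++t)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double g = dyp[(size_t)h + (size_t)Ho * (w + (size_t)Wo *
                         (t + (size_t)To * c))] * inv;
          for (int dt = 0; dt < st; ++dt)
            for (int dw = 0; dw < sw; ++dw)
              for (int dh = 0; dh < sh; ++dh)
                dxp[(size_t)(h * sh + dh) + (size_t)H * ((w * sw + dw) +
                    (size_t)W * ((t * st + dt) + (size_t)T * c))] += g;
        }
  dx.attr("dim") = IntegerVector::create(H, W, T, C);
  return dx;
}

// Crop each frame to its (0-based, half-open) box and resample to
// out_h x out_w with bilinear interpolation; pixel-center alignment, so a
// full-frame box at native size is an exact identity.
// boxes: T x 4 matrix, columns x0, y0, x1, y1.
// [[Rcpp::export]]
NumericVector cpp_crop_resize(NumericVector frames, const NumericMatrix& boxes,
                              int out_h, int out_w) {
  IntegerVector d = frames.attr("dim");
  int H = d[0], W = d[1], T = d[2];
  if (boxes.nrow() != T) stop("need one box per frame");
  NumericVector out((size_t)out_h * out_w * T);
  const double* fp = frames.begin();
  double* op = out.begin();
  for (int t = 0; t < T; ++t) {
    double x0 = boxes(t, 0), y0 = boxes(t, 1), x1 = boxes(t, 2), y1 = boxes(t, 3);
    double bw = x1 - x0, bh = y1 - y0;
    if (bw <= 1.0 || bh <= 1.0) stop("degenerate box (<= 1 px) at frame %d", t + 1);
    const double* src = fp + (size_t)H * W * t;
    double* dst = op + (size_t)out_h * out_w * t;
    for (int j = 0; j < out_w; ++j) {
      double sx = x0 + (j + 0.5) * bw / out_w - 0.5;
      if (sx < 0) sx = 0; if (sx > W - 1) sx = W - 1;
      int jx = (int)std::floor(sx);
      if (jx > W - 2) jx = W - 2;
      double fx = sx - jx;
      for (int i = 0; i < out_h; ++i) {
        double sy = y0 + (i + 0.5) * bh / out_h - 0.5;
        if (sy < 0) sy = 0; if (sy > H - 1) sy = H - 1;
        int iy = (int)std::floor(sy);
        if (iy > H - 2) iy = H - 2;
        double fy = sy - iy;
        double v00 = src[iy + (size_t)H * jx],     v01 = src[iy + (size_t)H * (jx + 1)];
        double v10 = src[iy + 1 + (size_t)H * jx], v11 = src[iy + 1 + (size_t)H * (jx + 1)];
        dst[i + (size_t)out_h * j] =
          (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(out_h, out_w, T);
  return out;
}

// 4-connected component labelling of a binary mask (H x W), BFS
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        int vi = v % H, vj = v / H;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = vi + di[k], nj = vj + dj[k];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + H * nj);
          }
        }
      }
    }
  return lab;
}
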