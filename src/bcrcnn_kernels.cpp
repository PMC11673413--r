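// Numeric kernels for the detector: all feature maps are R arrays [H, W, C]
// (column-major, so an arma::cube with n_rows = H maps onto them without copy
// semantics surprises). Batch size is always 1, matching the training regime.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a [H, W, C] array");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector cube_to_r(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// im2col for stride-1 convolution with symmetric zero padding.
// Column p = i + H*j (output pixel, column-major); row r = i_k + kh*(j_k + kw*c_in).
static arma::mat im2col(const arma::cube& x, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(kh * kw * C, (size_t)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int jk = 0; jk < kw; ++jk) {
      for (int ik = 0; ik < kh; ++ik) {
        const int r = ik + kh * (jk + kw * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + jk - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ik - pad;
            if (si < 0 || si >= H) continue;
            col(r, (size_t)j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return col;
}

static arma::cube col2im(const arma::mat& col, int H, int W, int C, int kh, int kw, int pad) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int jk = 0; jk < kw; ++jk) {
      for (int ik = 0; ik < kh; ++ik) {
        const int r = ik + kh * (jk + kw * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + jk - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ik - pad;
            if (si < 0 || si >= H) continue;
            x(si, sj, c) += col(r, (size_t)j * H + i);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b, int pad) {
  arma::cube xc = as_cube(x);
  IntegerVector wd = w.attr("dim"); // [kh, kw, Cin, Cout]
  if (wd.size() != 4) stop("weights must be [kh, kw, Cin, Cout]");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if ((int)xc.n_slices != cin) stop("channel mismatch in conv2d_fw");
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * cin, cout, false, true);
  arma::mat col = im2col(xc, kh, kw, pad);
  arma::mat y = wm.t() * col; // [Cout, H*W]
  arma::cube out(xc.n_rows, xc.n_cols, cout);
  arma::vec bv(const_cast<double*>(b.begin()), cout, false, true);
  for (int c = 0; c < cout; ++c) {
    out.slice(c) = arma::reshape(y.row(c), xc.n_rows, xc.n_cols) + bv(c);
  }
  return cube_to_r(out);
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int pad,
               bool skip_gx = false) {
  arma::cube xc = as_cube(x), gyc = as_cube(gy);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * cin, cout, false, true);
  const int H = xc.n_rows, W = xc.n_cols;
  arma::mat gym(cout, (size_t)H * W);
  for (int c = 0; c < cout; ++c)
    gym.row(c) = arma::vectorise(gyc.slice(c)).t();
  arma::mat col = im2col(xc, kh, kw, pad);
  arma::mat gw = col * gym.t();          // [kh*kw*Cin, Cout]
  arma::vec gb = arma::sum(gym, 1);      // [Cout]
  if (skip_gx) {
    NumericVector gwr0(gw.begin(), gw.end());
    gwr0.attr("dim") = wd;
    return List::create(_["gx"] = R_NilValue, _["gw"] = gwr0,
                        _["gb"] = NumericVector(gb.begin(), gb.end()));
  }
  // gx via flipped-kernel correlation with gy (stride 1, symmetric pad)
  arma::mat wflip(kh * kw * cout, cin);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int jk = 0; jk < kw; ++jk)
        for (int ik = 0; ik < kh; ++ik)
          wflip((kh - 1 - ik) + kh * ((kw - 1 - jk) + kw * co), ci) =
            wm(ik + kh * (jk + kw * ci), co);
  arma::mat colg = im2col(gyc, kh, kw, pad);
  arma::mat gxm = wflip.t() * colg; // [Cin, H*W]
  arma::cube gx(H, W, cin);
  for (int c = 0; c < cin; ++c)
    gx.slice(c) = arma::reshape(gxm.row(c), H, W);
  NumericVector gwr(gw.begin(), gw.end());
  gwr.attr("dim") = wd;
  return List::create(_["gx"] = cube_to_r(gx), _["gw"] = gwr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 2x2 stride-2 max pooling; records argmax for the backward pass.
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C); // linear index into x (0-based)
  int q = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int besti = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = xc(si, sj, c);
            if (v > best) { best = v; besti = si + H * (sj + (size_t)W * c); }
          }
        }
        y(i, j, c) = best;
        idx[q++] = besti;
      }
    }
  }
  List out = List::create(_["y"] = cube_to_r(y), _["idx"] = idx);
  return out;
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2]);
  for (int q = 0; q < gy.size(); ++q) gx[idx[q]] += gy[q];
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fw(NumericVector x) {
  arma::cube xc = as_cube(x);
  arma::cube y(2 * xc.n_rows, 2 * xc.n_cols, xc.n_slices);
  for (arma::uword c = 0; c < xc.n_slices; ++c)
    for (arma::uword j = 0; j < xc.n_cols; ++j)
      for (arma::uword i = 0; i < xc.n_rows; ++i) {
        const double v = xc(i, j, c);
        y(2*i, 2*j, c) = v; y(2*i+1, 2*j, c) = v;
        y(2*i, 2*j+1, c) = v; y(2*i+1, 2*j+1, c) = v;
      }
  return cube_to_r(y);
}

// [[Rcpp::export]]
NumericVector upsample2_bw(NumericVector gy) {
  arma::cube gyc = as_cube(gy);
  arma::cube gx(gyc.n_rows / 2, gyc.n_cols / 2, gyc.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < gyc.n_slices; ++c)
    for (arma::uword j = 0; j < gyc.n_cols; ++j)
      for (arma::uword i = 0; i < gyc.n_rows; ++i)
        gx(i / 2, j / 2, c) += gyc(i, j, c);
  return cube_to_r(gx);
}

// Bilinear lookup on the feature lattice: pixel (row i, col j) sits at the
// continuous point (x = j, y = i); values are clamped at the border.
static inline double bilinear(const arma::mat& f, double y, double x) {
  const int H = f.n_rows, W = f.n_cols;
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  const double dx = x - x0, dy = y - y0;
  return f(y0, x0) * (1 - dy) * (1 - dx) + f(y0, x1) * (1 - dy) * dx +
         f(y1, x0) * dy * (1 - dx) + f(y1, x1) * dy * dx;
}

static inline void bilinear_scatter(arma::mat& g, double y, double x, double v) {
  const int H = g.n_rows, W = g.n_cols;
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  const double dx = x - x0, dy = y - y0;
  g(y0, x0) += v * (1 - dy) * (1 - dx); g(y0, x1) += v * (1 - dy) * dx;
  g(y1, x0) += v * dy * (1 - dx);       g(y1, x1) += v * dy * dx;
}

// ROI align: image-coordinate boxes [n, 4] (x_min, y_min, x_max, y_max),
// half-open convention. Image point x maps to lattice coordinate
// x / stride - 0.5 (pixel centers at (j + 0.5) * stride). Each of the
// pooled x pooled bins averages sampling^2 regularly spaced bilinear samples.
// corner indices and weights for one bilinear sample (clamped lattice)
struct BilinearTap { int i00, i01, i10, i11; double w00, w01, w10, w11; };

static inline BilinearTap bilinear_tap(int H, int W, double y, double x) {
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  const double dx = x - x0, dy = y - y0;
  BilinearTap t;
  t.i00 = y0 + H * x0; t.i01 = y0 + H * x1;
  t.i10 = y1 + H * x0; t.i11 = y1 + H * x1;
  t.w00 = (1 - dy) * (1 - dx); t.w01 = (1 - dy) * dx;
  t.w10 = dy * (1 - dx);       t.w11 = dy * dx;
  return t;
}

// [[Rcpp::export]]
NumericVector roi_align_fw(NumericVector feat, NumericMatrix boxes, double stride,
                           int pooled, int sampling) {
  IntegerVector fd = feat.attr("dim");
  const int H = fd[0], W = fd[1], C = fd[2];
  const int n = boxes.nrow(), S = sampling;
  const size_t hw = (size_t)H * W, pp = (size_t)pooled * pooled;
  NumericVector out(pp * C * n);
  out.attr("dim") = IntegerVector::create(pooled, pooled, C, n);
  const double inv = 1.0 / (S * S);
  const double* f0 = feat.begin();
  for (int r = 0; r < n; ++r) {
    const double x0 = boxes(r, 0) / stride - 0.5, y0 = boxes(r, 1) / stride - 0.5;
    const double x1 = boxes(r, 2) / stride - 0.5, y1 = boxes(r, 3) / stride - 0.5;
    const double bw = (x1 - x0) / pooled, bh = (y1 - y0) / pooled;
    double* outr = out.begin() + (size_t)r * C * pp;
    for (int pj = 0; pj < pooled; ++pj)
      for (int pi = 0; pi < pooled; ++pi) {
        const size_t bin = pi + (size_t)pooled * pj;
        for (int sj = 0; sj < S; ++sj)
          for (int si = 0; si < S; ++si) {
            BilinearTap t = bilinear_tap(H, W,
              y0 + (pi + (si + 0.5) / S) * bh,
              x0 + (pj + (sj + 0.5) / S) * bw);
            for (int c = 0; c < C; ++c) {
              const double* f = f0 + (size_t)c * hw;
              outr[bin + c * pp] += inv * (f[t.i00] * t.w00 + f[t.i01] * t.w01 +
                                           f[t.i10] * t.w10 + f[t.i11] * t.w11);
            }
          }
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector roi_align_bw(NumericVector gy, NumericMatrix boxes, double stride,
                           int pooled, int sampling, IntegerVector featdim) {
  const int H = featdim[0], W = featdim[1], C = featdim[2], n = boxes.nrow(), S = sampling;
  const size_t hw = (size_t)H * W, pp = (size_t)pooled * pooled;
  NumericVector gf(hw * C);
  gf.attr("dim") = featdim;
  const double inv = 1.0 / (S * S);
  for (int r = 0; r < n; ++r) {
    const double x0 = boxes(r, 0) / stride - 0.5, y0 = boxes(r, 1) / stride - 0.5;
    const double x1 = boxes(r, 2) / stride - 0.5, y1 = boxes(r, 3) / stride - 0.5;
    const double bw = (x1 - x0) / pooled, bh = (y1 - y0) / pooled;
    const double* gyr = gy.begin() + (size_t)r * C * pp;
    for (int pj = 0; pj < pooled; ++pj)
      for (int pi = 0; pi < pooled; ++pi) {
        const size_t bin = pi + (size_t)pooled * pj;
        for (int sj = 0; sj < S; ++sj)
          for (int si = 0; si < S; ++si) {
            BilinearTap t = bilinear_tap(H, W,
              y0 + (pi + (si + 0.5) / S) * bh,
              x0 + (pj + (sj + 0.5) / S) * bw);
            for (int c = 0; c < C; ++c) {
              const double v = inv * gyr[bin + c * pp];
              double* g = gf.begin() + (size_t)c * hw;
              g[t.i00] += v * t.w00; g[t.i01] += v * t.w01;
              g[t.i10] += v * t.w10; g[t.i11] += v * t.w11;
            }
          }
      }
  }
  return gf;
}

static inline double pair_iou(const NumericMatrix& a, int i, const NumericMatrix& b, int j) {
  const double iw = std::min(a(i,2), b(j,2)) - std::max(a(i,0), b(j,0));
  const double ih = std::min(a(i,3), b(j,3)) - std::max(a(i,1), b(j,1));
  if (iw <= 0 || ih <= 0) return 0.0;
  const double inter = iw * ih;
  const double ua = (a(i,2)-a(i,0)) * (a(i,3)-a(i,1)) + (b(j,2)-b(j,0)) * (b(j,3)-b(j,1)) - inter;
  return ua > 0 ? inter / ua : 0.0;
}

// [[Rcpp::export]]
NumericMatrix iou_matrix_cpp(NumericMatrix a, NumericMatrix b) {
  NumericMatrix out(a.nrow(), b.nrow());
  for (int j = 0; j < b.nrow(); ++j)
    for (int i = 0; i < a.nrow(); ++i)
      out(i, j) = pair_iou(a, i, b, j);
  return out;
}

// Greedy NMS. Returns kept row indices (1-based), in descending score order;
// score ties broken toward the lower row index. max_keep > 0 stops early
// after that many boxes are kept (the kept prefix is unchanged by stopping).
// [[Rcpp::export]]
IntegerVector nms_cpp(NumericMatrix boxes, NumericVector scores, double threshold,
                      int max_keep = 0) {
  const int n = boxes.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return scores[a] > scores[b]; });
  // contiguous copies in score order for a tight suppression loop
  std::vector<double> x1(n), y1(n), x2(n), y2(n), area(n);
  for (int u = 0; u < n; ++u) {
    const int i = ord[u];
    x1[u] = boxes(i, 0); y1[u] = boxes(i, 1);
    x2[u] = boxes(i, 2); y2[u] = boxes(i, 3);
    area[u] = (x2[u] - x1[u]) * (y2[u] - y1[u]);
  }
  std::vector<char> dead(n, 0);
  std::vector<int> keep;
  for (int u = 0; u < n; ++u) {
    if (dead[u]) continue;
    keep.push_back(ord[u] + 1);
    if (max_keep > 0 && (int)keep.size() >= max_keep) break;
    const double ax1 = x1[u], ay1 = y1[u], ax2 = x2[u], ay2 = y2[u], aa = area[u];
    for (int v = u + 1; v < n; ++v) {
      if (dead[v]) continue;
      const double iw = std::min(ax2, x2[v]) - std::max(ax1, x1[v]);
      if (iw <= 0) continue;
      const double ih = std::min(ay2, y2[v]) - std::max(ay1, y1[v]);
      if (ih <= 0) continue;
      const double inter = iw * ih;
      if (inter > threshold * (aa + area[v] - inter)) dead[v] = 1;
    }
  }
  return wrap(keep);
}

// im2col over a whole stack [H, W, C, N]: output (kh*kw*C) x (H*W*N),
// column p = i + H*j + H*W*r.
static arma::mat im2col_stack(const double* x, int H, int W, int C, int N,
                              int kh, int kw, int pad) {
  arma::mat col(kh * kw * C, (size_t)H * W * N, arma::fill::zeros);
  const size_t xsz = (size_t)H * W * C;
  for (int r = 0; r < N; ++r) {
    const double* xr = x + r * xsz;
    double* cr = col.colptr((size_t)r * H * W);
    for (int c = 0; c < C; ++c) {
      const double* xc = xr + (size_t)c * H * W;
      for (int jk = 0; jk < kw; ++jk) {
        for (int ik = 0; ik < kh; ++ik) {
          const int rowi = ik + kh * (jk + kw * c);
          for (int j = 0; j < W; ++j) {
            const int sj = j + jk - pad;
            if (sj < 0 || sj >= W) continue;
            const double* src = xc + (size_t)sj * H;
            double* dst = cr + rowi + (size_t)(kh * kw * C) * ((size_t)j * H);
            const int i0 = std::max(0, pad - ik), i1 = std::min(H, H + pad - ik);
            for (int i = i0; i < i1; ++i)
              dst[(size_t)i * (kh * kw * C)] = src[i + ik - pad];
          }
        }
      }
    }
  }
  return col;
}

// Batched stride-1 convolution over a stack [H, W, Cin, N] -> [H, W, Cout, N],
// realized as a single im2col + one GEMM across all stack entries.
// [[Rcpp::export]]
NumericVector conv2d_stack_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("expected a [H, W, C, N] stack");
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int H = xd[0], W = xd[1], N = xd[3], pad = (kh - 1) / 2;
  if (xd[2] != cin) stop("channel mismatch in conv2d_stack_fw");
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * cin, cout, false, true);
  arma::mat col = im2col_stack(x.begin(), H, W, cin, N, kh, kw, pad);
  arma::mat y = wm.t() * col; // [Cout, H*W*N]
  NumericVector out((size_t)H * W * cout * N);
  out.attr("dim") = IntegerVector::create(H, W, cout, N);
  const size_t hw = (size_t)H * W;
  for (int r = 0; r < N; ++r)
    for (int c = 0; c < cout; ++c) {
      double* dst = out.begin() + ((size_t)r * cout + c) * hw;
      const double bc = b[c];
      for (size_t p = 0; p < hw; ++p)
        dst[p] = y(c, (size_t)r * hw + p) + bc;
    }
  return out;
}

// [[Rcpp::export]]
List conv2d_stack_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int H = xd[0], W = xd[1], N = xd[3], pad = (kh - 1) / 2;
  arma::mat wm(const_cast<double*>(w.begin()), kh * kw * cin, cout, false, true);
  const size_t hw = (size_t)H * W;
  // gy [H,W,Cout,N] -> [Cout, H*W*N]
  arma::mat gym(cout, hw * N);
  for (int r = 0; r < N; ++r)
    for (int c = 0; c < cout; ++c) {
      const double* src = gy.begin() + ((size_t)r * cout + c) * hw;
      for (size_t p = 0; p < hw; ++p)
        gym(c, (size_t)r * hw + p) = src[p];
    }
  arma::mat col = im2col_stack(x.begin(), H, W, cin, N, kh, kw, pad);
  arma::mat gw = col * gym.t();
  arma::vec gb = arma::sum(gym, 1);
  // gx as a correlation of gy with the spatially flipped, transposed kernel
  // (valid for stride 1 with symmetric padding): one more im2col + GEMM.
  arma::mat wflip(kh * kw * cout, cin);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int jk = 0; jk < kw; ++jk)
        for (int ik = 0; ik < kh; ++ik)
          wflip((kh - 1 - ik) + kh * ((kw - 1 - jk) + kw * co), ci) =
            wm(ik + kh * (jk + kw * ci), co);
  arma::mat colg = im2col_stack(gy.begin(), H, W, cout, N, kh, kw, pad);
  arma::mat gxm = wflip.t() * colg; // [Cin, H*W*N]
  NumericVector gx((size_t)H * W * cin * N);
  gx.attr("dim") = xd;
  for (int r = 0; r < N; ++r)
    for (int c = 0; c < cin; ++c) {
      double* dst = gx.begin() + ((size_t)r * cin + c) * hw;
      for (size_t p = 0; p < hw; ++p)
        dst[p] = gxm(c, (size_t)r * hw + p);
    }
  NumericVector gwr(gw.begin(), gw.end());
  gwr.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
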