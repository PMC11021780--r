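#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <limits>
using namespace Rcpp;

// Volumes are stored channel-last: dim (D, H, W, C), column-major, so the
// depth index is fastest and channel slices are contiguous blocks of D*H*W.

// Unfold a padded 3D volume into an N x (k^3 * C) patch matrix (N = D*H*W),
// stride 1, zero padding (k-1)/2, so conv = vol2col %*% weight_matrix.
// [[Rcpp::export]]
NumericMatrix vol2col3(NumericVector x, int D, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t N = (R_xlen_t)D * H * W;
  const int kk = k * k * k;
  NumericMatrix out(N, (R_xlen_t)kk * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)c * N;
    for (int ow = 0; ow < k; ++ow)
      for (int oh = 0; oh < k; ++oh)
        for (int od = 0; od < k; ++od) {
          const int o = od + k * (oh + k * ow);
          double* col = &out(0, o + (R_xlen_t)kk * c);
          const int dz = od - p, dy = oh - p, dx = ow - p;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dx;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dy;
              if (sh < 0 || sh >= H) continue;
              double* dst = col + (R_xlen_t)h * D + (R_xlen_t)w * D * H;
              const double* src = xc + (R_xlen_t)sh * D + (R_xlen_t)sw * D * H;
              const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
              for (int d = d0; d < d1; ++d) dst[d] = src[d + dz];
            }
          }
        }
  }
  return out;
}

// Adjoint of vol2col3: fold an N x (k^3 * C) matrix back into a (D,H,W,C)
// volume, accumulating overlapping contributions.
// [[Rcpp::export]]
NumericVector col2vol3(NumericMatrix cols, int D, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t N = (R_xlen_t)D * H * W;
  const int kk = k * k * k;
  NumericVector out((R_xlen_t)N * C);
  for (int c = 0; c < C; ++c) {
    double* xc = out.begin() + (R_xlen_t)c * N;
    for (int ow = 0; ow < k; ++ow)
      for (int oh = 0; oh < k; ++oh)
        for (int od = 0; od < k; ++od) {
          const int o = od + k * (oh + k * ow);
          const double* col = &cols(0, o + (R_xlen_t)kk * c);
          const int dz = od - p, dy = oh - p, dx = ow - p;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dx;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dy;
              if (sh < 0 || sh >= H) continue;
              const double* src = col + (R_xlen_t)h * D + (R_xlen_t)w * D * H;
              double* dst = xc + (R_xlen_t)sh * D + (R_xlen_t)sw * D * H;
              const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
              for (int d = d0; d < d1; ++d) dst[d + dz] += src[d];
            }
          }
        }
  }
  return out;
}

// 2x2x2 max pooling; returns pooled volume plus 1-based argmax positions
// into the input so the backward pass can scatter gradients.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, int D, int H, int W, int C) {
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const R_xlen_t No = (R_xlen_t)Do * Ho * Wo;
  NumericVector y(No * C);
  IntegerVector idx(No * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)c * D * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t besti = 0;
          for (int ow = 0; ow < 2; ++ow)
            for (int oh = 0; oh < 2; ++oh)
              for (int od = 0; od < 2; ++od) {
                const R_xlen_t i = (R_xlen_t)(2 * d + od) +
                  (R_xlen_t)D * (2 * h + oh) + (R_xlen_t)D * H * (2 * w + ow);
                if (xc[i] > best) { best = xc[i]; besti = i; }
              }
          const R_xlen_t j = (R_xlen_t)d + (R_xlen_t)Do * h + (R_xlen_t)Do * Ho * w;
          y[(R_xlen_t)c * No + j] = best;
          idx[(R_xlen_t)c * No + j] = (int)((R_xlen_t)c * D * H * W + besti) + 1;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector dy, IntegerVector idx, R_xlen_t n_in) {
  NumericVector dx(n_in);
  for (R_xlen_t j = 0; j < dy.size(); ++j) dx[idx[j] - 1] += dy[j];
  return dx;
}

static inline void up2x_axis(int n, std::vector<int>& lo, std::vector<int>& hi,
                             std::vector<double>& wlo) {
  // output coordinate i maps to input coordinate (i + 0.5)/2 - 0.5
  lo.resize(2 * n); hi.resize(2 * n); wlo.resize(2 * n);
  for (int i = 0; i < 2 * n; ++i) {
    double f = (i + 0.5) / 2.0 - 0.5;
    int i0 = (int)std::floor(f);
    double w1 = f - i0;
    int i1 = i0 + 1;
    if (i0 < 0) i0 = 0;
    if (i1 > n - 1) i1 = n - 1;
    lo[i] = i0; hi[i] = i1; wlo[i] = 1.0 - w1;
  }
}

// Trilinear 2x upsampling (half-voxel aligned, edge-clamped).
// [[Rcpp::export]]
NumericVector upsample2x_fwd(NumericVector x, int D, int H, int W, int C) {
  std::vector<int> dlo, dhi, hlo, hhi, wlo_i, whi;
  std::vector<double> dw, hw, ww;
  up2x_axis(D, dlo, dhi, dw);
  up2x_axis(H, hlo, hhi, hw);
  up2x_axis(W, wlo_i, whi, ww);
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Do * Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)c * D * H * W;
    double* yc = y.begin() + (R_xlen_t)c * Do * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const R_xlen_t b00 = (R_xlen_t)D * hlo[h] + (R_xlen_t)D * H * wlo_i[w];
        const R_xlen_t b01 = (R_xlen_t)D * hlo[h] + (R_xlen_t)D * H * whi[w];
        const R_xlen_t b10 = (R_xlen_t)D * hhi[h] + (R_xlen_t)D * H * wlo_i[w];
        const R_xlen_t b11 = (R_xlen_t)D * hhi[h] + (R_xlen_t)D * H * whi[w];
        const double wh = hw[h], wwv = ww[w];
        double* out = yc + (R_xlen_t)Do * h + (R_xlen_t)Do * Ho * w;
        for (int d = 0; d < Do; ++d) {
          const int d0 = dlo[d], d1 = dhi[d];
          const double wd = dw[d];
          const double v00 = wd * xc[b00 + d0] + (1 - wd) * xc[b00 + d1];
          const double v01 = wd * xc[b01 + d0] + (1 - wd) * xc[b01 + d1];
          const double v10 = wd * xc[b10 + d0] + (1 - wd) * xc[b10 + d1];
          const double v11 = wd * xc[b11 + d0] + (1 - wd) * xc[b11 + d1];
          out[d] = wwv * (wh * v00 + (1 - wh) * v10) +
                   (1 - wwv) * (wh * v01 + (1 - wh) * v11);
        }
      }
  }
  return y;
}

// Adjoint of upsample2x_fwd: scatter output-gradients back to input voxels.
// [[Rcpp::export]]
NumericVector upsample2x_bwd(NumericVector dy, int D, int H, int W, int C) {
  std::vector<int> dlo, dhi, hlo, hhi, wlo_i, whi;
  std::vector<double> dw, hw, ww;
  up2x_axis(D, dlo, dhi, dw);
  up2x_axis(H, hlo, hhi, hw);
  up2x_axis(W, wlo_i, whi, ww);
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((R_xlen_t)D * H * W * C);
  for (int c = 0; c < C; ++c) {
    double* xc = dx.begin() + (R_xlen_t)c * D * H * W;
    const double* yc = dy.begin() + (R_xlen_t)c * Do * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const R_xlen_t b00 = (R_xlen_t)D * hlo[h] + (R_xlen_t)D * H * wlo_i[w];
        const R_xlen_t b01 = (R_xlen_t)D * hlo[h] + (R_xlen_t)D * H * whi[w];
        const R_xlen_t b10 = (R_xlen_t)D * hhi[h] + (R_xlen_t)D * H * wlo_i[w];
        const R_xlen_t b11 = (R_xlen_t)D * hhi[h] + (R_xlen_t)D * H * whi[w];
        const double wh = hw[h], wwv = ww[w];
        const double* g = yc + (R_xlen_t)Do * h + (R_xlen_t)Do * Ho * w;
        for (int d = 0; d < Do; ++d) {
          const int d0 = dlo[d], d1 = dhi[d];
          const double wd = dw[d];
          const double g00 = g[d] * wwv * wh, g10 = g[d] * wwv * (1 - wh);
          const double g01 = g[d] * (1 - wwv) * wh, g11 = g[d] * (1 - wwv) * (1 - wh);
          xc[b00 + d0] += wd * g00; xc[b00 + d1] += (1 - wd) * g00;
          xc[b10 + d0] += wd * g10; xc[b10 + d1] += (1 - wd) * g10;
          xc[b01 + d0] += wd * g01; xc[b01 + d1] += (1 - wd) * g01;
          xc[b11 + d0] += wd * g11; xc[b11 + d1] += (1 - wd) * g11;
        }
      }
  }
  return dx;
}

// One-dimensional squared-distance transform (lower envelope of parabolas),
// exact for arbitrary sample spacing s. "Absent" sources carry a large
// finite sentinel so the envelope arithmetic stays well defined.
static const double DT_BIG = 1e15;

static void dt1d(const double* f, double* out, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  v.resize(n); z.resize(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    const double sq = (double)q * s;
    double sv = (double)v[k] * s;
    double inter = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
    while (k > 0 && inter <= z[k]) {
      --k;
      sv = (double)v[k] * s;
      inter = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
    }
    ++k;
    v[k] = q; z[k] = inter; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    const double sv = (double)v[k] * s;
    out[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3D logical mask with anisotropic
// voxel spacing: returns, per voxel, the distance to the nearest TRUE voxel
// (Inf if the mask is empty).
// [[Rcpp::export]]
NumericVector edt3d(LogicalVector mask, int D, int H, int W, NumericVector spacing) {
  const R_xlen_t N = (R_xlen_t)D * H * W;
  std::vector<double> f(N);
  for (R_xlen_t i = 0; i < N; ++i) f[i] = mask[i] ? 0.0 : DT_BIG;
  std::vector<int> v; std::vector<double> z;
  const int mx = std::max(D, std::max(H, W));
  std::vector<double> line(mx), out(mx);
  // depth axis (contiguous)
  for (R_xlen_t w = 0; w < W; ++w)
    for (R_xlen_t h = 0; h < H; ++h) {
      double* p = &f[(R_xlen_t)D * h + (R_xlen_t)D * H * w];
      dt1d(p, out.data(), D, spacing[0], v, z);
      std::copy(out.begin(), out.begin() + D, p);
    }
  // height axis
  for (R_xlen_t w = 0; w < W; ++w)
    for (R_xlen_t d = 0; d < D; ++d) {
      for (int h = 0; h < H; ++h) line[h] = f[d + (R_xlen_t)D * h + (R_xlen_t)D * H * w];
      dt1d(line.data(), out.data(), H, spacing[1], v, z);
      for (int h = 0; h < H; ++h) f[d + (R_xlen_t)D * h + (R_xlen_t)D * H * w] = out[h];
    }
  // width axis
  for (R_xlen_t h = 0; h < H; ++h)
    for (R_xlen_t d = 0; d < D; ++d) {
      for (int w = 0; w < W; ++w) line[w] = f[d + (R_xlen_t)D * h + (R_xlen_t)D * H * w];
      dt1d(line.data(), out.data(), W, spacing[2], v, z);
      for (int w = 0; w < W; ++w) f[d + (R_xlen_t)D * h + (R_xlen_t)D * H * w] = out[w];
    }
  NumericVector res(N);
  for (R_xlen_t i = 0; i < N; ++i)
    res[i] = (f[i] >= DT_BIG / 2) ? R_PosInf : std::sqrt(f[i]);
  return res;
}

// Build the patch matrix for one width-plane w: rows = D*H voxels of the
// plane, cols = k^3 * C patch entries.
static void vol2col_plane(const double* x, int D, int H, int W, int C, int k,
                          int w, double* cols) {
  const int p = (k - 1) / 2;
  const R_xlen_t DH = (R_xlen_t)D * H;
  const R_xlen_t chan = DH * W;
  const int kk = k * k * k;
  std::fill(cols, cols + DH * (R_xlen_t)kk * C, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)c * chan;
    for (int ow = 0; ow < k; ++ow) {
      const int sw = w + ow - p;
      if (sw < 0 || sw >= W) continue;
      for (int oh = 0; oh < k; ++oh)
        for (int od = 0; od < k; ++od) {
          const int o = od + k * (oh + k * ow);
          double* col = cols + DH * (o + (R_xlen_t)kk * c);
          const int dz = od - p, dy = oh - p;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dy;
            if (sh < 0 || sh >= H) continue;
            double* dst = col + (R_xlen_t)h * D;
            const double* src = xc + (R_xlen_t)sh * D + (R_xlen_t)sw * DH;
            const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
            for (int d = d0; d < d1; ++d) dst[d] = src[d + dz];
          }
        }
    }
  }
}

// Adjoint: scatter one plane's patch-gradient matrix back into dx.
static void col2vol_plane(const double* cols, int D, int H, int W, int C, int k,
                          int w, double* dx) {
  const int p = (k - 1) / 2;
  const R_xlen_t DH = (R_xlen_t)D * H;
  const R_xlen_t chan = DH * W;
  const int kk = k * k * k;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (R_xlen_t)c * chan;
    for (int ow = 0; ow < k; ++ow) {
      const int sw = w + ow - p;
      if (sw < 0 || sw >= W) continue;
      for (int oh = 0; oh < k; ++oh)
        for (int od = 0; od < k; ++od) {
          const int o = od + k * (oh + k * ow);
          const double* col = cols + DH * (o + (R_xlen_t)kk * c);
          const int dz = od - p, dy = oh - p;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dy;
            if (sh < 0 || sh >= H) continue;
            const double* src = col + (R_xlen_t)h * D;
            double* dst = xc + (R_xlen_t)sh * D + (R_xlen_t)sw * DH;
            const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
            for (int d = d0; d < d1; ++d) dst[d + dz] += src[d];
          }
        }
    }
  }
}

// Stride-1, same-padding 3D convolution: y = conv(x; Wm) + b, with Wm the
// (k^3*Cin) x Cout patch-weight matrix. Tiled over width-planes with BLAS
// GEMMs so no full patch matrix is ever materialized.
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, int D, int H, int W, int Cin,
                         NumericMatrix Wm, NumericVector b, int k) {
  const int Cout = Wm.ncol();
  const int kr = Wm.nrow();           // k^3 * Cin
  const R_xlen_t DH = (R_xlen_t)D * H;
  const R_xlen_t N = DH * W;
  NumericVector y(N * Cout);
  std::vector<double> cols(DH * (R_xlen_t)kr);
  const double one = 1.0, zero = 0.0;
  const int m = (int)DH;
  for (int w = 0; w < W; ++w) {
    vol2col_plane(x.begin(), D, H, W, Cin, k, w, cols.data());
    const int ldc = (int)N;
    F77_CALL(dgemm)("N", "N", &m, &Cout, &kr, &one, cols.data(), &m,
                    REAL(Wm), &kr, &zero, y.begin() + w * DH, &ldc
                    FCONE FCONE);
  }
  for (int c = 0; c < Cout; ++c) {
    double* yc = y.begin() + (R_xlen_t)c * N;
    const double bc = b[c];
    for (R_xlen_t i = 0; i < N; ++i) yc[i] += bc;
  }
  return y;
}

// Backward of conv3d_fwd: recomputes the per-plane patch matrices and
// returns dx, dW and db.
// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector dy, int D, int H, int W,
                int Cin, NumericMatrix Wm, int k) {
  const int Cout = Wm.ncol();
  const int kr = Wm.nrow();
  const R_xlen_t DH = (R_xlen_t)D * H;
  const R_xlen_t N = DH * W;
  NumericVector dx(N * Cin);
  NumericMatrix dW(kr, Cout);
  NumericVector db(Cout);
  std::vector<double> cols(DH * (R_xlen_t)kr);
  std::vector<double> dcols(DH * (R_xlen_t)kr);
  const double one = 1.0, zero = 0.0;
  const int m = (int)DH;
  const int ldy = (int)N;
  for (int w = 0; w < W; ++w) {
    vol2col_plane(x.begin(), D, H, W, Cin, k, w, cols.data());
    // dW += cols^T %*% dy_plane
    F77_CALL(dgemm)("T", "N", &kr, &Cout, &m, &one, cols.data(), &m,
                    dy.begin() + w * DH, &ldy, &one, REAL(dW), &kr
                    FCONE FCONE);
    // dcols = dy_plane %*% Wm^T
    F77_CALL(dgemm)("N", "T", &m, &kr, &Cout, &one, dy.begin() + w * DH, &ldy,
                    REAL(Wm), &kr, &zero, dcols.data(), &m FCONE FCONE);
    col2vol_plane(dcols.data(), D, H, W, Cin, k, w, dx.begin());
  }
  for (int c = 0; c < Cout; ++c) {
    const double* dyc = dy.begin() + (R_xlen_t)c * N;
    double s = 0.0;
    for (R_xlen_t i = 0; i < N; ++i) s += dyc[i];
    db[c] = s;
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Row-wise max of a numeric matrix (hot path: channelwise softmax).
// [[Rcpp::export]]
NumericVector row_max(NumericMatrix m) {
  const R_xlen_t n = m.nrow();
  const int C = m.ncol();
  NumericVector out(n);
  std::copy(&m(0, 0), &m(0, 0) + n, out.begin());
  for (int c = 1; c < C; ++c) {
    const double* col = &m(0, c);
    for (R_xlen_t i = 0; i < n; ++i) if (col[i] > out[i]) out[i] = col[i];
  }
  return out;
}

// Label 6-connected components of a 3D logical mask (1-based ids, 0 = not
// in mask), by iterative flood fill.
// [[Rcpp::export]]
IntegerVector label_components6(LogicalVector mask, int D, int H, int W) {
  const R_xlen_t N = (R_xlen_t)D * H * W;
  IntegerVector lab(N);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int dD[6] = {1, -1, 0, 0, 0, 0};
  const int dH[6] = {0, 0, 1, -1, 0, 0};
  const int dW[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int d = (int)(v % D);
      const int h = (int)((v / D) % H);
      const int w = (int)(v / ((R_xlen_t)D * H));
      for (int k = 0; k < 6; ++k) {
        const int nd = d + dD[k], nh = h + dH[k], nw = w + dW[k];
        if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
        const R_xlen_t u = nd + (R_xlen_t)D * nh + (R_xlen_t)D * H * nw;
        if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}
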