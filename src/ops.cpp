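#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Activation layout used throughout: a numeric matrix with
// nrow = H * W * N (each sample stored column-major as an H x W slab,
// samples stacked along rows) and ncol = C channels.  Row index of pixel
// (y, x) of sample n is n*H*W + x*H + y (all 0-based here).

// Extract 3x3 neighbourhoods (zero padding 1) so that a 3x3 convolution
// becomes a single matrix product patches %*% W with W of dim (9*C, Cout).
// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& x, int H, int W, int N) {
  const int C = x.ncol();
  const int HW = H * W;
  const int R = x.nrow();
  NumericMatrix out(R, 9 * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * R;
    for (int t = 0; t < 9; ++t) {
      const int dy = t % 3 - 1;
      const int dx = t / 3 - 1;
      double* oc = op + (size_t)(c * 9 + t) * R;
      for (int n = 0; n < N; ++n) {
        const int base = n * HW;
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        const int len = y1 - y0;
        if (len <= 0) continue;
        for (int xx = x0; xx < x1; ++xx) {
          std::memcpy(oc + base + xx * H + y0,
                      xc + base + (xx + dx) * H + y0 + dy,
                      len * sizeof(double));
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& dp, int H, int W, int N, int C) {
  const int HW = H * W;
  const int R = dp.nrow();
  NumericMatrix dx_(R, C);
  const double* pp = dp.begin();
  double* gp = dx_.begin();
  for (int c = 0; c < C; ++c) {
    double* gc = gp + (size_t)c * R;
    for (int t = 0; t < 9; ++t) {
      const int dy = t % 3 - 1;
      const int dx = t / 3 - 1;
      const double* pc = pp + (size_t)(c * 9 + t) * R;
      for (int n = 0; n < N; ++n) {
        const int base = n * HW;
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        for (int xx = x0; xx < x1; ++xx) {
          double* g = gc + base + (xx + dx) * H + y0 + dy;
          const double* p = pc + base + xx * H + y0;
          for (int k = 0; k < y1 - y0; ++k) g[k] += p[k];
        }
      }
    }
  }
  return dx_;
}

// Fused per-column affine transform: out[r, c] = x[r, c] * mult[c] + add[c].
// [[Rcpp::export]]
NumericMatrix colop(const NumericMatrix& x, const NumericVector& mult,
                    const NumericVector& add) {
  const int R = x.nrow(), C = x.ncol();
  NumericMatrix out(R, C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double m = mult[c], a = add[c];
    const double* xc = xp + (size_t)c * R;
    double* oc = op + (size_t)c * R;
    for (int r = 0; r < R; ++r) oc[r] = xc[r] * m + a;
  }
  return out;
}

// 2x2 max pooling (stride 2).  Returns the pooled activations and, for the
// backward pass, the 1-based row index of the winning input pixel.
// [[Rcpp::export]]
List maxpool2(const NumericMatrix& x, int H, int W, int N) {
  const int C = x.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const int HWo = Ho * Wo, HW = H * W;
  const int R = x.nrow(), Ro = HWo * N;
  NumericMatrix out(Ro, C);
  IntegerMatrix idx(Ro, C);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * R;
    double* oc = op + (size_t)c * Ro;
    int* ic = ip + (size_t)c * Ro;
    for (int n = 0; n < N; ++n) {
      const int obase = n * HWo, ibase = n * HW;
      for (int xx = 0; xx < Wo; ++xx) {
        const int col0 = ibase + (2 * xx) * H;
        for (int yy = 0; yy < Ho; ++yy) {
          int best = col0 + 2 * yy;
          double bv = xc[best];
          const int cand[3] = {best + 1, best + H, best + H + 1};
          for (int k = 0; k < 3; ++k)
            if (xc[cand[k]] > bv) { bv = xc[cand[k]]; best = cand[k]; }
          oc[obase + xx * Ho + yy] = bv;
          ic[obase + xx * Ho + yy] = best + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_bw(const NumericMatrix& dout, const IntegerMatrix& idx,
                          int nrow_in) {
  const int C = dout.ncol();
  const int Ro = dout.nrow();
  NumericMatrix dx_(nrow_in, C);
  const double* dp = dout.begin();
  const int* ip = idx.begin();
  double* gp = dx_.begin();
  for (int c = 0; c < C; ++c) {
    const double* dc = dp + (size_t)c * Ro;
    const int* ic = ip + (size_t)c * Ro;
    double* gc = gp + (size_t)c * nrow_in;
    for (int r = 0; r < Ro; ++r) gc[ic[r] - 1] += dc[r];
  }
  return dx_;
}

static inline void up_taps(int i, int n_in, int& i0, int& i1, double& w1) {
  // output pixel centre mapped into input coordinates (half-pixel centres)
  double u = (i + 0.5) / 2.0 - 0.5;
  if (u < 0) u = 0;
  if (u > n_in - 1) u = n_in - 1;
  i0 = (int)std::floor(u);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = u - i0;
}

// Bilinear 2x upsampling.
// [[Rcpp::export]]
NumericMatrix upsample2(const NumericMatrix& x, int H, int W, int N) {
  const int C = x.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  const int HW = H * W, HWo = Ho * Wo;
  const int R = x.nrow(), Ro = HWo * N;
  std::vector<int> y0(Ho), y1(Ho), xs0(Wo), xs1(Wo);
  std::vector<double> wy(Ho), wx(Wo);
  for (int i = 0; i < Ho; ++i) up_taps(i, H, y0[i], y1[i], wy[i]);
  for (int i = 0; i < Wo; ++i) up_taps(i, W, xs0[i], xs1[i], wx[i]);
  NumericMatrix out(Ro, C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * R;
    double* oc = op + (size_t)c * Ro;
    for (int n = 0; n < N; ++n) {
      const int obase = n * HWo, ibase = n * HW;
      for (int xx = 0; xx < Wo; ++xx) {
        const double* ca = xc + ibase + xs0[xx] * H;
        const double* cb = xc + ibase + xs1[xx] * H;
        const double wxx = wx[xx];
        double* ocol = oc + obase + xx * Ho;
        for (int yy = 0; yy < Ho; ++yy) {
          const double a = ca[y0[yy]] * (1 - wy[yy]) + ca[y1[yy]] * wy[yy];
          const double b = cb[y0[yy]] * (1 - wy[yy]) + cb[y1[yy]] * wy[yy];
          ocol[yy] = a * (1 - wxx) + b * wxx;
        }
      }
    }
  }
  return out;
}

// Adjoint of upsample2.
// [[Rcpp::export]]
NumericMatrix upsample2_bw(const NumericMatrix& dout, int H, int W, int N) {
  const int C = dout.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  const int HW = H * W, HWo = Ho * Wo;
  const int Ro = dout.nrow(), R = HW * N;
  std::vector<int> y0(Ho), y1(Ho), xs0(Wo), xs1(Wo);
  std::vector<double> wy(Ho), wx(Wo);
  for (int i = 0; i < Ho; ++i) up_taps(i, H, y0[i], y1[i], wy[i]);
  for (int i = 0; i < Wo; ++i) up_taps(i, W, xs0[i], xs1[i], wx[i]);
  NumericMatrix dx_(R, C);
  const double* dp = dout.begin();
  double* gp = dx_.begin();
  for (int c = 0; c < C; ++c) {
    const double* dc = dp + (size_t)c * Ro;
    double* gc = gp + (size_t)c * R;
    for (int n = 0; n < N; ++n) {
      const int obase = n * HWo, ibase = n * HW;
      for (int xx = 0; xx < Wo; ++xx) {
        double* ca = gc + ibase + xs0[xx] * H;
        double* cb = gc + ibase + xs1[xx] * H;
        const double wxx = wx[xx];
        const double* dcol = dc + obase + xx * Ho;
        for (int yy = 0; yy < Ho; ++yy) {
          const double g = dcol[yy];
          ca[y0[yy]] += g * (1 - wxx) * (1 - wy[yy]);
          ca[y1[yy]] += g * (1 - wxx) * wy[yy];
          cb[y0[yy]] += g * wxx * (1 - wy[yy]);
          cb[y1[yy]] += g * wxx * wy[yy];
        }
      }
    }
  }
  return dx_;
}

// Connected-component labelling of a 2D binary image, 4- or 8-connectivity,
// depth-first flood fill.  Labels are 1..k in raster-scan discovery order.
// [[Rcpp::export]]
IntegerMatrix label_cc(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int xx = 0; xx < W; ++xx) {
    for (int yy = 0; yy < H; ++yy) {
      if (mask(yy, xx) == 0 || lab(yy, xx) != 0) continue;
      ++next;
      stack.push_back(xx * H + yy);
      lab(yy, xx) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int py = p % H, px = p / H;
        for (int k = 0; k < nn; ++k) {
          const int qy = py + dy8[k], qx = px + dx8[k];
          if (qy < 0 || qy >= H || qx < 0 || qx >= W) continue;
          if (mask(qy, qx) != 0 && lab(qy, qx) == 0) {
            lab(qy, qx) = next;
            stack.push_back(qx * H + qy);
          }
        }
      }
    }
  }
  return lab;
}
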