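#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Half-sample symmetric reflection: index into [0, n) with edge repetition,
// the padding dialect used throughout the package.  It preserves the global
// mean under symmetric normalized kernels, which the gray-level metrics rely on.
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static NumericMatrix mirror_pad(const NumericMatrix& x, int pad) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H + 2 * pad, W + 2 * pad);
  for (int j = 0; j < W + 2 * pad; ++j) {
    const int sj = reflect(j - pad, W);
    for (int i = 0; i < H + 2 * pad; ++i)
      out(i, j) = x(reflect(i - pad, H), sj);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_mirror_pad(NumericMatrix x, int pad) {
  return mirror_pad(x, pad);
}

// Fast double-precision exp(-x) for x >= 0 via 2^k/256 table and a short
// Taylor tail; max relative error ~1e-15, i.e. indistinguishable from libm
// at the tolerances used anywhere in this package, but several times faster
// (the weight kernel is evaluated tens of millions of times per image).
static double exp2_table[256];
static bool exp2_table_ready = false;
static inline void init_exp_table() {
  if (!exp2_table_ready) {
    for (int i = 0; i < 256; ++i) exp2_table[i] = std::pow(2.0, -i / 256.0);
    exp2_table_ready = true;
  }
}
static inline double exp_neg(double x) {
  if (x > 708.0) return 0.0;
  const double invln2_256 = 369.3299304675746271;   // 256 / ln 2
  const double ln2_256 = 0.002707606173999011;      // ln 2 / 256
  const double k = std::nearbyint(x * invln2_256);
  const double r = x - k * ln2_256;                 // |r| <= ln2/512
  // exp(-r) by degree-4 Taylor: error < 4e-17 on this range
  const double er = 1.0 - r * (1.0 - r * (0.5 - r * (1.0 / 6.0 - r * (1.0 / 24.0))));
  const long ik = static_cast<long>(k);
  return std::ldexp(exp2_table[ik & 255], -static_cast<int>(ik >> 8)) * er;
}

// ROAD statistic: sum of the L smallest |u_i - u_j| over the (2*radius+1)^2
// neighborhood of each pixel, center excluded.
// [[Rcpp::export]]
NumericMatrix cpp_road(NumericMatrix img, int radius, int L) {
  const int H = img.nrow(), W = img.ncol();
  const int n_nb = (2 * radius + 1) * (2 * radius + 1) - 1;
  if (L < 1 || L > n_nb) stop("road_L must lie in [1, neighborhood size - 1]");
  NumericMatrix pad = mirror_pad(img, radius);
  NumericMatrix out(H, W);
  std::vector<double> d(n_nb);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double c = pad(i + radius, j + radius);
      int k = 0;
      for (int dj = -radius; dj <= radius; ++dj)
        for (int di = -radius; di <= radius; ++di) {
          if (di == 0 && dj == 0) continue;
          d[k++] = std::fabs(pad(i + radius + di, j + radius + dj) - c);
        }
      std::partial_sort(d.begin(), d.begin() + L, d.end());
      double s = 0.0;
      for (int m = 0; m < L; ++m) s += d[m];
      out(i, j) = s;
    }
  }
  return out;
}

// Probability-weighted non-local means restoration.
//
// For every search offset t the probability-weighted squared patch distance
//   d2(i, i+t) = (1/(2f+1)^2) * sum_k [ min(p_{i+k}, p_{i+t+k}) * (u_{i+k} - u_{i+t+k}) ]^2
// is a (2f+1)^2 box sum of a per-offset difference image, so the whole filter
// runs in O(H * W * (2r+1)^2) independent of patch size.  The center pixel
// enters with the maximum weight observed among its competitors (standard NLM
// self-weight rule), times its own undamaged probability.
// [[Rcpp::export]]
NumericMatrix cpp_pnlm(NumericMatrix img, NumericMatrix P,
                       int r, int f, double h) {
  const int H = img.nrow(), W = img.ncol();
  if (P.nrow() != H || P.ncol() != W) stop("probability map shape mismatch");
  if (h <= 0) stop("bandwidth h must be > 0");
  init_exp_table();
  const int pad = r + f;
  NumericMatrix U = mirror_pad(img, pad);
  NumericMatrix Q = mirror_pad(P, pad);
  const int Hp = H + 2 * f, Wp = W + 2 * f;   // region needing q values
  std::vector<double> q(Hp * Wp), colsum(Hp * Wp);
  std::vector<double> num(H * W, 0.0), den(H * W, 0.0), wmax(H * W, 0.0);
  const double inv_patch = 1.0 / ((2 * f + 1) * (2 * f + 1));
  const double inv_h2 = 1.0 / (h * h);

  for (int tj = -r; tj <= r; ++tj) {
    for (int ti = -r; ti <= r; ++ti) {
      if (ti == 0 && tj == 0) continue;
      // q over the core extended by f on all sides; (x,y) indexes U at (x+r, y+r)
      for (int y = 0; y < Wp; ++y) {
        const int uy = y + r, vy = y + r + tj;
        for (int x = 0; x < Hp; ++x) {
          const double du = U(x + r, uy) - U(x + r + ti, vy);
          const double pm = std::min(Q(x + r, uy), Q(x + r + ti, vy));
          q[x + y * Hp] = pm * pm * du * du;
        }
      }
      // vertical running sums of height 2f+1: colsum[x, y] = sum q[x..x+2f, y]
      for (int y = 0; y < Wp; ++y) {
        double s = 0.0;
        const double* qc = &q[y * Hp];
        for (int x = 0; x < 2 * f; ++x) s += qc[x];
        for (int x = 0; x + 2 * f < Hp; ++x) {
          s += qc[x + 2 * f];
          colsum[x + y * Hp] = s;
          s -= qc[x];
        }
      }
      // horizontal running sums of width 2f+1, then accumulate weights
      for (int i = 0; i < H; ++i) {
        double s = 0.0;
        for (int y = 0; y < 2 * f; ++y) s += colsum[i + y * Hp];
        for (int j = 0; j + 2 * f < Wp; ++j) {
          s += colsum[i + (j + 2 * f) * Hp];
          const double d2 = s * inv_patch;
          s -= colsum[i + j * Hp];
          const double w = exp_neg(d2 * inv_h2);
          const int idx = i + j * H;
          const double pj = Q(i + pad + ti, j + pad + tj);
          num[idx] += w * pj * U(i + pad + ti, j + pad + tj);
          den[idx] += w * pj;
          if (w > wmax[idx]) wmax[idx] = w;
        }
      }
    }
  }

  NumericMatrix out(H, W);
  int fallback = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int idx = i + j * H;
      const double u0 = img(i, j), p0 = P(i, j);
      const double nn = num[idx] + wmax[idx] * p0 * u0;
      const double dd = den[idx] + wmax[idx] * p0;
      if (dd > 0) out(i, j) = nn / dd;
      else { out(i, j) = u0; ++fallback; }
    }
  if (fallback > 0)
    Rf_warning("pnlm: %d pixels had degenerate all-zero weights; kept input value", fallback);
  return out;
}

// Separable convolution with a symmetric normalized 1-D kernel, mirror padding.
// [[Rcpp::export]]
NumericMatrix cpp_sep_conv(NumericMatrix img, NumericVector kernel) {
  const int H = img.nrow(), W = img.ncol();
  const int K = kernel.size();
  if (K % 2 == 0) stop("kernel length must be odd");
  const int f = K / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // along rows (vertical)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int k = -f; k <= f; ++k) s += kernel[k + f] * img(reflect(i + k, H), j);
      tmp(i, j) = s;
    }
  // along columns (horizontal)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int k = -f; k <= f; ++k) s += kernel[k + f] * tmp(i, reflect(j + k, W));
      out(i, j) = s;
    }
  return out;
}

// Replace only masked pixels by the median of their (window x window)
// neighborhood in the input image; all other pixels are returned untouched.
// [[Rcpp::export]]
NumericMatrix cpp_masked_median(NumericMatrix img, LogicalMatrix mask, int window) {
  const int H = img.nrow(), W = img.ncol();
  if (mask.nrow() != H || mask.ncol() != W) stop("mask shape mismatch");
  if (window < 1 || window % 2 == 0) stop("window must be a positive odd integer");
  const int f = window / 2;
  NumericMatrix out = clone(img);
  std::vector<double> buf(window * window);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int k = 0;
      for (int dj = -f; dj <= f; ++dj)
        for (int di = -f; di <= f; ++di)
          buf[k++] = img(reflect(i + di, H), reflect(j + dj, W));
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];   // odd count: exact median
    }
  return out;
}

// Two-stage adaptive median filter (window grows until the median is not an
// extremum, then the center is replaced only if it is itself an extremum).
// [[Rcpp::export]]
NumericMatrix cpp_adaptive_median(NumericMatrix img, int max_window) {
  const int H = img.nrow(), W = img.ncol();
  if (max_window < 3 || max_window % 2 == 0) stop("max_window must be odd and >= 3");
  NumericMatrix out(H, W);
  std::vector<double> buf(max_window * max_window);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double z = img(i, j);
      double res = z;
      for (int w = 3; w <= max_window; w += 2) {
        const int f = w / 2;
        int k = 0;
        for (int dj = -f; dj <= f; ++dj)
          for (int di = -f; di <= f; ++di)
            buf[k++] = img(reflect(i + di, H), reflect(j + dj, W));
        std::sort(buf.begin(), buf.begin() + k);
        const double zmin = buf[0], zmax = buf[k - 1], zmed = buf[k / 2];
        if (zmed > zmin && zmed < zmax) {          // stage A: usable median
          res = (z > zmin && z < zmax) ? z : zmed; // stage B: impulse test
          break;
        }
        res = zmed;                                // window exhausted
      }
      out(i, j) = res;
    }
  return out;
}
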