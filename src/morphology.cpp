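#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Non-flat (grayscale) erosion/dilation with a ball structuring element,
// applied per 2D slice. The ball of radius r has height profile
// h(dx,dy) = sqrt(r^2 - dx^2 - dy^2); the rolling-ball background is the
// grayscale opening (erode then dilate) with that element. Out-of-bounds
// offsets are skipped (equivalent to +Inf / -Inf padding).

static void ball_offsets(double radius, std::vector<int> &dx,
                         std::vector<int> &dy, std::vector<double> &h) {
  int r = (int)std::floor(radius);
  for (int j = -r; j <= r; ++j) {
    for (int i = -r; i <= r; ++i) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= radius * radius) {
        dx.push_back(i);
        dy.push_back(j);
        h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_background(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dx, dy;
  std::vector<double> h;
  ball_offsets(radius, dx, dy, h);
  size_t K = h.size();
  NumericMatrix ero(nr, nc), bg(nr, nc);
  std::fill(ero.begin(), ero.end(), R_PosInf);
  std::fill(bg.begin(), bg.end(), R_NegInf);
  // offset-outer loops keep the inner loop contiguous in memory
  const double *im = img.begin();
  double *er = ero.begin(), *bgp = bg.begin();
  for (size_t k = 0; k < K; ++k) {
    int oy = dy[k], ox = dx[k];
    double hk = h[k];
    int c0 = std::max(0, -ox), c1 = std::min(nc, nc - ox);
    int r0 = std::max(0, -oy), r1 = std::min(nr, nr - oy);
    for (int c = c0; c < c1; ++c) {
      const double *src = im + (size_t)(c + ox) * nr + (r0 + oy);
      double *dst = er + (size_t)c * nr + r0;
      for (int r = 0; r < r1 - r0; ++r) {
        double v = src[r] - hk;
        if (v < dst[r]) dst[r] = v;
      }
    }
  }
  for (size_t k = 0; k < K; ++k) {
    int oy = dy[k], ox = dx[k];
    double hk = h[k];
    int c0 = std::max(0, -ox), c1 = std::min(nc, nc - ox);
    int r0 = std::max(0, -oy), r1 = std::min(nr, nr - oy);
    for (int c = c0; c < c1; ++c) {
      const double *src = er + (size_t)(c + ox) * nr + (r0 + oy);
      double *dst = bgp + (size_t)c * nr + r0;
      for (int r = 0; r < r1 - r0; ++r) {
        double v = src[r] + hk;
        if (v > dst[r]) dst[r] = v;
      }
    }
  }
  return bg;
}

// Separable Gaussian blur of a 2D slice, reflected boundaries,
// kernel truncated at 4 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int hw = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * hw + 1);
  double s = 0;
  for (int i = -hw; i <= hw; ++i) {
    k[i + hw] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + hw];
  }
  for (auto &v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // rows direction
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -hw; i <= hw; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= nr) rr = 2 * nr - rr - 1;
        acc += k[i + hw] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  }
  // columns direction
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int i = -hw; i <= hw; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= nc) cc = 2 * nc - cc - 1;
        acc += k[i + hw] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// 6-connected component labelling of a 3D logical mask (dims z, y, x,
// column-major as stored by R). Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(idx);
    lab[idx] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur % nz, rest = cur / nz;
      int y = rest % ny, x = rest / ny;
      const int dz[6] = {1, -1, 0, 0, 0, 0};
      const int dy6[6] = {0, 0, 1, -1, 0, 0};
      const int dx6[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy6[k], xx = x + dx6[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int nidx = zz + nz * (yy + ny * xx);
        if (mask[nidx] && lab[nidx] == 0) {
          lab[nidx] = next;
          stack.push_back(nidx);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
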