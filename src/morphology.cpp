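#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3-D connected-component labeling, 26-connectivity, on a (ny, nx, nz)
// logical/integer mask. Returns an integer array of the same shape with
// consecutive labels 1..K (0 = background). Iterative flood fill: large
// organoid stacks would overflow the C stack with recursion.
// [[Rcpp::export]]
IntegerVector cc_label_26(LogicalVector mask, int ny, int nx, int nz) {
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(4096);
  int next = 0;
  const R_xlen_t sy = 1, sx = ny, sz = (R_xlen_t)ny * nx;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      R_xlen_t z = v / sz, rem = v % sz;
      R_xlen_t x = rem / ny, y = rem % ny;
      for (int dz = -1; dz <= 1; ++dz) {
        R_xlen_t zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          R_xlen_t xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            R_xlen_t yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            R_xlen_t w = yy * sy + xx * sx + zz * sz;
            if (mask[w] && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(ny, nx, nz);
  return lab;
}

static void conv_axis(std::vector<double>& a, int ny, int nx, int nz,
                      const std::vector<double>& k, int axis) {
  int half = ((int)k.size() - 1) / 2;
  if (half == 0) return;
  R_xlen_t sy = 1, sx = ny, sz = (R_xlen_t)ny * nx;
  R_xlen_t stride = axis == 0 ? sy : (axis == 1 ? sx : sz);
  int len = axis == 0 ? ny : (axis == 1 ? nx : nz);
  std::vector<double> line(len);
  R_xlen_t nlines = (R_xlen_t)ny * nx * nz / len;
  for (R_xlen_t l = 0; l < nlines; ++l) {
    // base index of this line (reflect boundary)
    R_xlen_t base;
    if (axis == 0) {
      base = (l % nx) * sx + (l / nx) * sz;
    } else if (axis == 1) {
      base = (l % ny) * sy + (l / ny) * sz;
    } else {
      base = l;  // (y,x) flattened is contiguous
    }
    for (int i = 0; i < len; ++i) line[i] = a[base + (R_xlen_t)i * stride];
    int lo = std::min(half, len), hi = std::max(len - half, lo);
    for (int i = lo; i < hi; ++i) {  // interior: no boundary handling
      double acc = 0.0;
      const double* lp = &line[i - half];
      for (int j = 0; j <= 2 * half; ++j) acc += lp[j] * k[j];
      a[base + (R_xlen_t)i * stride] = acc;
    }
    for (int i = 0; i < len; ++i) {
      if (i >= lo && i < hi) continue;
      double acc = 0.0;
      for (int j = -half; j <= half; ++j) {
        int p = i + j;
        if (p < 0) p = -p - 1;
        if (p >= len) p = 2 * len - p - 1;
        acc += line[p] * k[j + half];
      }
      a[base + (R_xlen_t)i * stride] = acc;
    }
  }
}

// Separable convolution of a (ny,nx,nz) array with 1-D kernels per axis
// (y, x, z order), reflecting at the boundaries. Kernels must have odd length.
// [[Rcpp::export]]
NumericVector conv_sep_3d(NumericVector img, int ny, int nx, int nz,
                          NumericVector ky, NumericVector kx, NumericVector kz) {
  std::vector<double> a(img.begin(), img.end());
  conv_axis(a, ny, nx, nz, std::vector<double>(ky.begin(), ky.end()), 0);
  conv_axis(a, ny, nx, nz, std::vector<double>(kx.begin(), kx.end()), 1);
  conv_axis(a, ny, nx, nz, std::vector<double>(kz.begin(), kz.end()), 2);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(ny, nx, nz);
  return out;
}

// In-place-style scatter-add: out = arr with out[idx[i]] += val[i]
// (1-based indices, duplicates accumulate).
// [[Rcpp::export]]
NumericVector scatter_add(NumericVector arr, NumericVector idx, NumericVector val) {
  NumericVector out = clone(arr);
  const R_xlen_t n = idx.size();
  for (R_xlen_t i = 0; i < n; ++i) out[(R_xlen_t)idx[i] - 1] += val[i];
  return out;
}

// Camera model applied in one pass: Poisson shot noise on positive signal,
// constant background offset, Gaussian read noise, rounded and clamped to
// the 16-bit range. Uses R's RNG stream (deterministic under set.seed).
// [[Rcpp::export]]
NumericVector add_camera_noise(NumericVector img, double background,
                               double read_sd) {
  const R_xlen_t n = img.size();
  NumericVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    double s = img[i];
    if (s > 0) s = R::rpois(s);
    double v = s + background + (read_sd > 0 ? R::rnorm(0.0, read_sd) : 0.0);
    v = std::round(v);
    if (v < 0) v = 0;
    if (v > 65535) v = 65535;
    out[i] = v;
  }
  out.attr("dim") = img.attr("dim");
  return out;
}

// Local maxima of a (ny,nx,nz) array: voxels strictly above `threshold` that
// attain the maximum of their window (half-widths hy, hx, hz per axis).
// Plateau ties are broken by linear index (first voxel of the plateau wins).
// Returns a 3-column (y,x,z) 1-based integer matrix.
// [[Rcpp::export]]
IntegerMatrix local_maxima_3d(NumericVector img, int ny, int nx, int nz,
                              int hy, int hx, int hz, double threshold) {
  std::vector<R_xlen_t> hits;
  const R_xlen_t sx = ny, sz = (R_xlen_t)ny * nx;
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t v = y + (R_xlen_t)x * sx + (R_xlen_t)z * sz;
        double c = img[v];
        if (!(c > threshold)) continue;
        bool ismax = true;
        for (int dz = -hz; dz <= hz && ismax; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dx = -hx; dx <= hx && ismax; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            for (int dy = -hy; dy <= hy; ++dy) {
              int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              R_xlen_t w = yy + (R_xlen_t)xx * sx + (R_xlen_t)zz * sz;
              if (w == v) continue;
              double o = img[w];
              if (o > c || (o == c && w < v)) { ismax = false; break; }
            }
          }
        }
        if (ismax) hits.push_back(v);
      }
    }
  }
  IntegerMatrix out(hits.size(), 3);
  for (size_t i = 0; i < hits.size(); ++i) {
    R_xlen_t v = hits[i];
    out(i, 0) = (int)(v % ny) + 1;
    out(i, 1) = (int)((v % sz) / ny) + 1;
    out(i, 2) = (int)(v / sz) + 1;
  }
  return out;
}
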