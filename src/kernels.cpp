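#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Correlate every column of `m` with the (odd-length) kernel `k`,
// replicate padding at both ends. Building block for separable Gaussian
// smoothing and finite-difference Laplacians. The interior is branch-free
// so the compiler can vectorize it.
// [[Rcpp::export]]
NumericMatrix conv_cols(const NumericMatrix& m, const NumericVector& k) {
  const int n = m.nrow(), nc = m.ncol(), kl = k.size(), h = kl / 2;
  if (kl % 2 == 0) stop("kernel length must be odd");
  NumericMatrix out(n, nc);
  const double* kk = REAL(k);
  for (int c = 0; c < nc; ++c) {
    const double* col = &m(0, c);
    double* o = &out(0, c);
    const int lo = std::min(h, n), hi = std::max(n - h, lo);
    for (int i = 0; i < lo; ++i) {            // top edge (clamped)
      double s = 0.0;
      for (int j = 0; j < kl; ++j) {
        int idx = i + j - h;
        if (idx < 0) idx = 0; else if (idx >= n) idx = n - 1;
        s += col[idx] * kk[j];
      }
      o[i] = s;
    }
    for (int i = lo; i < hi; ++i) {           // interior, branch-free
      double s = 0.0;
      const double* p = col + i - h;
      for (int j = 0; j < kl; ++j) s += p[j] * kk[j];
      o[i] = s;
    }
    for (int i = hi; i < n; ++i) {            // bottom edge (clamped)
      double s = 0.0;
      for (int j = 0; j < kl; ++j) {
        int idx = i + j - h;
        if (idx < 0) idx = 0; else if (idx >= n) idx = n - 1;
        s += col[idx] * kk[j];
      }
      o[i] = s;
    }
  }
  return out;
}

// Strict 26-connected (3x3x3) local maxima of a [z,y,x] array above `thr`.
// Ties on a plateau keep the voxel with the smallest linear index.
// Border voxels are compared against their existing neighbours only.
// Returns a 3-column matrix of 1-based (z, y, x) indices.
// [[Rcpp::export]]
IntegerMatrix local_max3(const NumericVector& a, int nz, int ny, int nx,
                         double thr) {
  std::vector<int> zz, yy, xx;
  const double* p = REAL(a);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t ci = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        const double v = p[ci];
        if (!(v >= thr)) continue;
        bool mx = true;
        for (int dx = -1; dx <= 1 && mx; ++dx) {
          const int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          for (int dy = -1; dy <= 1 && mx; ++dy) {
            const int y2 = y + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              const int z2 = z + dz;
              if (z2 < 0 || z2 >= nz) continue;
              const R_xlen_t ni = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
              if (ni == ci) continue;
              const double w = p[ni];
              if (w > v || (w == v && ni < ci)) { mx = false; break; }
            }
          }
        }
        if (mx) { zz.push_back(z + 1); yy.push_back(y + 1); xx.push_back(x + 1); }
      }
    }
  }
  const int n = zz.size();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = zz[i]; out(i, 1) = yy[i]; out(i, 2) = xx[i];
  }
  return out;
}

// Maximum over the first dimension of a [z,y,x] array -> [y,x] matrix.
// [[Rcpp::export]]
NumericMatrix max_over_dim1(const NumericVector& a, int nz, int ny, int nx) {
  NumericMatrix out(ny, nx);
  const double* p = REAL(a);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      double m = p[base];
      for (int z = 1; z < nz; ++z) {
        const double v = p[base + z];
        if (v > m) m = v;
      }
      out(y, x) = m;
    }
  }
  return out;
}

// 3x3 lateral median filter applied independently to every z-plane of a
// [z,y,x] array (replicate borders). Suppresses single-voxel outliers
// (hot pixels, extreme shot noise) before blob detection.
// [[Rcpp::export]]
NumericVector median3_planes(const NumericVector& a, int nz, int ny, int nx) {
  NumericVector out(a.size());
  const double* p = REAL(a);
  double* o = REAL(out);
  double buf[9];
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int n = 0;
        for (int dx = -1; dx <= 1; ++dx) {
          int x2 = x + dx;
          if (x2 < 0) x2 = 0; else if (x2 >= nx) x2 = nx - 1;
          for (int dy = -1; dy <= 1; ++dy) {
            int y2 = y + dy;
            if (y2 < 0) y2 = 0; else if (y2 >= ny) y2 = ny - 1;
            buf[n++] = p[z + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2)];
          }
        }
        std::nth_element(buf, buf + 4, buf + 9);
        o[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = buf[4];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  return out;
}

// round(x) clamped below at 0, in one pass (integer detector counts).
// [[Rcpp::export]]
NumericVector round_clamp0(const NumericVector& x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = std::nearbyint(x[i]);
    out[i] = v < 0 ? 0.0 : v;
  }
  return out;
}

// Round every element to the nearest IEEE single-precision value,
// returned as double. Defines the stored precision of stack voxels.
// [[Rcpp::export]]
NumericVector round_f32(const NumericVector& x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = (double)(float)x[i];
  return out;
}
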