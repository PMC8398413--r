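#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Flat indexing for 3D arrays stored in R column-major order: i + nx*(j + ny*k)

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (Felzenszwalb & Huttenlocher, lower envelope
// of parabolas). f: input costs, d: output, n: length. v, z: scratch.
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = (q - p) * (double)(q - p) + f[p];
  }
}

// Exact Euclidean distance (in voxel units) from every voxel to the nearest
// voxel with feature == 1. Voxels that are themselves features get 0.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector feature, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = feature[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = &d[(R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      for (int i = 0; i < nx; ++i) f[i] = row[i];
      dt1d(f.data(), dd.data(), nx, v.data(), z.data());
      for (int i = 0; i < nx; ++i) row[i] = dd[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f.data(), dd.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j) d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = dd[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f.data(), dd.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k) d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = dd[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::isinf(d[i]) ? R_PosInf : std::sqrt(d[i]);
  return out;
}

// Connected-component labeling of mask == 1 voxels with 6- or 26-connectivity.
// Labels are assigned in raster-scan discovery order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label(IntegerVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        offs.push_back({dx, dy, dz});
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = cur % nx;
      int j = (cur / nx) % ny;
      int k = cur / ((R_xlen_t)nx * ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Local-thickness map (maximal inscribed sphere, Hildebrand-Rüegsegger style):
// thickness(v) = diameter (in voxels, = 2 * edt of the center) of the largest
// sphere fully inside the phase that contains v. Sphere centers are restricted
// to ridge voxels (those whose sphere is not contained in a neighbour's) and
// spheres are painted in decreasing-radius order.
// edt: distance (voxels) to the complementary phase; mask: phase of interest.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(IntegerVector mask, NumericVector edt,
                                  IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n, 0.0);
  for (R_xlen_t s = 0; s < n; ++s)
    if (mask[s]) th[s] = 2.0 * edt[s];

  // ridge filter: drop v if a 26-neighbour's sphere covers v's sphere
  std::vector<R_xlen_t> centers;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = s % nx;
    int j = (s / nx) % ny;
    int k = s / ((R_xlen_t)nx * ny);
    bool covered = false;
    for (int dz = -1; dz <= 1 && !covered; ++dz)
      for (int dy = -1; dy <= 1 && !covered; ++dy)
        for (int dx = -1; dx <= 1 && !covered; ++dx) {
          if (!dx && !dy && !dz) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (!mask[q]) continue;
          double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
          if (edt[q] >= edt[s] + dist) covered = true;
        }
    if (!covered) centers.push_back(s);
  }

  std::stable_sort(centers.begin(), centers.end(),
                   [&](R_xlen_t a, R_xlen_t b) {
                     if (edt[a] != edt[b]) return edt[a] > edt[b];
                     return a < b;
                   });

  for (size_t c = 0; c < centers.size(); ++c) {
    R_xlen_t s = centers[c];
    double r = edt[s];
    double dia = 2.0 * r;
    double rp = r;            // paint radius (half-voxel-generous coverage)
    if (rp <= 0) continue;
    int ir = (int)std::floor(rp);
    int i = s % nx;
    int j = (s / nx) % ny;
    int k = s / ((R_xlen_t)nx * ny);
    double rp2 = rp * rp;
    for (int dz = -ir; dz <= ir; ++dz) {
      int kk = k + dz;
      if (kk < 0 || kk >= nz) continue;
      for (int dy = -ir; dy <= ir; ++dy) {
        int jj = j + dy;
        if (jj < 0 || jj >= ny) continue;
        double r2yz = (double)dy * dy + (double)dz * dz;
        if (r2yz > rp2) continue;
        int mx = (int)std::floor(std::sqrt(rp2 - r2yz));
        for (int dx = -mx; dx <= mx; ++dx) {
          int ii = i + dx;
          if (ii < 0 || ii >= nx) continue;
          R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (mask[q] && th[q] < dia) th[q] = dia;
        }
      }
    }
  }
  return th;
}

// 26-neighbourhood local maxima of a field restricted to mask == 1
// (value >= all masked neighbours). Returns 0-based flat indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector field, IntegerVector mask,
                               IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> out;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = s % nx;
    int j = (s / nx) % ny;
    int k = s / ((R_xlen_t)nx * ny);
    bool ismax = true;
    for (int dz = -1; dz <= 1 && ismax; ++dz)
      for (int dy = -1; dy <= 1 && ismax; ++dy)
        for (int dx = -1; dx <= 1 && ismax; ++dx) {
          if (!dx && !dy && !dz) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (mask[q] && field[q] > field[s]) ismax = false;
        }
    if (ismax) out.push_back((int)s);
  }
  return IntegerVector(out.begin(), out.end());
}
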