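#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes along x, y, z.  Distances are in voxel
// units, measured between voxel centres.  `site` marks distance-zero voxels.

static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; continue; }
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector site, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = site[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; k++) f[k] = out[base + stride * k];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; k++) out[base + stride * k] = d[k];
    }
  return out;
}

// Local thickness by sphere fitting: for every phase voxel p, the squared
// radius of the largest sphere (centred on some phase voxel c, radius
// sq-root of the distance-to-complement of c) that strictly contains p.
// Containment is |p - c|^2 < r^2(c).  Returns squared radii; thickness map
// is 2*sqrt(out) in voxel units.
// [[Rcpp::export(name = ".local_thickness_sq_cpp")]]
NumericVector local_thickness_sq_cpp(LogicalVector phase, NumericVector r2,
                                     IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::fill(out.begin(), out.end(), 0.0);

  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!phase[idx]) continue;
        double rc2 = r2[idx];
        if (!(rc2 > 0) || !R_finite(rc2)) continue;
        double rc = std::sqrt(rc2);
        // prune centres whose sphere is strictly inside a neighbour's sphere
        bool dominated = false;
        for (int dk = -1; dk <= 1 && !dominated; dk++)
          for (int dj = -1; dj <= 1 && !dominated; dj++)
            for (int di = -1; di <= 1 && !dominated; di++) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              R_xlen_t nidx = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              if (!phase[nidx]) continue;
              double rn2 = r2[nidx];
              if (!R_finite(rn2)) { dominated = true; continue; }
              double dd = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (std::sqrt(rn2) >= rc + dd) dominated = true;
            }
        if (dominated) continue;
        int R = (int)std::ceil(rc);
        for (int dk = -R; dk <= R; dk++) {
          int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -R; dj <= R; dj++) {
            int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            int rem2 = dk * dk + dj * dj;
            for (int di = -R; di <= R; di++) {
              int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              double dist2 = rem2 + di * di;
              if (dist2 >= rc2) continue;
              R_xlen_t pidx = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              if (phase[pidx] && out[pidx] < rc2) out[pidx] = rc2;
            }
          }
        }
      }
  return out;
}
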