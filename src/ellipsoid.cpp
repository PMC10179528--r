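#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Containment is checked against a (lightly smoothed) phase field sampled
// with trilinear interpolation, so single-voxel surface roughness and index
// rounding do not freeze the growth while genuine marrow gaps still block
// it.  Out-of-grid samples use edge replication: a structure cut by the
// volume boundary is treated as continuing (growth is still capped by
// max_iter).
static inline double sampleField(const NumericVector &field,
                                 int nx, int ny, int nz,
                                 double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2;
  if (j0 > ny - 2) j0 = ny - 2;
  if (k0 > nz - 2) k0 = nz - 2;
  double tx = x - i0, ty = y - j0, tz = z - k0;
  double acc = 0;
  for (int dk = 0; dk <= 1; dk++)
    for (int dj = 0; dj <= 1; dj++)
      for (int di = 0; di <= 1; di++) {
        double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
        if (w == 0) continue;
        acc += w * field[(i0 + di) +
                         (R_xlen_t)nx * ((j0 + dj) + (R_xlen_t)ny * (k0 + dk))];
      }
  return acc;
}

// Grow one maximal ellipsoid per seed inside the foreground.  Axis directions
// are fixed (rows of `rot`, one 3x3 rotation per seed, column-major flattened
// 9-vector per row); each semi-axis is dilated in turn by `step` while every
// surface sample (unit directions `sphere_dirs` mapped through the axes)
// stays on foreground voxels.  Everything is in voxel-index coordinates.
// Returns an m x 3 matrix of semi-axis lengths.
// [[Rcpp::export(name = ".grow_ellipsoids_cpp")]]
NumericMatrix grow_ellipsoids_cpp(NumericVector field, double level,
                                  IntegerVector dims,
                                  NumericMatrix seeds, NumericMatrix rot,
                                  NumericVector r0, double step, int max_iter,
                                  NumericMatrix sphere_dirs) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = seeds.nrow();
  int ns = sphere_dirs.nrow();
  NumericMatrix axes(m, 3);

  for (int s = 0; s < m; s++) {
    double cx = seeds(s, 0), cy = seeds(s, 1), cz = seeds(s, 2);
    double V[3][3]; // columns = axis directions
    for (int c = 0; c < 3; c++)
      for (int r = 0; r < 3; r++) V[r][c] = rot(s, 3 * c + r);
    double a[3] = {r0[s], r0[s], r0[s]};
    bool frozen[3] = {false, false, false};

    // pass: no sample clearly outside (field < level/2) and at most 3 of
    // the ns surface samples marginally below the level (grazing contacts)
    auto contained = [&](const double aa[3]) {
      int soft = 0;
      for (int q = 0; q < ns; q++) {
        double u0 = sphere_dirs(q, 0) * aa[0];
        double u1 = sphere_dirs(q, 1) * aa[1];
        double u2 = sphere_dirs(q, 2) * aa[2];
        double x = cx + V[0][0] * u0 + V[0][1] * u1 + V[0][2] * u2;
        double y = cy + V[1][0] * u0 + V[1][1] * u1 + V[1][2] * u2;
        double z = cz + V[2][0] * u0 + V[2][1] * u1 + V[2][2] * u2;
        double f = sampleField(field, nx, ny, nz, x, y, z);
        if (f < 0.5 * level) return false;
        if (f < level && ++soft > 3) return false;
      }
      return true;
    };

    if (!contained(a)) { // seed sphere already touching: shrink to fit
      while (a[0] > 0.5 && !contained(a)) {
        a[0] -= 0.25; a[1] -= 0.25; a[2] -= 0.25;
      }
    }
    for (int it = 0; it < max_iter; it++) {
      bool moved = false;
      for (int i = 0; i < 3; i++) {
        if (frozen[i]) continue;
        double trial[3] = {a[0], a[1], a[2]};
        trial[i] += step;
        if (contained(trial)) { a[i] = trial[i]; moved = true; }
        else frozen[i] = true;
      }
      if (!moved) break;
    }
    axes(s, 0) = a[0]; axes(s, 1) = a[1]; axes(s, 2) = a[2];
  }
  return axes;
}

// Paint per-voxel EF: ellipsoids are visited in the given order (pass them
// sorted by decreasing volume); each still-unassigned foreground voxel inside
// an ellipsoid gets that ellipsoid's EF value.  A half-voxel margin is added
// to the semi-axes for the containment test so that near-voxel-thin
// ellipsoids still claim the voxel centres of the strut they sit in.
// [[Rcpp::export(name = ".assign_ef_cpp")]]
NumericVector assign_ef_cpp(LogicalVector fg, IntegerVector dims,
                            NumericMatrix seeds, NumericMatrix rot,
                            NumericMatrix axes, NumericVector ef,
                            IntegerVector order) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int oo = 0; oo < order.size(); oo++) {
    int s = order[oo]; // 0-based
    double cx = seeds(s, 0), cy = seeds(s, 1), cz = seeds(s, 2);
    double V[3][3];
    for (int c = 0; c < 3; c++)
      for (int r = 0; r < 3; r++) V[r][c] = rot(s, 3 * c + r);
    double a0 = axes(s, 0) + 0.5, a1 = axes(s, 1) + 0.5, a2 = axes(s, 2) + 0.5;
    double rmax = std::max(a0, std::max(a1, a2));
    int ilo = std::max(0, (int)std::floor(cx - rmax)),
        ihi = std::min(nx - 1, (int)std::ceil(cx + rmax));
    int jlo = std::max(0, (int)std::floor(cy - rmax)),
        jhi = std::min(ny - 1, (int)std::ceil(cy + rmax));
    int klo = std::max(0, (int)std::floor(cz - rmax)),
        khi = std::min(nz - 1, (int)std::ceil(cz + rmax));
    for (int k = klo; k <= khi; k++)
      for (int j = jlo; j <= jhi; j++)
        for (int i = ilo; i <= ihi; i++) {
          R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (!fg[idx] || !ISNA(out[idx])) continue;
          double dx = i - cx, dy = j - cy, dz = k - cz;
          // coordinates in the ellipsoid frame
          double q0 = (V[0][0] * dx + V[1][0] * dy + V[2][0] * dz) / a0;
          double q1 = (V[0][1] * dx + V[1][1] * dy + V[2][1] * dz) / a1;
          double q2 = (V[0][2] * dx + V[1][2] * dy + V[2][2] * dz) / a2;
          if (q0 * q0 + q1 * q1 + q2 * q2 <= 1.0) out[idx] = ef[s];
        }
  }
  return out;
}
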