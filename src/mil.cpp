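#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean-intercept-length sampling: for each test direction a parallel grid of
// lines is marched through the volume at a fixed sub-voxel step; bone path
// length and bone/marrow crossings are accumulated over samples that fall
// inside the analysis mask.  All quantities are in voxel units.
// dirs: n x 3 unit vectors; offsets: n x 2 fractional line-grid offsets.
// [[Rcpp::export(name = ".mil_cast_cpp")]]
NumericMatrix mil_cast_cpp(LogicalVector fg, LogicalVector mask,
                           IntegerVector dims, NumericMatrix dirs,
                           double line_spacing, double step,
                           NumericMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ndir = dirs.nrow();
  NumericMatrix out(ndir, 2); // bone length (voxels), crossings

  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cz = 0.5 * (nz - 1);
  double Rad = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny + (double)nz * nz) + 1.0;

  for (int d = 0; d < ndir; d++) {
    double wx = dirs(d, 0), wy = dirs(d, 1), wz = dirs(d, 2);
    // orthonormal basis perpendicular to w
    double ax = 1, ay = 0, az = 0;
    if (std::fabs(wx) > 0.9) { ax = 0; ay = 1; }
    double e1x = wy * az - wz * ay, e1y = wz * ax - wx * az, e1z = wx * ay - wy * ax;
    double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= n1; e1y /= n1; e1z /= n1;
    double e2x = wy * e1z - wz * e1y, e2y = wz * e1x - wx * e1z, e2z = wx * e1y - wy * e1x;

    double len = 0;
    double crossings = 0;
    int nsteps = (int)std::ceil(2.0 * Rad / step);
    double u0 = (offsets(d, 0) - 0.5) * line_spacing;
    double v0 = (offsets(d, 1) - 0.5) * line_spacing;
    for (double u = -Rad + u0; u <= Rad; u += line_spacing)
      for (double v = -Rad + v0; v <= Rad; v += line_spacing) {
        double ox = cx + u * e1x + v * e2x - Rad * wx;
        double oy = cy + u * e1y + v * e2y - Rad * wy;
        double oz = cz + u * e1z + v * e2z - Rad * wz;
        int prev = -1; // -1 invalid, 0 marrow, 1 bone
        for (int s = 0; s <= nsteps; s++) {
          double x = ox + s * step * wx;
          double y = oy + s * step * wy;
          double z = oz + s * step * wz;
          int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
          int cur = -1;
          if (i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz) {
            R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            if (mask[idx]) cur = fg[idx] ? 1 : 0;
          }
          if (cur == 1) len += step;
          if (prev >= 0 && cur >= 0 && cur != prev) crossings += 1;
          prev = cur;
        }
      }
    out(d, 0) = len;
    out(d, 1) = crossings;
  }
  return out;
}
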