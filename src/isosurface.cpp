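#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface triangulation of a 3D scalar field by tetrahedral decomposition
// of each grid cube (six tetrahedra sharing the 0-6 diagonal; face diagonals
// match between neighbouring cubes, so the mesh is crack-free).  Vertices are
// linearly interpolated on tet edges; per-vertex outward normals come from
// the trilinearly interpolated central-difference gradient of the field.
// Positions are in voxel-index coordinates (voxel centres at integers).

struct P3 { double x, y, z; };

static inline double fieldAt(const NumericVector &f, int nx, int ny, int nz,
                             int i, int j, int k) {
  if (i < 0) i = 0; if (i >= nx) i = nx - 1;
  if (j < 0) j = 0; if (j >= ny) j = ny - 1;
  if (k < 0) k = 0; if (k >= nz) k = nz - 1;
  return f[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

static P3 gradAtNode(const NumericVector &f, int nx, int ny, int nz,
                     int i, int j, int k) {
  P3 g;
  g.x = 0.5 * (fieldAt(f, nx, ny, nz, i + 1, j, k) - fieldAt(f, nx, ny, nz, i - 1, j, k));
  g.y = 0.5 * (fieldAt(f, nx, ny, nz, i, j + 1, k) - fieldAt(f, nx, ny, nz, i, j - 1, k));
  g.z = 0.5 * (fieldAt(f, nx, ny, nz, i, j, k + 1) - fieldAt(f, nx, ny, nz, i, j, k - 1));
  return g;
}

static P3 gradInterp(const NumericVector &f, int nx, int ny, int nz,
                     double x, double y, double z) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double tx = x - i0, ty = y - j0, tz = z - k0;
  P3 acc = {0, 0, 0};
  for (int dk = 0; dk <= 1; dk++)
    for (int dj = 0; dj <= 1; dj++)
      for (int di = 0; di <= 1; di++) {
        double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
        if (w == 0) continue;
        P3 g = gradAtNode(f, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
        acc.x += w * g.x; acc.y += w * g.y; acc.z += w * g.z;
      }
  return acc;
}

// [[Rcpp::export(name = ".isosurface_cpp")]]
List isosurface_cpp(NumericVector f, IntegerVector dims, double level) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  // cube corner offsets, VTK ordering
  const int C[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                       {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  const int TETS[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                          {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  std::vector<double> vx, vy, vz;

  double fv[8];
  double px[8], py[8], pz[8];
  for (int k = 0; k + 1 < nz; k++)
    for (int j = 0; j + 1 < ny; j++)
      for (int i = 0; i + 1 < nx; i++) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; c++) {
          int ci = i + C[c][0], cj = j + C[c][1], ck = k + C[c][2];
          fv[c] = f[ci + (R_xlen_t)nx * (cj + (R_xlen_t)ny * ck)];
          px[c] = ci; py[c] = cj; pz[c] = ck;
          if (fv[c] >= level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; t++) {
          const int *T = TETS[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int q = 0; q < 4; q++) {
            if (fv[T[q]] >= level) in[nin++] = T[q];
            else out[nout++] = T[q];
          }
          if (nin == 0 || nin == 4) continue;
          auto edgePt = [&](int a, int b, double *p) {
            double tt = (level - fv[a]) / (fv[b] - fv[a]);
            p[0] = px[a] + tt * (px[b] - px[a]);
            p[1] = py[a] + tt * (py[b] - py[a]);
            p[2] = pz[a] + tt * (pz[b] - pz[a]);
          };
          double p1[3], p2[3], p3[3], p4[3];
          if (nin == 1) {
            edgePt(in[0], out[0], p1);
            edgePt(in[0], out[1], p2);
            edgePt(in[0], out[2], p3);
            vx.push_back(p1[0]); vy.push_back(p1[1]); vz.push_back(p1[2]);
            vx.push_back(p2[0]); vy.push_back(p2[1]); vz.push_back(p2[2]);
            vx.push_back(p3[0]); vy.push_back(p3[1]); vz.push_back(p3[2]);
          } else if (nin == 3) {
            edgePt(out[0], in[0], p1);
            edgePt(out[0], in[1], p2);
            edgePt(out[0], in[2], p3);
            vx.push_back(p1[0]); vy.push_back(p1[1]); vz.push_back(p1[2]);
            vx.push_back(p2[0]); vy.push_back(p2[1]); vz.push_back(p2[2]);
            vx.push_back(p3[0]); vy.push_back(p3[1]); vz.push_back(p3[2]);
          } else { // nin == 2: quad p_ac, p_ad, p_bd, p_bc
            edgePt(in[0], out[0], p1);
            edgePt(in[0], out[1], p2);
            edgePt(in[1], out[1], p3);
            edgePt(in[1], out[0], p4);
            vx.push_back(p1[0]); vy.push_back(p1[1]); vz.push_back(p1[2]);
            vx.push_back(p2[0]); vy.push_back(p2[1]); vz.push_back(p2[2]);
            vx.push_back(p3[0]); vy.push_back(p3[1]); vz.push_back(p3[2]);
            vx.push_back(p1[0]); vy.push_back(p1[1]); vz.push_back(p1[2]);
            vx.push_back(p3[0]); vy.push_back(p3[1]); vz.push_back(p3[2]);
            vx.push_back(p4[0]); vy.push_back(p4[1]); vz.push_back(p4[2]);
          }
        }
      }

  R_xlen_t nv = (R_xlen_t)vx.size();
  NumericMatrix V(nv, 3), N(nv, 3);
  for (R_xlen_t q = 0; q < nv; q++) {
    V(q, 0) = vx[q]; V(q, 1) = vy[q]; V(q, 2) = vz[q];
    P3 g = gradInterp(f, nx, ny, nz, vx[q], vy[q], vz[q]);
    double nrm = std::sqrt(g.x * g.x + g.y * g.y + g.z * g.z);
    if (nrm < 1e-12) { N(q, 0) = 0; N(q, 1) = 0; N(q, 2) = 0; }
    else { N(q, 0) = -g.x / nrm; N(q, 1) = -g.y / nrm; N(q, 2) = -g.z / nrm; }
  }
  return List::create(_["vertices"] = V, _["normals"] = N);
}
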