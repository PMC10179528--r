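#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Matrix-free operations with one shared 24x24 stiffness for all voxel
// hexahedra (identical cube elements).  elems: n x 8 node indices (0-based);
// global dof of node q, component c is 3*q + c.  Element dof ordering matches
// the local node ordering used to build Ke.

// flat copies of the element table (3*node dof base per local node) and of
// Ke (row-major) keep the inner PCG loop free of Rcpp accessor overhead
struct FlatOp {
  std::vector<int> dof;   // ne*8 global dof bases
  std::vector<double> ke; // 576, row-major
  int ne;
  FlatOp(const IntegerMatrix &elems, const NumericMatrix &Ke) {
    ne = elems.nrow();
    dof.resize((size_t)ne * 8);
    for (int e = 0; e < ne; e++)
      for (int l = 0; l < 8; l++) dof[(size_t)e * 8 + l] = 3 * elems(e, l);
    ke.resize(576);
    for (int r = 0; r < 24; r++)
      for (int c = 0; c < 24; c++) ke[24 * r + c] = Ke(r, c);
  }
  void apply(const std::vector<double> &u, std::vector<double> &out) const {
    std::fill(out.begin(), out.end(), 0.0);
    double ue[24], fe[24];
    const double *K = ke.data();
    for (int e = 0; e < ne; e++) {
      const int *d = &dof[(size_t)e * 8];
      for (int l = 0; l < 8; l++) {
        const double *up = &u[d[l]];
        ue[3 * l] = up[0]; ue[3 * l + 1] = up[1]; ue[3 * l + 2] = up[2];
      }
      for (int r = 0; r < 24; r++) {
        const double *Kr = K + 24 * r;
        double acc = 0;
        for (int c = 0; c < 24; c++) acc += Kr[c] * ue[c];
        fe[r] = acc;
      }
      for (int l = 0; l < 8; l++) {
        double *op = &out[d[l]];
        op[0] += fe[3 * l]; op[1] += fe[3 * l + 1]; op[2] += fe[3 * l + 2];
      }
    }
  }
};

static void matvec(const IntegerMatrix &elems, const NumericMatrix &Ke,
                   const std::vector<double> &u, std::vector<double> &out) {
  FlatOp op(elems, Ke);
  op.apply(u, out);
}

// [[Rcpp::export(name = ".fe_matvec_cpp")]]
NumericVector fe_matvec_cpp(IntegerMatrix elems, NumericMatrix Ke,
                            NumericVector u) {
  std::vector<double> uu(u.begin(), u.end()), out(u.size());
  matvec(elems, Ke, uu, out);
  return NumericVector(out.begin(), out.end());
}

// Jacobi-preconditioned conjugate gradient for K_ff v = -K_fc u_c.
// u0 holds prescribed values at fixed dofs (zero elsewhere); `fixed` flags
// constrained dofs.  Returns the full displacement vector u0 + v, the
// iteration count and the final relative residual.
// [[Rcpp::export(name = ".fe_pcg_cpp")]]
List fe_pcg_cpp(IntegerMatrix elems, NumericMatrix Ke, NumericVector u0,
                LogicalVector fixed, double tol, int max_iter) {
  R_xlen_t n = u0.size();
  std::vector<double> diag(n, 0.0);
  int ne = elems.nrow();
  for (int e = 0; e < ne; e++)
    for (int l = 0; l < 8; l++) {
      int g = elems(e, l);
      diag[3 * g] += Ke(3 * l, 3 * l);
      diag[3 * g + 1] += Ke(3 * l + 1, 3 * l + 1);
      diag[3 * g + 2] += Ke(3 * l + 2, 3 * l + 2);
    }

  std::vector<double> ufix(u0.begin(), u0.end());
  std::vector<double> b(n), tmp(n);
  matvec(elems, Ke, ufix, b);
  double bnorm2 = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    b[i] = fixed[i] ? 0.0 : -b[i];
    bnorm2 += b[i] * b[i];
  }
  std::vector<double> x(n, 0.0), r(b), z(n), p(n), Ap(n);
  double relres = 0.0;
  int it = 0;
  FlatOp op(elems, Ke);
  if (bnorm2 == 0) {
    // prescribed values induce no load on free dofs (or none exist)
  } else {
    double rz = 0;
    for (R_xlen_t i = 0; i < n; i++) {
      z[i] = (fixed[i] || diag[i] <= 0) ? 0.0 : r[i] / diag[i];
      p[i] = z[i];
      rz += r[i] * z[i];
    }
    for (it = 1; it <= max_iter; it++) {
      op.apply(p, Ap);
      double pAp = 0;
      for (R_xlen_t i = 0; i < n; i++) {
        if (fixed[i]) Ap[i] = 0.0;
        pAp += p[i] * Ap[i];
      }
      if (pAp <= 0) stop("stiffness operator not positive definite (floating elements?)");
      double alpha = rz / pAp;
      double rnorm2 = 0;
      for (R_xlen_t i = 0; i < n; i++) {
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        rnorm2 += r[i] * r[i];
      }
      relres = std::sqrt(rnorm2 / bnorm2);
      if (relres <= tol) break;
      double rznew = 0;
      for (R_xlen_t i = 0; i < n; i++) {
        z[i] = (fixed[i] || diag[i] <= 0) ? 0.0 : r[i] / diag[i];
        rznew += r[i] * z[i];
      }
      double beta = rznew / rz;
      rz = rznew;
      for (R_xlen_t i = 0; i < n; i++) p[i] = z[i] + beta * p[i];
    }
  }
  NumericVector u(n);
  for (R_xlen_t i = 0; i < n; i++) u[i] = ufix[i] + x[i];
  return List::create(_["u"] = u, _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = (bnorm2 == 0) || (relres <= tol));
}

// ---------------------------------------------------------------------------
// Sparse-assembled solver: the free-dof stiffness is assembled once into a
// lower-triangular CSR, factorised by zero-fill incomplete Cholesky (with a
// diagonal shift retry on breakdown) and used as the PCG preconditioner.
// This keeps memory linear in the number of nonzeros while cutting the
// iteration count by an order of magnitude versus diagonal scaling.

struct CSRLower {
  int n = 0;
  std::vector<R_xlen_t> rowptr;
  std::vector<int> col;
  std::vector<double> val;
};

// y = A x with A symmetric, stored as its lower triangle (diagonal included)
static void symMatvec(const CSRLower &A, const std::vector<double> &x,
                      std::vector<double> &y) {
  std::fill(y.begin(), y.end(), 0.0);
  for (int i = 0; i < A.n; i++) {
    double xi = x[i], acc = 0;
    for (R_xlen_t k = A.rowptr[i]; k < A.rowptr[i + 1]; k++) {
      int j = A.col[k];
      double v = A.val[k];
      acc += v * x[j];
      if (j != i) y[j] += v * xi;
    }
    y[i] += acc;
  }
}

// in-pattern incomplete Cholesky of A (lower CSR, sorted columns, diagonal
// last in each row); returns false on breakdown
static bool ic0(const CSRLower &A, std::vector<double> &lv, double shift) {
  int n = A.n;
  lv.assign(A.val.begin(), A.val.end());
  // boost the diagonal
  if (shift > 0)
    for (int i = 0; i < n; i++)
      lv[A.rowptr[i + 1] - 1] *= (1.0 + shift);
  std::vector<R_xlen_t> diag(n);
  for (int i = 0; i < n; i++) diag[i] = A.rowptr[i + 1] - 1; // diag is last
  for (int i = 0; i < n; i++) {
    for (R_xlen_t ki = A.rowptr[i]; ki < A.rowptr[i + 1]; ki++) {
      int j = A.col[ki];
      // dot of rows i and j over columns < j (merge of sorted patterns)
      double s = 0;
      R_xlen_t pi = A.rowptr[i], pj = A.rowptr[j];
      while (pi < ki && pj < diag[j]) {
        int ci = A.col[pi], cj = A.col[pj];
        if (ci == cj) { s += lv[pi] * lv[pj]; pi++; pj++; }
        else if (ci < cj) pi++;
        else pj++;
      }
      if (j < i) {
        double d = lv[diag[j]];
        if (d == 0) return false;
        lv[ki] = (lv[ki] - s) / d;
      } else { // diagonal entry
        double d = lv[ki] - s;
        if (d <= 0) return false;
        lv[ki] = std::sqrt(d);
      }
    }
  }
  return true;
}

// solve L L^T z = r
static void icSolve(const CSRLower &A, const std::vector<double> &lv,
                    const std::vector<double> &r, std::vector<double> &z) {
  int n = A.n;
  // forward: L y = r (store y in z)
  for (int i = 0; i < n; i++) {
    double s = r[i];
    R_xlen_t last = A.rowptr[i + 1] - 1;
    for (R_xlen_t k = A.rowptr[i]; k < last; k++) s -= lv[k] * z[A.col[k]];
    z[i] = s / lv[last];
  }
  // backward: L^T x = y
  for (int i = n - 1; i >= 0; i--) {
    R_xlen_t last = A.rowptr[i + 1] - 1;
    double xi = z[i] / lv[last];
    z[i] = xi;
    for (R_xlen_t k = A.rowptr[i]; k < last; k++) z[A.col[k]] -= lv[k] * xi;
  }
}

// [[Rcpp::export(name = ".fe_solve_ic_cpp")]]
List fe_solve_ic_cpp(IntegerMatrix elems, NumericMatrix Ke, NumericVector u0,
                     LogicalVector fixed, double tol, int max_iter) {
  R_xlen_t n = u0.size();
  int ne = elems.nrow();
  // compact numbering of free dofs
  std::vector<int> fid(n, -1);
  int nf = 0;
  for (R_xlen_t i = 0; i < n; i++) if (!fixed[i]) fid[i] = nf++;

  // rhs: b = -(K u0) restricted to free dofs
  std::vector<double> ufix(u0.begin(), u0.end()), ku(n);
  matvec(elems, Ke, ufix, ku);
  std::vector<double> b(nf);
  for (R_xlen_t i = 0; i < n; i++) if (fid[i] >= 0) b[fid[i]] = -ku[i];
  double bnorm2 = 0;
  for (int i = 0; i < nf; i++) bnorm2 += b[i] * b[i];

  NumericVector uout(n);
  for (R_xlen_t i = 0; i < n; i++) uout[i] = ufix[i];
  if (nf == 0 || bnorm2 == 0)
    return List::create(_["u"] = uout, _["iterations"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);

  // assemble the free-dof lower triangle as sorted (key, value) pairs
  std::vector<std::pair<uint64_t, double>> trip;
  trip.reserve((size_t)ne * 300);
  for (int e = 0; e < ne; e++) {
    int gdof[24];
    for (int l = 0; l < 8; l++) {
      int g = 3 * elems(e, l);
      gdof[3 * l] = g; gdof[3 * l + 1] = g + 1; gdof[3 * l + 2] = g + 2;
    }
    for (int r = 0; r < 24; r++) {
      int fr = fid[gdof[r]];
      if (fr < 0) continue;
      for (int c = 0; c < 24; c++) {
        int fc = fid[gdof[c]];
        if (fc < 0 || fc > fr) continue;
        trip.emplace_back(((uint64_t)fr << 32) | (uint32_t)fc, Ke(r, c));
      }
    }
  }
  std::sort(trip.begin(), trip.end(),
            [](const std::pair<uint64_t, double> &a,
               const std::pair<uint64_t, double> &b) { return a.first < b.first; });
  CSRLower A;
  A.n = nf;
  A.rowptr.assign(nf + 1, 0);
  for (size_t t = 0; t < trip.size(); t++) {
    if (t > 0 && trip[t].first == trip[t - 1].first) {
      A.val.back() += trip[t].second;
    } else {
      int i = (int)(trip[t].first >> 32);
      A.rowptr[i + 1]++;
      A.col.push_back((int)(trip[t].first & 0xffffffffu));
      A.val.push_back(trip[t].second);
    }
  }
  trip.clear();
  trip.shrink_to_fit();
  for (int i = 0; i < nf; i++) A.rowptr[i + 1] += A.rowptr[i];

  // incomplete Cholesky with diagonal-shift retries
  std::vector<double> lv;
  double shift = 0.0;
  bool ok = ic0(A, lv, shift);
  while (!ok && shift < 1.0) {
    shift = (shift == 0.0) ? 1e-3 : shift * 10;
    ok = ic0(A, lv, shift);
  }
  if (!ok) stop("incomplete Cholesky breakdown (floating elements?)");

  // preconditioned conjugate gradient
  std::vector<double> x(nf, 0.0), r(b), z(nf), p(nf), Ap(nf);
  icSolve(A, lv, r, z);
  p = z;
  double rz = 0;
  for (int i = 0; i < nf; i++) rz += r[i] * z[i];
  double relres = 1.0;
  int it;
  for (it = 1; it <= max_iter; it++) {
    symMatvec(A, p, Ap);
    double pAp = 0;
    for (int i = 0; i < nf; i++) pAp += p[i] * Ap[i];
    if (pAp <= 0) stop("stiffness operator not positive definite (floating elements?)");
    double alpha = rz / pAp;
    double rnorm2 = 0;
    for (int i = 0; i < nf; i++) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rnorm2 += r[i] * r[i];
    }
    relres = std::sqrt(rnorm2 / bnorm2);
    if (relres <= tol) break;
    icSolve(A, lv, r, z);
    double rznew = 0;
    for (int i = 0; i < nf; i++) rznew += r[i] * z[i];
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < nf; i++) p[i] = z[i] + beta * p[i];
  }
  for (R_xlen_t i = 0; i < n; i++)
    if (fid[i] >= 0) uout[i] = ufix[i] + x[fid[i]];
  return List::create(_["u"] = uout, _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = relres <= tol);
}
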