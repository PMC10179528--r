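## Voxel hexahedral micro-finite elements: linear elastostatics of the bone
## phase under macroscopic uniaxial compression along z.  One trilinear
## 8-node hexahedron per solid voxel, 2x2x2 Gauss quadrature, matrix-free
## Jacobi-preconditioned conjugate gradient.  Units: mm, MPa, dimensionless
## strain.

#' Isotropic elastic material
#'
#' @param E_MPa Young's modulus in MPa (default 15000, i.e. 15 GPa bone
#'   tissue modulus).
#' @param nu Poisson's ratio (default 0.3).
#' @return object of class `elastic_material`
#' @export
elastic_material <- function(E_MPa = 15000, nu = 0.3) {
  if (E_MPa <= 0) stop("E must be positive")
  if (nu <= -1 || nu >= 0.5) stop("nu must be in (-1, 0.5)")
  structure(list(E_MPa = E_MPa, nu = nu), class = "elastic_material")
}

#' Uniaxial compression boundary conditions
#'
#' Macroscopic compressive strain along z: all bottom-surface nodes are
#' fixed axially, all top-surface nodes are displaced by
#' `-applied_strain * specimen height` (e.g. 0.2% over an 8 mm core gives
#' 0.016 mm).  Only axial degrees of freedom are constrained; lateral
#' rigid-body modes are removed by pinning one bottom node in x and y and a
#' second (same y) in y.
#'
#' @param applied_strain macroscopic compressive strain (> 0), e.g. 0.002.
#' @return object of class `compression_bc`
#' @export
compression_bc <- function(applied_strain = 0.002) {
  if (applied_strain <= 0) stop("applied_strain must be positive")
  structure(list(applied_strain = applied_strain), class = "compression_bc")
}

#' Prescribed top displacement for a compression test
#'
#' `u_z = -applied_strain * height_mm`; the boundary-condition arithmetic
#' of the compression setup.
#' @param bc a [compression_bc()]
#' @param height_mm specimen height in mm
#' @return displacement in mm (negative = compression)
#' @export
top_displacement <- function(bc, height_mm) {
  stopifnot(inherits(bc, "compression_bc"))
  -bc$applied_strain * height_mm
}

# local node offsets of a hexahedron (VTK ordering)
HEX_OFFSETS <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                        0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
                      ncol = 3, byrow = TRUE)

#' Build a voxel hexahedral mesh
#'
#' One 8-node hexahedron per solid voxel, shared corner nodes deduplicated.
#' Only the largest 26-connected component is meshed (a message reports any
#' removal); the component must span from its bottom to its top occupied
#' layer, otherwise there is no load path.
#'
#' @param binary binary [voxel_volume()]
#' @return object of class `fe_mesh`: `nodes` (N x 3, mm), `elems`
#'   (n x 8 node indices), `top_nodes`, `bottom_nodes`, `spacing_mm`,
#'   `height_mm`
#' @export
build_hex_mesh <- function(binary) {
  assert_binary(binary)
  fg <- binary$data > 0
  if (!any(fg)) stop("empty volume: nothing to mesh")
  zocc <- which(apply(fg, 3, any))
  lab <- .label_components_cpp(as.vector(fg), dim(fg), 26L)
  counts <- tabulate(lab[lab > 0])
  if (length(counts) > 1) {
    keep <- which.max(counts)
    message(length(counts) - 1L, " unconnected component(s) removed before meshing")
    fg <- array(lab == keep, dim(fg))
  }
  d <- dim(fg)
  vox <- arrayInd(which(fg), d) # 1-based voxel indices
  kmin <- min(vox[, 3])
  kmax <- max(vox[, 3])
  if (kmin > min(zocc) || kmax < max(zocc))
    stop("load path missing: no single component spans the occupied z-range")

  np1 <- d + 1L
  # raw node key of corner lattice point (i,j,k), 0-based coords
  key <- function(i, j, k) i + as.numeric(np1[1]) * (j + as.numeric(np1[2]) * k)
  ne <- nrow(vox)
  raw <- matrix(0, ne, 8)
  for (l in 1:8) {
    raw[, l] <- key(vox[, 1] - 1 + HEX_OFFSETS[l, 1],
                    vox[, 2] - 1 + HEX_OFFSETS[l, 2],
                    vox[, 3] - 1 + HEX_OFFSETS[l, 3])
  }
  uk <- sort(unique(as.vector(raw)))
  elems <- matrix(match(raw, uk), ne, 8)
  # decode node coordinates
  k <- floor(uk / (np1[1] * np1[2]))
  rem <- uk - k * np1[1] * np1[2]
  j <- floor(rem / np1[1])
  i <- rem - j * np1[1]
  sp <- binary$spacing_mm
  nodes <- cbind(i, j, k) * sp
  nodes <- sweep(nodes, 2, binary$origin_mm, "+")

  bottom <- which(k == kmin - 1L)
  top <- which(k == kmax)
  structure(list(nodes = nodes, elems = elems, top_nodes = top,
                 bottom_nodes = bottom, spacing_mm = sp,
                 height_mm = (kmax - kmin + 1L) * sp,
                 node_k = k, kmin = kmin, kmax = kmax),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d hexahedra, %d nodes, height %.3f mm\n",
              nrow(x$elems), nrow(x$nodes), x$height_mm))
  invisible(x)
}

# 6x6 isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx),
# engineering shear strains
elasticity_matrix <- function(mat) {
  E <- mat$E_MPa
  nu <- mat$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# strain-displacement matrix (6 x 24) of the trilinear hex at natural
# coordinates xi (length 3), edge length h
hex_B <- function(xi, h) {
  s <- 2 * HEX_OFFSETS - 1 # node signs
  B <- matrix(0, 6, 24)
  for (i in 1:8) {
    dN <- c(s[i, 1] * (1 + s[i, 2] * xi[2]) * (1 + s[i, 3] * xi[3]),
            s[i, 2] * (1 + s[i, 1] * xi[1]) * (1 + s[i, 3] * xi[3]),
            s[i, 3] * (1 + s[i, 1] * xi[1]) * (1 + s[i, 2] * xi[2])) / 8
    dN <- dN * 2 / h # d/dx = d/dxi * dxi/dx
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- dN[1]
    B[2, c0 + 2] <- dN[2]
    B[3, c0 + 3] <- dN[3]
    B[4, c0 + 1] <- dN[2]; B[4, c0 + 2] <- dN[1]
    B[5, c0 + 2] <- dN[3]; B[5, c0 + 3] <- dN[2]
    B[6, c0 + 1] <- dN[3]; B[6, c0 + 3] <- dN[1]
  }
  B
}

gauss_points <- function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(x = c(-g, g), y = c(-g, g), z = c(-g, g)))
}

# 24 x 24 stiffness of a cube element of edge h
hex_stiffness <- function(mat, h) {
  D <- elasticity_matrix(mat)
  gp <- gauss_points()
  w <- (h / 2)^3
  Ke <- matrix(0, 24, 24)
  for (g in seq_len(nrow(gp))) {
    B <- hex_B(gp[g, ], h)
    Ke <- Ke + w * t(B) %*% D %*% B
  }
  (Ke + t(Ke)) / 2
}

#' Assemble and solve the compression problem
#'
#' Prescribes the boundary conditions on the mesh and solves the symmetric
#' positive-definite linear elastostatic system with a preconditioned
#' conjugate gradient (deterministic: lexicographic node ordering, fixed
#' iteration schedule).  The default preconditioner is a zero-fill
#' incomplete Cholesky factorisation of the sparse-assembled free-dof
#' stiffness; `method = "jacobi"` selects the matrix-free
#' diagonally-preconditioned variant (slower on large meshes, no assembly
#' memory).
#'
#' @param mesh a [build_hex_mesh()] result.
#' @param material an [elastic_material()].
#' @param bc a [compression_bc()].
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap; non-convergence is an error.
#' @param method "ic" (incomplete-Cholesky PCG) or "jacobi" (matrix-free).
#' @return object of class `fe_solution`: `u` (N x 3 displacements, mm),
#'   `iterations`, `relres`, plus the inputs
#' @export
fe_solve <- function(mesh, material, bc = compression_bc(), tol = 1e-8,
                     max_iter = 20000, method = c("ic", "jacobi")) {
  method <- match.arg(method)
  stopifnot(inherits(mesh, "fe_mesh"), inherits(material, "elastic_material"),
            inherits(bc, "compression_bc"))
  nN <- nrow(mesh$nodes)
  fixed <- logical(3 * nN)
  u0 <- numeric(3 * nN)
  zdof <- function(q) 3 * (q - 1) + 3
  xdof <- function(q) 3 * (q - 1) + 1
  ydof <- function(q) 3 * (q - 1) + 2
  fixed[zdof(mesh$bottom_nodes)] <- TRUE
  uz_top <- top_displacement(bc, mesh$height_mm)
  fixed[zdof(mesh$top_nodes)] <- TRUE
  u0[zdof(mesh$top_nodes)] <- uz_top
  # rigid-body pins: node A in x and y; node B (same y as A, different x) in y
  A <- mesh$bottom_nodes[1]
  fixed[xdof(A)] <- TRUE
  fixed[ydof(A)] <- TRUE
  sameY <- mesh$bottom_nodes[abs(mesh$nodes[mesh$bottom_nodes, 2] -
                                   mesh$nodes[A, 2]) < 1e-12]
  sameY <- setdiff(sameY, A)
  if (length(sameY)) {
    B <- sameY[which.max(abs(mesh$nodes[sameY, 1] - mesh$nodes[A, 1]))]
    fixed[ydof(B)] <- TRUE
  }
  Ke <- hex_stiffness(material, mesh$spacing_mm)
  res <- if (method == "ic")
    .fe_solve_ic_cpp(mesh$elems - 1L, Ke, u0, fixed, tol, as.integer(max_iter))
  else
    .fe_pcg_cpp(mesh$elems - 1L, Ke, u0, fixed, tol, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("PCG did not converge in %d iterations (relative residual %.3g)",
                 res$iterations, res$relres))
  structure(list(u = matrix(res$u, ncol = 3, byrow = TRUE),
                 iterations = res$iterations, relres = res$relres,
                 mesh = mesh, material = material, bc = bc, Ke = Ke),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> %d dofs, %d PCG iterations, relres %.2g\n",
              3 * nrow(x$u), x$iterations, x$relres))
  invisible(x)
}

#' Element-wise micromechanical fields
#'
#' Per element: the strain tensor at the centroid (equal to the average of
#' the 2x2x2 Gauss-point strains for trilinear hexahedra), stress by
#' isotropic Hooke's law, axial strain `eps_z`, axial stress `sigma_z`, von
#' Mises stress `sigma_vm`, and the element-mean strain energy density
#' `W_e` integrated with the full quadrature (so total energy matches
#' 0.5 u'Ku exactly).
#'
#' @param sol an [fe_solve()] result.
#' @return object of class `fe_fields`: data.frame with columns `eps_z`,
#'   `sigma_z`, `sigma_vm`, `W_e`, plus attributes used by [energy_balance()]
#' @export
element_fields <- function(sol) {
  stopifnot(inherits(sol, "fe_solution"))
  mesh <- sol$mesh
  D <- elasticity_matrix(sol$material)
  h <- mesh$spacing_mm
  ne <- nrow(mesh$elems)
  # element displacement matrix (ne x 24)
  U <- matrix(0, ne, 24)
  for (l in 1:8) {
    q <- mesh$elems[, l]
    U[, 3 * (l - 1) + 1] <- sol$u[q, 1]
    U[, 3 * (l - 1) + 2] <- sol$u[q, 2]
    U[, 3 * (l - 1) + 3] <- sol$u[q, 3]
  }
  B0 <- hex_B(c(0, 0, 0), h)
  eps <- U %*% t(B0) # ne x 6 (engineering shears)
  sig <- eps %*% D   # D symmetric
  sxx <- sig[, 1]; syy <- sig[, 2]; szz <- sig[, 3]
  sxy <- sig[, 4]; syz <- sig[, 5]; szx <- sig[, 6]
  svm <- sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) +
                3 * (sxy^2 + syz^2 + szx^2))
  # quadrature-consistent mean energy density
  gp <- gauss_points()
  W <- numeric(ne)
  for (g in seq_len(nrow(gp))) {
    eg <- U %*% t(hex_B(gp[g, ], h))
    W <- W + rowSums((eg %*% D) * eg) / 2
  }
  W <- W / nrow(gp)
  out <- data.frame(eps_z = eps[, 3], sigma_z = szz, sigma_vm = svm, W_e = W)
  attr(out, "element_volume_mm3") <- h^3
  attr(out, "sol") <- sol
  class(out) <- c("fe_fields", "data.frame")
  out
}

#' Global energy balance diagnostic
#'
#' External work `0.5 * sum(top reactions) * u_z` versus internal strain
#' energy `sum(W_e * element volume)`; their relative mismatch is a solver
#' and post-processing consistency check.
#'
#' @param fields an [element_fields()] result.
#' @return list with `external_mJ`, `internal_mJ`, `relative_error`
#' @export
energy_balance <- function(fields) {
  sol <- attr(fields, "sol")
  mesh <- sol$mesh
  f <- .fe_matvec_cpp(mesh$elems - 1L, sol$Ke, as.vector(t(sol$u)))
  zdof <- 3 * (mesh$top_nodes - 1) + 3
  uz <- top_displacement(sol$bc, mesh$height_mm)
  wext <- 0.5 * sum(f[zdof]) * uz
  wint <- sum(fields$W_e) * attr(fields, "element_volume_mm3")
  list(external_mJ = wext, internal_mJ = wint,
       relative_error = abs(wext - wint) / max(abs(wint), .Machine$double.eps))
}

#' Sample-mean micromechanical profile
#'
#' Unweighted mean over elements (all voxels share one volume, so this
#' equals the volume-weighted mean); axial strain is reported in percent.
#'
#' @param fields an [element_fields()] result.
#' @return object of class `micromech_profile`: `mean_eps_z` (%),
#'   `mean_sigma_z` (MPa), `mean_sigma_vm` (MPa), `mean_W_e` (MPa)
#' @export
micromech_summary <- function(fields) {
  stopifnot(inherits(fields, "fe_fields"))
  if (!nrow(fields)) stop("no elements")
  structure(list(mean_eps_z = 100 * mean(fields$eps_z),
                 mean_sigma_z = mean(fields$sigma_z),
                 mean_sigma_vm = mean(fields$sigma_vm),
                 mean_W_e = mean(fields$W_e)),
            class = "micromech_profile")
}

#' @export
print.micromech_profile <- function(x, ...) {
  cat("<micromech_profile>\n")
  cat(sprintf("  mean eps_z  %.4f %%   mean sigma_z %.3f MPa\n",
              x$mean_eps_z, x$mean_sigma_z))
  cat(sprintf("  mean sigma_vm %.3f MPa   mean W_e %.5f MPa\n",
              x$mean_sigma_vm, x$mean_W_e))
  invisible(x)
}

#' @export
as.data.frame.micromech_profile <- function(x, ...) {
  data.frame(eps_z = x$mean_eps_z, sigma_z = x$mean_sigma_z,
             sigma_vm = x$mean_sigma_vm, W_e = x$mean_W_e)
}

#' One-call micro-FE compression of a binary volume
#'
#' Mesh, solve, recover element fields and summarise.  Convenience wrapper
#' used by the pipeline.
#'
#' @param binary binary [voxel_volume()]
#' @param material an [elastic_material()]
#' @param bc a [compression_bc()]
#' @param tol,max_iter solver settings, see [fe_solve()].
#' @return list: `profile` ([micromech_summary()]), `fields`, `solution`,
#'   `energy` ([energy_balance()])
#' @export
fe_compress <- function(binary, material = elastic_material(),
                        bc = compression_bc(), tol = 1e-8, max_iter = 20000) {
  mesh <- build_hex_mesh(binary)
  sol <- fe_solve(mesh, material, bc, tol, max_iter)
  fields <- element_fields(sol)
  list(profile = micromech_summary(fields), fields = fields, solution = sol,
       energy = energy_balance(fields))
}

#' Export mesh and element fields as legacy VTK
#'
#' ASCII legacy-format unstructured grid (hexahedra) with the element
#' fields as CELL_DATA, for inspection in ParaView.
#'
#' @param fields an [element_fields()] result.
#' @param path output `.vtk` path.
#' @return `path`, invisibly
#' @export
write_vtk <- function(fields, path) {
  sol <- attr(fields, "sol")
  mesh <- sol$mesh
  con <- file(path, "w")
  on.exit(close(con))
  nN <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "daefbone voxel micro-FE result", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nN)), con)
  write(t(mesh$nodes), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  write(t(cbind(8L, mesh$elems - 1L)), con, ncolumns = 9)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  write(rep(12L, ne), con, ncolumns = 20)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  for (nm in c("eps_z", "sigma_z", "sigma_vm", "W_e")) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    write(fields[[nm]], con, ncolumns = 9)
  }
  invisible(path)
}
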