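## Microarchitectural parameters of a trabecular volume: volume fraction,
## surface-to-volume ratio, direct-3D thickness/separation, plate-model
## trabecular number, structure model index, MIL fabric tensor / degree of
## anisotropy, and the ellipsoid factor.  Conventions: 26-connected
## foreground, 6-connected background; single global Otsu threshold;
## voxel-centred coordinates.

full_mask <- function(v) array(TRUE, dim(v$data))

resolve_mask <- function(v, mask) {
  if (is.null(mask)) return(full_mask(v))
  if (inherits(mask, "voxel_volume")) mask <- mask$data
  if (!identical(dim(mask), dim(v$data))) stop("mask dimensions do not match the volume")
  array(as.logical(mask), dim(v$data))
}

#' Global Otsu threshold of a grayscale volume
#'
#' Chooses the threshold that maximises the between-class variance of the
#' full 3D gray-level histogram (256 bins over the observed range, or the
#' distinct values themselves when there are few), then binarizes.  The
#' chosen threshold is reported in `meta$threshold`.
#'
#' @param gray grayscale [voxel_volume()] with at least two distinct values.
#' @param mask optional logical array restricting the histogram (e.g. the
#'   analysis cylinder); the whole volume is binarized either way.
#' @return binary [voxel_volume()] with `meta$threshold`
#' @export
otsu_threshold <- function(gray, mask = NULL) {
  stopifnot(inherits(gray, "voxel_volume"))
  m <- resolve_mask(gray, mask)
  x <- gray$data[m]
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant volume: no threshold exists")
  ux <- sort(unique(x))
  if (length(ux) <= 256) {
    # candidate thresholds between consecutive distinct values
    cand <- (ux[-1] + ux[-length(ux)]) / 2
    counts <- tabulate(match(x, ux), nbins = length(ux))
    mids <- ux
  } else {
    nb <- 256L
    br <- seq(rng[1], rng[2], length.out = nb + 1L)
    counts <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nb)
    mids <- (br[-1] + br[-(nb + 1)]) / 2
    cand <- br[2:nb]
  }
  w <- counts / sum(counts)
  mu <- mids * w
  cw <- cumsum(w)
  cmu <- cumsum(mu)
  mu_t <- cmu[length(cmu)]
  k <- seq_len(length(mids) - 1L) # split after bin k
  w0 <- cw[k]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(k))
  sigma_b[valid] <- (mu_t * w0[valid] - cmu[k][valid])^2 / (w0[valid] * w1[valid])
  thr <- cand[which.max(sigma_b)]
  out <- voxel_volume(array(as.numeric(gray$data >= thr), dim(gray$data)),
                      gray$spacing_mm, gray$origin_mm,
                      meta = c(gray$meta, list(threshold = thr)))
  out
}

#' Keep the largest connected foreground component
#'
#' Labels the foreground with the given connectivity (26 by default, the
#' foreground convention throughout) and keeps only the largest component.
#' The number and total volume of removed components are reported in the
#' metadata.
#'
#' @param binary binary [voxel_volume()]
#' @param connectivity 26 or 6
#' @return binary [voxel_volume()] with `meta$removed_components`,
#'   `meta$removed_voxels`
#' @export
largest_component <- function(binary, connectivity = 26) {
  assert_binary(binary)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  fg <- binary$data > 0
  if (!any(fg)) stop("empty foreground: nothing to keep")
  lab <- .label_components_cpp(as.vector(fg), dim(fg), as.integer(connectivity))
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  data <- array(as.numeric(array(lab, dim(fg)) == keep), dim(fg))
  voxel_volume(data, binary$spacing_mm, binary$origin_mm,
               meta = modifyList(binary$meta, list(
                 removed_components = length(counts) - 1L,
                 removed_voxels = sum(counts) - counts[keep])))
}

#' Cylindrical region-of-interest specification
#'
#' A z-axis cylinder of given diameter and height, centred on the grid
#' centre by default, emulating the central analysis cylinder used to avoid
#' boundary effects (classically 6 mm diameter x 8 mm height).
#'
#' @param diameter_mm,height_mm cylinder size in mm (both > 0).
#' @param center_mm optional physical centre; grid centre when NULL.
#' @return object of class `roi_spec`
#' @export
roi_spec <- function(diameter_mm, height_mm, center_mm = NULL) {
  if (diameter_mm <= 0 || height_mm <= 0)
    stop("ROI diameter and height must be positive")
  structure(list(diameter_mm = diameter_mm, height_mm = height_mm,
                 center_mm = center_mm), class = "roi_spec")
}

#' Apply a cylindrical ROI
#'
#' Voxels outside the cylinder are set to background and the mask is
#' returned so that total volume (TV) is the mask volume, not the bounding
#' box.
#'
#' @param v a [voxel_volume()]
#' @param roi a [roi_spec()]
#' @return list with `volume` (masked [voxel_volume()]) and `mask`
#'   (logical array)
#' @export
apply_roi <- function(v, roi) {
  stopifnot(inherits(v, "voxel_volume"), inherits(roi, "roi_spec"))
  d <- dim(v$data)
  sp <- v$spacing_mm
  if (roi$diameter_mm > min(d[1], d[2]) * sp + 1e-9 ||
      roi$height_mm > d[3] * sp + 1e-9)
    stop("ROI is larger than the volume")
  ctr <- roi$center_mm
  if (is.null(ctr)) ctr <- v$origin_mm + d / 2 * sp
  # voxel-centre physical coordinates
  xc <- v$origin_mm[1] + (seq_len(d[1]) - 0.5) * sp
  yc <- v$origin_mm[2] + (seq_len(d[2]) - 0.5) * sp
  zc <- v$origin_mm[3] + (seq_len(d[3]) - 0.5) * sp
  r2 <- outer((xc - ctr[1])^2, (yc - ctr[2])^2, "+")
  inplane <- r2 <= (roi$diameter_mm / 2)^2
  zin <- abs(zc - ctr[3]) <= roi$height_mm / 2
  mask <- array(FALSE, d)
  for (k in which(zin)) mask[, , k] <- inplane
  if (!any(mask)) stop("ROI mask is empty at this voxel size")
  vv <- v
  vv$data[!mask] <- 0
  list(volume = vv, mask = mask)
}

#' Bone volume fraction (BV/TV, %)
#'
#' `100 * (foreground voxels within the mask) / (mask voxels)`.
#'
#' @param binary binary [voxel_volume()]
#' @param mask optional logical array (total volume = mask volume).
#' @return percentage in \[0, 100\]
#' @export
bv_tv <- function(binary, mask = NULL) {
  assert_binary(binary)
  m <- resolve_mask(binary, mask)
  if (!any(m)) stop("empty mask")
  100 * sum(binary$data[m] > 0) / sum(m)
}

# Triangulated bone surface of a binary volume: the 0.5-level isosurface of
# the lightly smoothed phase field.  Returns vertices/normals in mm and the
# per-triangle areas and centroids.  Triangles are dropped (not cut) when
# their centroid falls outside `mask`, so ROI cut faces never count as bone
# surface.
bone_surface <- function(binary, mask = NULL, smooth_sigma = 0.8) {
  assert_binary(binary)
  fg <- binary$data
  f <- .gaussian_blur3d_cpp(as.vector(fg), dim(fg), smooth_sigma)
  iso <- .isosurface_cpp(f, dim(fg), 0.5)
  V <- iso$vertices
  N <- iso$normals
  if (!nrow(V)) stop("empty surface (no bone/marrow interface)")
  if (!is.null(mask)) {
    # Keep only triangles whose centroid lies in the mask interior (mask
    # eroded by one voxel): cut faces created where the ROI slices through
    # bone sit on the mask boundary and are excluded.
    m <- resolve_mask(binary, mask)
    if (!all(m)) {
      d2 <- .edt_sq_cpp(as.vector(!m), dim(fg))
      m_int <- array(d2 > 1, dim(fg))
      cx <- (V[seq(1, nrow(V), 3), , drop = FALSE] +
               V[seq(2, nrow(V), 3), , drop = FALSE] +
               V[seq(3, nrow(V), 3), , drop = FALSE]) / 3
      ii <- pmin(pmax(round(cx) + 1, 1), rep(dim(fg), each = nrow(cx)))
      keep <- m_int[cbind(ii[, 1], ii[, 2], ii[, 3])]
      sel <- rep(keep, each = 3)
      V <- V[sel, , drop = FALSE]
      N <- N[sel, , drop = FALSE]
      if (!nrow(V)) stop("empty surface after ROI clipping")
    }
  }
  sp <- binary$spacing_mm
  list(vertices_mm = (V + 0.5) * sp, normals = N, spacing_mm = sp)
}

triangle_areas <- function(verts) {
  n <- nrow(verts) / 3
  a <- verts[seq(1, nrow(verts), 3), , drop = FALSE]
  b <- verts[seq(2, nrow(verts), 3), , drop = FALSE]
  cc <- verts[seq(3, nrow(verts), 3), , drop = FALSE]
  u <- b - a
  v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Bone surface-to-volume ratio (BS/BV, 1/mm)
#'
#' BS is the area of the triangulated 0.5-level isosurface of the bone
#' phase (restricted to the ROI interior; cut faces at the ROI boundary are
#' excluded); BV is the bone voxel count times the voxel volume.
#'
#' @param binary binary [voxel_volume()]
#' @param mask optional logical ROI array.
#' @param smooth_sigma Gaussian pre-smoothing of the phase field before
#'   isosurfacing, in voxels.
#' @return BS/BV in 1/mm
#' @export
bs_bv <- function(binary, mask = NULL, smooth_sigma = 0.8) {
  m <- resolve_mask(binary, mask)
  nbone <- sum(binary$data[m] > 0)
  if (!nbone) stop("no bone voxels in the mask")
  surf <- bone_surface(binary, mask, smooth_sigma)
  bs <- sum(triangle_areas(surf$vertices_mm))
  bv <- nbone * binary$spacing_mm^3
  bs / bv
}

#' Local thickness map (direct 3D sphere-fitting)
#'
#' Per-voxel thickness: the diameter of the largest sphere that lies fully
#' inside the phase and contains the voxel (model-independent definition).
#' Sphere radii are the Euclidean distances from phase voxel centres to the
#' nearest complement voxel centre; a sphere contains a voxel when the
#' centre distance is strictly below the radius.
#'
#' @param binary binary [voxel_volume()]
#' @param phase "foreground" (bone) or "background" (marrow).
#' @param mask optional logical array; the map is computed for phase voxels
#'   inside the mask (the complement keeps its full extent).
#' @return [voxel_volume()] whose data is the thickness map in mm (0 outside
#'   the phase)
#' @export
local_thickness <- function(binary, phase = c("foreground", "background"),
                            mask = NULL) {
  assert_binary(binary)
  phase <- match.arg(phase)
  m <- resolve_mask(binary, mask)
  fg <- binary$data > 0
  ph <- if (phase == "foreground") fg & m else (!fg) & m
  opp <- if (phase == "foreground") !fg else fg
  if (!any(ph)) stop("empty ", phase, " phase")
  if (!any(opp)) stop("no opposite phase: thickness is unbounded")
  r2 <- .edt_sq_cpp(as.vector(opp), dim(fg))
  th2 <- .local_thickness_sq_cpp(as.vector(ph), r2, dim(fg))
  map <- array(2 * sqrt(th2) * binary$spacing_mm, dim(fg))
  voxel_volume(map, binary$spacing_mm, binary$origin_mm,
               meta = list(measure = paste0("local_thickness_", phase)))
}

#' Trabecular thickness (Tb.Th, mm)
#'
#' Volume-weighted mean of the local thickness map over the bone phase
#' within the mask.
#' @inheritParams local_thickness
#' @param mask optional logical ROI array
#' @return mm
#' @export
tb_th <- function(binary, mask = NULL) {
  m <- resolve_mask(binary, mask)
  map <- local_thickness(binary, "foreground", mask)
  sel <- (binary$data > 0) & m
  mean(map$data[sel])
}

#' Trabecular separation (Tb.Sp, mm)
#'
#' The same sphere-fitting thickness applied to the marrow phase within the
#' ROI.
#' @inheritParams tb_th
#' @return mm
#' @export
tb_sp <- function(binary, mask = NULL) {
  m <- resolve_mask(binary, mask)
  map <- local_thickness(binary, "background", mask)
  sel <- (binary$data == 0) & m
  if (!any(sel)) stop("no marrow voxels in the mask")
  mean(map$data[sel])
}

#' Trabecular number (Tb.N, 1/mm)
#'
#' Plate-model convention: `Tb.N = (BV/TV as a fraction) / Tb.Th`.
#'
#' @param bv_tv bone volume fraction in percent.
#' @param tb_th trabecular thickness in mm (> 0).
#' @return 1/mm
#' @export
tb_n <- function(bv_tv, tb_th) {
  if (tb_th <= 0) stop("tb_th must be positive")
  (bv_tv / 100) / tb_th
}

#' Structure model index (SMI)
#'
#' `SMI = 6 * V * S' / S^2` where S and V are the bone surface area and
#' volume and `S' = (S(r) - S)/r` is the surface-area derivative estimated
#' by offsetting each surface vertex outward along its normal by `r`.
#' Plates give values near 0, rods near 3, spheres near 4; concave surfaces
#' can give negative values.
#'
#' @param binary binary [voxel_volume()]
#' @param mask optional logical ROI array.
#' @param dilation_mm offset distance r; default half a voxel.
#' @param smooth_sigma phase-field smoothing (voxels) before isosurfacing.
#' @return dimensionless SMI
#' @export
smi <- function(binary, mask = NULL, dilation_mm = NULL, smooth_sigma = 0.8) {
  m <- resolve_mask(binary, mask)
  nbone <- sum(binary$data[m] > 0)
  if (!nbone) stop("no bone voxels in the mask")
  if (is.null(dilation_mm)) dilation_mm <- 0.5 * binary$spacing_mm
  surf <- bone_surface(binary, mask, smooth_sigma)
  s0 <- sum(triangle_areas(surf$vertices_mm))
  v_off <- surf$vertices_mm + dilation_mm * surf$normals
  s1 <- sum(triangle_areas(v_off))
  sprime <- (s1 - s0) / dilation_mm
  vol <- nbone * binary$spacing_mm^3
  6 * vol * sprime / s0^2
}

# quasi-uniform directions on the upper hemisphere (Fibonacci lattice)
hemisphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Mean-intercept-length fabric tensor
#'
#' For each of `n_directions` quasi-uniform hemisphere directions a parallel
#' grid of test lines is cast through the masked volume;
#' `MIL(w) = total bone length / bone-marrow crossings`.  The quadric
#' `1/MIL^2(w) = w' H w` is fitted by least squares and the MIL ellipsoid
#' semi-axis lengths (`1/sqrt(eigenvalues of H)`, in mm) are returned in
#' decreasing order with their principal directions.
#'
#' @param binary binary [voxel_volume()]
#' @param mask optional logical ROI array.
#' @param n_directions number of test directions (default 257).
#' @param line_spacing_vox spacing of the test-line grid, in voxels.
#' @param step_vox sampling step along each line, in voxels (0.25 by
#'   default; coarser steps miss thin marrow gaps and bias MIL upward).
#' @param seed seed for the per-direction random line-grid offsets.
#' @return object of class `fabric_tensor`: `tensor` (fitted H), ordered
#'   `eigenvalues` (semi-axes, mm), `eigenvectors`, `mil_mm` per direction
#' @export
mil_fabric <- function(binary, mask = NULL, n_directions = 257,
                       line_spacing_vox = 2, step_vox = 0.25, seed = 1) {
  assert_binary(binary)
  m <- resolve_mask(binary, mask)
  fg <- binary$data > 0
  if (!any(fg & m)) stop("no bone in the mask")
  if (!any(!fg & m)) stop("no marrow in the mask: MIL needs both phases")
  dirs <- hemisphere_directions(n_directions)
  offs <- with_seed(seed, matrix(runif(2 * n_directions), ncol = 2))
  cast <- .mil_cast_cpp(as.vector(fg), as.vector(m), dim(fg), dirs,
                        line_spacing_vox, step_vox, offs)
  len_mm <- cast[, 1] * binary$spacing_mm
  crossings <- cast[, 2]
  ok <- crossings > 0 & len_mm > 0
  if (any(!ok))
    warning(sum(!ok), " direction(s) with no bone-marrow crossings dropped")
  if (sum(ok) < 9)
    stop("fewer than 9 usable directions: fabric tensor under-determined")
  mil <- len_mm[ok] / crossings[ok]
  w <- dirs[ok, , drop = FALSE]
  A <- cbind(w[, 1]^2, w[, 2]^2, w[, 3]^2,
             2 * w[, 1] * w[, 2], 2 * w[, 1] * w[, 3], 2 * w[, 2] * w[, 3])
  h <- qr.solve(A, 1 / mil^2)
  H <- matrix(c(h[1], h[4], h[5],
                h[4], h[2], h[6],
                h[5], h[6], h[3]), 3, 3)
  e <- eigen(H, symmetric = TRUE)
  ev <- e$values
  if (max(ev) <= 0) stop("degenerate MIL fabric (non-positive quadric)")
  # a perfectly layered structure has an unbounded in-plane MIL: the quadric
  # eigenvalue goes to zero (or slightly negative from the fit); clip it so
  # the semi-axis is finite and DA -> 1
  tiny <- ev < 1e-8 * max(ev)
  if (any(tiny)) {
    warning("nearly degenerate MIL fabric: unbounded semi-axes clipped (DA ~ 1)")
    ev[tiny] <- 1e-8 * max(ev)
  }
  semi <- 1 / sqrt(ev) # increasing eigenvalue of H = longest semi-axis
  ord <- order(semi, decreasing = TRUE)
  structure(list(tensor = H, eigenvalues = semi[ord],
                 eigenvectors = e$vectors[, ord, drop = FALSE],
                 mil_mm = mil, directions = w),
            class = "fabric_tensor")
}

#' @export
print.fabric_tensor <- function(x, ...) {
  cat("<fabric_tensor> MIL semi-axes (mm):",
      paste(sprintf("%.4g", x$eigenvalues), collapse = ", "), "\n")
  cat("  DA =", sprintf("%.3f", degree_of_anisotropy(x)), "\n")
  invisible(x)
}

#' Degree of anisotropy (DA, 0 = isotropic)
#'
#' The bounded form `DA = 1 - shortest/longest MIL semi-axis`, ranging from
#' 0 (isotropic) to 1 (fully anisotropic).
#'
#' @param f a [mil_fabric()] result (or a numeric vector of semi-axes).
#' @return DA in \[0, 1\]
#' @export
degree_of_anisotropy <- function(f) {
  ev <- if (inherits(f, "fabric_tensor")) f$eigenvalues else as.numeric(f)
  1 - min(ev) / max(ev)
}

#' Ellipsoid factor (EF)
#'
#' Seeds are placed on the distance-ridge (medial axis) of the bone phase;
#' from each seed a maximal ellipsoid is grown inside the bone along locally
#' estimated principal directions.  Each bone voxel takes the
#' `EF = a/b - b/c` (semi-axes a <= b <= c) of the largest-volume ellipsoid
#' containing it: -1 for plates, +1 for rods, 0 for spheres.
#'
#' @param binary binary [voxel_volume()]
#' @param mask optional logical ROI array (the sample mean and coverage are
#'   computed inside it; ellipsoids may extend through bone outside).
#' @param n_seeds number of seed points to draw from the distance ridge.
#' @param growth_step semi-axis dilation per step, in voxels.
#' @param max_iterations growth iterations per ellipsoid.
#' @param seed RNG seed for the seed-point draw.
#' @return list: `ef_sample` (volume-weighted mean EF), `map`
#'   ([voxel_volume()] of per-voxel EF, NA where uncovered), `coverage`
#'   (fraction of bone voxels covered), `n_seeds_used`
#' @export
ellipsoid_factor <- function(binary, mask = NULL, n_seeds = 120,
                             growth_step = 0.5, max_iterations = 200,
                             seed = 1) {
  assert_binary(binary)
  m <- resolve_mask(binary, mask)
  fg <- binary$data > 0
  if (!any(fg)) stop("empty foreground")
  d <- dim(fg)
  r2 <- array(.edt_sq_cpp(as.vector(!fg), d), d)

  # distance ridge: local maxima of the squared EDT over the 26-neighbourhood
  ridge <- fg
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (!di && !dj && !dk) next
    shifted <- array(0, d)
    xs <- max(1, 1 + di):min(d[1], d[1] + di)
    ys <- max(1, 1 + dj):min(d[2], d[2] + dj)
    zs <- max(1, 1 + dk):min(d[3], d[3] + dk)
    shifted[xs - di, ys - dj, zs - dk] <- r2[xs, ys, zs]
    ridge <- ridge & (r2 >= shifted)
  }
  ridge <- ridge & m & (r2 > 0)
  cand <- which(ridge)
  if (!length(cand)) stop("no seed candidates on the distance ridge")
  sel <- with_seed(seed, {
    if (length(cand) > n_seeds) sort(sample(cand, n_seeds)) else cand
  })
  if (!length(sel)) stop("zero seeds")
  sc <- arrayInd(sel, d)

  # local orientation from the structure tensor: the sum of outer products
  # of the smoothed phase-field gradient over a neighbourhood.  Gradients
  # live on the phase boundary, so for a plate the dominant eigenvector is
  # the normal and for a rod the minor eigenvector is the axis; the growth
  # itself discovers which axes are long.
  fsm <- array(.gaussian_blur3d_cpp(as.vector(as.numeric(fg)), d, 1.0), d)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (fsm[3:d[1], , ] - fsm[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (fsm[, 3:d[2], ] - fsm[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (fsm[, , 3:d[3]] - fsm[, , 1:(d[3] - 2)]) / 2
  rots <- matrix(0, nrow(sc), 9)
  r0 <- numeric(nrow(sc))
  for (s in seq_len(nrow(sc))) {
    rad <- max(5, ceiling(2.5 * sqrt(r2[sel[s]])))
    lo <- pmax(1, sc[s, ] - rad)
    hi <- pmin(d, sc[s, ] + rad)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    g <- cbind(as.vector(gx[ii, jj, kk]), as.vector(gy[ii, jj, kk]),
               as.vector(gz[ii, jj, kk]))
    ST <- crossprod(g)
    if (!all(is.finite(ST)) || sum(diag(ST)) < 1e-12) ST <- diag(3)
    ev <- eigen(ST, symmetric = TRUE)
    R <- ev$vectors
    if (det(R) < 0) R[, 3] <- -R[, 3]
    rots[s, ] <- as.vector(R)
    r0[s] <- max(0.5, sqrt(r2[sel[s]]) - 0.5)
  }

  sdirs <- fibonacci_sphere(162)
  # growth runs against the smoothed phase field: tolerant of single-voxel
  # surface roughness, still blocked by real marrow gaps
  field <- .gaussian_blur3d_cpp(as.vector(as.numeric(fg)), d, 0.5)
  axes <- .grow_ellipsoids_cpp(field, 0.45, d, sc - 1, rots, r0,
                               growth_step, as.integer(max_iterations), sdirs)
  srt <- t(apply(axes, 1, sort))
  ef_vals <- srt[, 1] / srt[, 2] - srt[, 2] / srt[, 3]
  vols <- srt[, 1] * srt[, 2] * srt[, 3]
  ord <- order(vols, decreasing = TRUE) - 1L
  map <- .assign_ef_cpp(as.vector(fg), d, sc - 1, rots, axes, ef_vals,
                        as.integer(ord))
  map <- array(map, d)
  inmask <- fg & m
  covered <- inmask & !is.na(map)
  coverage <- sum(covered) / sum(inmask)
  if (coverage < 0.5)
    warning(sprintf("ellipsoid coverage %.0f%% of bone voxels: EF unreliable",
                    100 * coverage))
  ef_sample <- mean(map[covered])
  list(ef_sample = ef_sample,
       map = voxel_volume(ifelse(is.na(map), NA_real_, map), binary$spacing_mm,
                          binary$origin_mm, meta = list(measure = "ef")),
       coverage = coverage, n_seeds_used = nrow(sc))
}

#' Microarchitecture analysis settings
#'
#' Collects the tunable settings (and seeds) of the stochastic
#' microarchitecture operations so that [microarch_profile()] is
#' deterministic given its config.
#'
#' @param mil named list overriding [mil_fabric()] arguments.
#' @param ef named list overriding [ellipsoid_factor()] arguments.
#' @param smi named list overriding [smi()] arguments.
#' @return object of class `microarch_config`
#' @export
microarch_config <- function(mil = list(), ef = list(), smi = list()) {
  structure(list(
    mil = modifyList(list(n_directions = 257, line_spacing_vox = 2,
                          step_vox = 0.25, seed = 1), mil),
    ef = modifyList(list(n_seeds = 120, growth_step = 0.5,
                         max_iterations = 200, seed = 1), ef),
    smi = modifyList(list(dilation_mm = NULL, smooth_sigma = 0.8), smi)),
    class = "microarch_config")
}

#' Full microarchitectural profile of one sample
#'
#' Computes the eight parameters (BV/TV, BS/BV, Tb.Th, Tb.N, Tb.Sp, SMI,
#' DA, EF) in one call.  Deterministic given the seeds in `config`.
#'
#' @param binary binary [voxel_volume()]
#' @param mask optional logical ROI array.
#' @param config a [microarch_config()]
#' @return object of class `microarch_profile` (named list of the eight
#'   parameters plus diagnostics `ef_coverage`)
#' @export
microarch_profile <- function(binary, mask = NULL, config = microarch_config()) {
  stopifnot(inherits(config, "microarch_config"))
  bvtv <- bv_tv(binary, mask)
  bsbv <- bs_bv(binary, mask, smooth_sigma = config$smi$smooth_sigma)
  th <- tb_th(binary, mask)
  sp <- tb_sp(binary, mask)
  smi_v <- do.call(smi, c(list(binary = binary, mask = mask), config$smi))
  fab <- do.call(mil_fabric, c(list(binary = binary, mask = mask), config$mil))
  da <- degree_of_anisotropy(fab)
  efr <- do.call(ellipsoid_factor, c(list(binary = binary, mask = mask), config$ef))
  structure(list(bv_tv = bvtv, bs_bv = bsbv, tb_th = th,
                 tb_n = tb_n(bvtv, th), tb_sp = sp, smi = smi_v,
                 da = da, ef = efr$ef_sample, ef_coverage = efr$coverage),
            class = "microarch_profile")
}

#' @export
print.microarch_profile <- function(x, ...) {
  cat("<microarch_profile>\n")
  cat(sprintf("  BV/TV %.1f %%   BS/BV %.2f 1/mm   Tb.Th %.3f mm\n",
              x$bv_tv, x$bs_bv, x$tb_th))
  cat(sprintf("  Tb.N  %.2f 1/mm Tb.Sp %.3f mm\n", x$tb_n, x$tb_sp))
  cat(sprintf("  SMI %.2f   DA %.3f   EF %.3f (coverage %.0f%%)\n",
              x$smi, x$da, x$ef, 100 * x$ef_coverage))
  invisible(x)
}

#' @export
as.data.frame.microarch_profile <- function(x, ...) {
  data.frame(BV_TV = x$bv_tv, BS_BV = x$bs_bv, Tb_Th = x$tb_th,
             Tb_N = x$tb_n, Tb_Sp = x$tb_sp, SMI = x$smi, DA = x$da,
             EF = x$ef)
}

#' Root-mean-square coefficient of variation (RMSCV, %)
#'
#' Precision metric over repeated measurements:
#' `RMSCV = 100 * sqrt(mean_i (SD_i / mean_i)^2)` where SD_i and mean_i are
#' taken over the replicates of sample i.  Parameters whose within-sample
#' mean is zero are reported as NA.
#'
#' @param replicate_profiles a list (one element per sample) of lists of
#'   [microarch_profile()]s, or of single-row data frames with identical
#'   columns.
#' @return named numeric vector of per-parameter RMSCV percentages
#' @export
rmscv <- function(replicate_profiles) {
  if (length(replicate_profiles) < 1) stop("at least one sample required")
  tabs <- lapply(replicate_profiles, function(reps) {
    if (length(reps) < 2) stop("each sample needs >= 2 replicates")
    do.call(rbind, lapply(reps, function(p)
      if (inherits(p, "microarch_profile")) as.data.frame(p) else as.data.frame(p)))
  })
  params <- colnames(tabs[[1]])
  out <- sapply(params, function(pn) {
    cv2 <- sapply(tabs, function(tb) {
      mu <- mean(tb[[pn]])
      if (mu == 0) return(NA_real_)
      (sd(tb[[pn]]) / mu)^2
    })
    100 * sqrt(mean(cv2))
  })
  names(out) <- params
  out
}
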