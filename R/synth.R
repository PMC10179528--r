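## Synthetic microstructures: analytic primitives with known ground truth and
## trabecular-like plate/rod composites, so every downstream stage can be
## exercised and checked without scanner data.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Solid calibration block
#'
#' A fully or partially filled box: the lowest `round(fill_fraction * Nz)`
#' z-slabs are solid bone.  Used as a known-answer fixture for volume
#' fraction, boundary-condition arithmetic and the FE patch test.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing_mm isotropic voxel size (mm).
#' @param fill_fraction 1.0 for a solid block, or a fraction in (0,1) filling
#'   the lowest z-slab.
#' @return binary [voxel_volume()]
#' @examples
#' v <- make_block(c(10, 10, 10), 0.05, 0.5)
#' mean(v$data) # 0.5
#' @export
make_block <- function(shape, spacing_mm, fill_fraction = 1.0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stop("`shape` must be 3 values >= 2")
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be positive")
  if (fill_fraction <= 0 || fill_fraction > 1)
    stop("`fill_fraction` must be in (0, 1]")
  nzfill <- if (fill_fraction == 1.0) shape[3] else round(fill_fraction * shape[3])
  data <- array(0, shape)
  if (nzfill > 0) data[, , seq_len(nzfill)] <- 1
  voxel_volume(data, spacing_mm, meta = list(generator = "block",
                                             fill_fraction = fill_fraction))
}

# squared distance field helpers -------------------------------------------

# voxel-centre coordinates (1-based indices) relative to the grid centre
grid_axes <- function(shape) {
  lapply(shape, function(n) seq_len(n) - (n + 1) / 2)
}

#' Voxelized analytic primitive
#'
#' Binary voxelization of a sphere, a z-axis cylinder or a z-normal plate,
#' centred in the grid.  A voxel is solid when its centre lies inside the
#' analytic solid.  Primitives must leave at least two voxels of background
#' margin; with `allow_span = TRUE` an extent that covers the whole grid
#' along an axis is clipped instead (deliberate, to build open-ended rod and
#' edge-free plate fixtures for the surface-based shape indices).
#'
#' @param kind "sphere", "cylinder" or "plate".
#' @param dims_mm sphere: radius; cylinder: c(radius, length); plate:
#'   c(width_x, width_y, thickness).
#' @param shape grid dimensions.
#' @param spacing_mm voxel size (mm).
#' @param allow_span allow extents that span the full grid along an axis.
#' @return binary [voxel_volume()]
#' @examples
#' sph <- make_primitive("sphere", 0.2, c(24, 24, 24), 0.025)
#' @export
make_primitive <- function(kind = c("sphere", "cylinder", "plate"), dims_mm,
                           shape, spacing_mm, allow_span = FALSE) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be positive")
  ax <- grid_axes(shape)
  margin <- 2
  check_fit <- function(extent_vox, axis) {
    # extent_vox: full extent along `axis` in voxels
    if (extent_vox <= shape[axis] - 2 * margin) return(FALSE) # fits, no span
    if (allow_span && extent_vox >= shape[axis]) return(TRUE) # spans fully
    stop("primitive exceeds the grid (needs >= 2 voxels of margin); ",
         "enlarge the grid or use allow_span = TRUE to span the full extent")
  }
  data <- array(0, shape)
  if (kind == "sphere") {
    r <- dims_mm[1] / spacing_mm
    check_fit(2 * r, 1); check_fit(2 * r, 2); check_fit(2 * r, 3)
    d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
    data[d2 <= r^2] <- 1
  } else if (kind == "cylinder") {
    r <- dims_mm[1] / spacing_mm
    len <- dims_mm[2] / spacing_mm
    check_fit(2 * r, 1); check_fit(2 * r, 2); check_fit(len, 3)
    rad2 <- outer(ax[[1]]^2, ax[[2]]^2, "+")
    inplane <- rad2 <= r^2
    zin <- abs(ax[[3]]) <= len / 2
    for (k in which(zin)) data[, , k] <- as.numeric(inplane)
  } else {
    wx <- dims_mm[1] / spacing_mm
    wy <- dims_mm[2] / spacing_mm
    th <- dims_mm[3] / spacing_mm
    check_fit(wx, 1); check_fit(wy, 2); check_fit(th, 3)
    xin <- abs(ax[[1]]) <= wx / 2
    yin <- abs(ax[[2]]) <= wy / 2
    zin <- abs(ax[[3]]) <= th / 2
    for (k in which(zin)) data[xin, yin, k] <- 1
  }
  if (!sum(data)) stop("primitive voxelized to an empty volume (too small for this spacing)")
  voxel_volume(data, spacing_mm,
               meta = list(generator = "primitive", kind = kind,
                           dims_mm = dims_mm))
}

#' Trabecular generator specification
#'
#' Parameters of the plate/rod Boolean-union trabecular generator.  The
#' defaults emulate human femoral-head trabecular bone: target volume
#' fraction `thickness_mm / spacing_struct_mm` (about 31%), strut thickness
#' 0.2 mm, characteristic spacing 0.65 mm, and a moderate axial orientation
#' concentration.
#'
#' @param shape grid dimensions (default 64^3).
#' @param spacing_mm voxel size in mm (default 0.05).
#' @param rod_fraction fraction of placed solid volume contributed by rods,
#'   in \[0,1\].
#' @param thickness_mm strut/plate thickness (mm); must be at least two
#'   voxels so structures are resolvable.
#' @param spacing_struct_mm characteristic centre-to-centre spacing between
#'   structures (mm); the generator fills until the volume fraction reaches
#'   `thickness_mm / spacing_struct_mm`.
#' @param kappa orientation concentration: 0 draws directions isotropically;
#'   large values align rod axes with z and plate normals with the
#'   transverse plane.
#' @param seed RNG seed; equal specs with equal seeds give bit-identical
#'   volumes.
#' @return object of class `trabecular_spec`
#' @export
trabecular_spec <- function(shape = c(64, 64, 64), spacing_mm = 0.05,
                            rod_fraction = 0.5, thickness_mm = 0.2,
                            spacing_struct_mm = 0.65, kappa = 12, seed = 1) {
  if (rod_fraction < 0 || rod_fraction > 1) stop("`rod_fraction` must be in [0,1]")
  if (thickness_mm < 2 * spacing_mm)
    stop("`thickness_mm` must be >= 2 * spacing_mm (structures must be resolvable)")
  if (spacing_struct_mm <= thickness_mm)
    stop("`spacing_struct_mm` must exceed `thickness_mm`")
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 rod_fraction = rod_fraction, thickness_mm = thickness_mm,
                 spacing_struct_mm = spacing_struct_mm, kappa = kappa,
                 seed = seed),
            class = "trabecular_spec")
}

# Axially symmetric (Watson-type) direction sampling: density on the unit
# sphere proportional to exp(kappa * (v.z)^2).  kappa > 0 concentrates along
# z (bipolar); kappa < 0 concentrates in the transverse plane (girdle);
# kappa = 0 is isotropic.  Rejection sampling from the uniform sphere.
sample_axis <- function(kappa) {
  repeat {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    lp <- if (kappa >= 0) kappa * (v[3]^2 - 1) else kappa * v[3]^2
    if (log(runif(1)) < lp) return(v)
  }
}

orthobasis <- function(w) {
  a <- if (abs(w[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- c(w[2] * a[3] - w[3] * a[2], w[3] * a[1] - w[1] * a[3],
          w[1] * a[2] - w[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2] * e1[3] - w[3] * e1[2], w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# rasterize a capsule (segment + radius) into logical array `acc` (voxels)
add_capsule <- function(acc, c0, axis, half_len, radius) {
  d <- dim(acc)
  lo <- pmax(1, floor(c0 - half_len - radius - 1))
  hi <- pmin(d, ceiling(c0 + half_len + radius + 1))
  if (any(lo > hi)) return(acc)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(x = ii, y = jj, z = kk)
  p <- t(t(as.matrix(g)) - c0)
  t_ax <- p %*% axis
  t_cl <- pmin(pmax(t_ax, -half_len), half_len)
  d2 <- rowSums((p - t_cl %*% t(axis))^2)
  sel <- d2 <= radius^2
  if (any(sel)) {
    idx <- cbind(g$x[sel], g$y[sel], g$z[sel])
    acc[idx] <- TRUE
  }
  acc
}

# rasterize a finite plate (thin box): normal n, half-thickness ht,
# in-plane half-extent he (square)
add_plate <- function(acc, c0, normal, ht, he) {
  d <- dim(acc)
  r <- sqrt(ht^2 + 2 * he^2)
  lo <- pmax(1, floor(c0 - r - 1))
  hi <- pmin(d, ceiling(c0 + r + 1))
  if (any(lo > hi)) return(acc)
  b <- orthobasis(normal)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(x = ii, y = jj, z = kk)
  p <- t(t(as.matrix(g)) - c0)
  sel <- abs(p %*% normal) <= ht & abs(p %*% b$e1) <= he & abs(p %*% b$e2) <= he
  if (any(sel)) {
    idx <- cbind(g$x[sel], g$y[sel], g$z[sel])
    acc[idx] <- TRUE
  }
  acc
}

#' Generate a trabecular-like microstructure
#'
#' Boolean union of randomly placed plates (thin boxes) and rods (capsules)
#' with orientations drawn from an axially symmetric distribution, followed
#' by morphological closing and largest-component extraction.  The achieved
#' volume fraction is reported in the metadata (`meta$achieved_bvtv`), along
#' with the spec and seed.
#'
#' @param spec a [trabecular_spec()]
#' @return binary [voxel_volume()] with a single 26-connected component
#' @examples
#' v <- make_trabecular(trabecular_spec(shape = c(32, 32, 32), seed = 7))
#' v$meta$achieved_bvtv
#' @export
make_trabecular <- function(spec) {
  stopifnot(inherits(spec, "trabecular_spec"))
  sh <- spec$shape
  sp <- spec$spacing_mm
  target <- spec$thickness_mm / spec$spacing_struct_mm
  th_vox <- spec$thickness_mm / sp
  # a voxel centre lies inside the rasterized solid when its distance to the
  # axis/mid-plane is below r: subtract half a voxel so the realized width
  # of the voxelized strut matches thickness_mm
  half_th <- max(0.6, th_vox / 2 - 1.25)
  half_rod_len <- spec$spacing_struct_mm * 2.0 / sp
  half_plate_ext <- spec$spacing_struct_mm * 1.0 / sp

  acc <- with_seed(spec$seed, {
    acc <- array(FALSE, sh)
    ntot <- prod(sh)
    max_structs <- 4000L
    placed <- 0L
    while (sum(acc) / ntot < 0.88 * target && placed < max_structs) {
      c0 <- runif(3) * (sh - 1) + 1
      if (runif(1) < spec$rod_fraction) {
        axis <- sample_axis(spec$kappa)
        acc <- add_capsule(acc, c0, axis, half_rod_len, half_th)
      } else {
        normal <- sample_axis(-spec$kappa)
        acc <- add_plate(acc, c0, normal, half_th, half_plate_ext)
      }
      placed <- placed + 1L
    }
    acc
  })
  # morphological closing with a Euclidean ball of one voxel radius
  rc <- 1.0
  d2fg <- .edt_sq_cpp(as.vector(acc), dim(acc))
  dil <- d2fg <= rc^2
  d2bg <- .edt_sq_cpp(!dil, dim(acc))
  closed <- array(d2bg > rc^2, dim(acc))

  lab <- array(.label_components_cpp(as.vector(closed), dim(closed), 26L), dim(closed))
  if (max(lab) == 0) stop("generated volume is empty")
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  data <- array(as.numeric(lab == keep), dim(closed))

  reached <- mean(data) >= target * 0.85
  if (!reached)
    warning("target volume fraction not reached; best-effort volume flagged in metadata")

  voxel_volume(data, sp, meta = list(
    generator = "trabecular", spec = unclass(spec),
    achieved_bvtv = mean(data), target_bvtv = target,
    target_reached = reached))
}

#' Simulated repeat scans of one sample
#'
#' Emulates scanning the same physical sample several times: the binary
#' phase is scaled to a two-level grayscale (0 background / 255 bone) and
#' additive Gaussian noise of standard deviation `noise_sd` is applied
#' independently per scan.  Each scan is intended to be re-thresholded and
#' re-measured downstream, feeding the RMSCV precision metric.
#'
#' @param volume binary [voxel_volume()]
#' @param noise_sd noise standard deviation in gray levels.
#' @param n number of repeat scans (>= 2).
#' @param seed RNG seed.
#' @return list of `n` grayscale [voxel_volume()]s
#' @export
make_repeat_scans <- function(volume, noise_sd, n, seed = 1) {
  assert_binary(volume)
  if (n < 2) stop("`n` must be >= 2")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  base <- volume$data * 255
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      g <- base + array(rnorm(length(base), sd = noise_sd), dim(base))
      voxel_volume(g, volume$spacing_mm,
                   meta = list(generator = "repeat_scan", replicate = i,
                               noise_sd = noise_sd))
    })
  })
}

#' Synthetic dataset for the composite-index regression
#'
#' Draws DA uniform on \[0,1\] and EF uniform on \[-1,1\] and builds
#' `Y = beta0 + beta1*DA + beta2*EF + N(0, noise_sd)` — the parameter-recovery
#' fixture for the multilinear fit.
#'
#' @param beta0,beta1,beta2 true coefficients.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n number of samples (>= 3).
#' @param seed RNG seed.
#' @return data.frame with columns DA, EF, Y
#' @export
make_regression_dataset <- function(beta0, beta1, beta2, noise_sd, n, seed = 1) {
  if (n < 3) stop("`n` must be >= 3")
  with_seed(seed, {
    DA <- runif(n, 0, 1)
    EF <- runif(n, -1, 1)
    Y <- beta0 + beta1 * DA + beta2 * EF + rnorm(n, sd = noise_sd)
    data.frame(DA = DA, EF = EF, Y = Y)
  })
}
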