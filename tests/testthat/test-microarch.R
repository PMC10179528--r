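test_that("global Otsu separates two-level volumes and flags degenerate input", {
  d <- array(40, c(12, 12, 12))
  d[5:8, 5:8, 5:8] <- 200
  v <- voxel_volume(d, 0.05)
  b <- otsu_threshold(v)
  expect_identical(b$data, array(as.numeric(d == 200), dim(d)))
  expect_true(b$meta$threshold > 40 && b$meta$threshold < 200)

  # Gaussian noise sd 20 on levels {40, 200}: misclassification is the
  # normal tail beyond the midpoint, < 1%
  set.seed(5)
  noisy <- voxel_volume(d + array(rnorm(length(d), sd = 20), dim(d)), 0.05)
  bn <- otsu_threshold(noisy)
  expect_lt(mean(bn$data != (d == 200)), 0.01)

  already <- voxel_volume(array(as.numeric(d == 200), dim(d)), 0.05)
  expect_identical(otsu_threshold(already)$data, already$data)

  expect_error(otsu_threshold(voxel_volume(array(7, c(4, 4, 4)), 1)),
               "no threshold")
})

test_that("largest_component agrees with a brute-force flood fill", {
  d <- array(0, c(14, 14, 14))
  # two disjoint spheres, radii 5 and 3
  for (s in list(list(c = c(5, 5, 5), r = 4), list(c = c(11, 11, 11), r = 2.5))) {
    g <- as.matrix(expand.grid(1:14, 1:14, 1:14))
    d[g[rowSums(sweep(g, 2, s$c)^2) <= s$r^2, , drop = FALSE]] <- 1
  }
  v <- voxel_volume(d, 0.05)
  kept <- largest_component(v)
  lab <- label_oracle(d > 0)
  sizes <- tabulate(lab[lab > 0])
  expect_equal(sum(kept$data), max(sizes))
  expect_equal(kept$meta$removed_voxels, sum(sizes) - max(sizes))
  expect_equal(kept$meta$removed_components, length(sizes) - 1L)

  # identity on a single component
  single <- largest_component(kept)
  expect_identical(single$data, kept$data)
  expect_equal(single$meta$removed_components, 0L)

  # random speckle + one rod: the rod survives, removed count = speckle count
  set.seed(8)
  sp <- array(0, c(16, 16, 16))
  sp[8, 8, 3:14] <- 1 # rod, 12 voxels
  speckle <- sample(which(sp == 0), 25)
  # keep speckle strictly away from the rod so nothing merges
  pts <- arrayInd(speckle, dim(sp))
  far <- abs(pts[, 1] - 8) > 2 | abs(pts[, 2] - 8) > 2
  sp[speckle[far]] <- 1
  vs <- voxel_volume(sp, 0.05)
  ks <- largest_component(vs)
  lab2 <- label_oracle(sp > 0)
  expect_equal(sum(ks$data), max(tabulate(lab2[lab2 > 0])))

  expect_error(largest_component(voxel_volume(array(0, c(4, 4, 4)), 1)),
               "empty")
})

test_that("cylindrical ROI masks voxels but keeps TV = mask volume", {
  v <- make_block(c(40, 40, 40), 0.1) # 4 mm cube, solid
  r <- apply_roi(v, roi_spec(2, 2))
  expect_lt(sum(r$mask), length(v$data) * 0.55)
  expect_equal(bv_tv(r$volume, r$mask), 100) # TV is the ROI volume

  # inscribed full-width cylinder: mask volume ~ pi/4 of the slab
  r2 <- apply_roi(v, roi_spec(4, 4))
  expect_rel(sum(r2$mask), pi / 4 * 40^2 * 40, 0.01)

  expect_error(apply_roi(v, roi_spec(10, 2)), "larger")
  expect_error(roi_spec(2, 0), "positive")
})

test_that("bv_tv is an exact voxel tally", {
  v <- make_trabecular(trabecular_spec(shape = c(32, 32, 32), seed = 2))
  m <- array(FALSE, dim(v$data))
  m[5:28, 3:30, 2:31] <- TRUE
  expect_equal(bv_tv(v, m), 100 * sum(v$data[m] > 0) / sum(m))
  expect_error(bv_tv(v, array(FALSE, dim(v$data))), "empty mask")
})

test_that("surface-based BS/BV matches analytic sphere and cylinder values", {
  s <- make_primitive("sphere", 0.5, c(48, 48, 48), 0.025)
  expect_rel(bs_bv(s), 3 / 0.5, 0.05)
  rod <- make_primitive("cylinder", c(0.1, 10), c(48, 48, 64), 0.0125,
                        allow_span = TRUE)
  expect_rel(bs_bv(rod), 2 / 0.1, 0.05)
  # mesh-convergence: doubling the spacing changes BS/BV by < 5%
  s2 <- make_primitive("sphere", 0.5, c(24, 24, 24), 0.05)
  expect_rel(bs_bv(s2), bs_bv(s), 0.05)
})

test_that("local thickness matches analytic plates, rods and gaps", {
  pl <- make_primitive("plate", c(10, 10, 0.1), c(32, 32, 32), 0.025,
                       allow_span = TRUE)
  expect_lt(abs(tb_th(pl) - 0.1), 0.025) # within one voxel
  cyl <- make_primitive("cylinder", c(0.1, 10), c(32, 32, 32), 0.025,
                        allow_span = TRUE)
  expect_lt(abs(tb_th(cyl) - 0.2), 0.025)
  # two plates 0.6 mm apart: gap is the only marrow
  d <- array(0, c(24, 24, 40))
  d[, , 1:14] <- 1
  d[, , 27:40] <- 1
  expect_lt(abs(tb_sp(voxel_volume(d, 0.05)) - 0.6), 0.05)
})

test_that("local thickness equals the brute-force inscribed-sphere oracle", {
  v <- make_trabecular(trabecular_spec(shape = c(16, 16, 16), seed = 4,
                                       spacing_mm = 0.1, thickness_mm = 0.25,
                                       spacing_struct_mm = 0.8))
  fg <- v$data > 0
  map <- local_thickness(v)
  oracle <- 2 * sqrt(thickness_oracle_sq(fg)) * v$spacing_mm
  expect_equal(map$data[fg], oracle[fg], tolerance = 1e-12)
  # background phase too
  mapb <- local_thickness(v, "background")
  oracleb <- 2 * sqrt(thickness_oracle_sq(!fg)) * v$spacing_mm
  expect_equal(mapb$data[!fg], oracleb[!fg], tolerance = 1e-12)
})

test_that("tb_n follows the plate-model convention", {
  expect_equal(tb_n(30.9, 0.2), 1.545)
  expect_equal(tb_n(100, 0.8), 1 / 0.8) # solid limit: 1/height
  expect_equal(tb_n(20, 0.1), 2)
  expect_error(tb_n(50, 0), "positive")
})

test_that("SMI hits the plate, rod and sphere reference values", {
  pl <- make_block(c(48, 48, 48), 0.025, 0.5)
  expect_lt(abs(smi(pl)), 0.5)
  rod <- make_primitive("cylinder", c(0.1, 10), c(48, 48, 64), 0.0125,
                        allow_span = TRUE)
  expect_lt(abs(smi(rod) - 3), 0.5)
  s <- make_primitive("sphere", 0.5, c(48, 48, 48), 0.025)
  expect_lt(abs(smi(s) - 4), 0.5)
})

test_that("MIL fabric matches a dense line-casting oracle and is rotation-stable", {
  v <- boolean_spheres(c(48, 48, 48))
  fab <- mil_fabric(v)
  expect_lt(fab$eigenvalues[1] / fab$eigenvalues[3], 1.15) # isotropy

  dirs <- daefbone:::hemisphere_directions(60)
  oracle <- mil_oracle(v$data > 0, v$spacing_mm, dirs)
  expect_lt(max(abs(fab$eigenvalues - oracle) / oracle), 0.03)

  # DA invariant under 90-degree rotation about a grid axis
  da0 <- degree_of_anisotropy(fab)
  vr <- voxel_volume(aperm(v$data, c(3, 2, 1))[dim(v$data)[3]:1, , ],
                     v$spacing_mm)
  da1 <- degree_of_anisotropy(mil_fabric(vr))
  expect_lt(abs(da0 - da1), 0.05)

  # layered structure: MIL along the normal is far below in-plane MIL
  d <- array(0, c(48, 48, 48))
  for (k0 in seq(2, 46, by = 8)) d[, , k0:(k0 + 2)] <- 1
  fp <- suppressWarnings(mil_fabric(voxel_volume(d, 0.05)))
  wz <- abs(fp$directions[, 3]) > 0.95
  wxy <- abs(fp$directions[, 3]) < 0.2
  expect_lt(mean(fp$mil_mm[wz]) * 3, mean(fp$mil_mm[wxy]))
  expect_gt(degree_of_anisotropy(fp), 0.8)

  # a full solid has no interfaces: error path
  expect_error(suppressWarnings(mil_fabric(make_block(c(12, 12, 12), 0.05))),
               "marrow|usable")
})

test_that("degree of anisotropy is the bounded eigenvalue ratio", {
  expect_equal(degree_of_anisotropy(c(1, 1, 1)), 0)
  expect_equal(degree_of_anisotropy(c(2, 1, 1)), 0.5)
  expect_equal(degree_of_anisotropy(c(5, 1, 1e-9)), 1, tolerance = 1e-8)
})

test_that("ellipsoid factor separates rods, plates and spheres", {
  rod <- make_primitive("cylinder", c(0.1, 10), c(64, 64, 64), 0.05,
                        allow_span = TRUE)
  ef_rod <- suppressWarnings(ellipsoid_factor(rod, n_seeds = 40, seed = 3))
  expect_gt(ef_rod$ef_sample, 1 - 0.15)

  pl <- make_primitive("plate", c(10, 10, 0.2), c(64, 64, 64), 0.05,
                       allow_span = TRUE)
  ef_pl <- suppressWarnings(ellipsoid_factor(pl, n_seeds = 40, seed = 3))
  expect_lt(ef_pl$ef_sample, -1 + 0.15)

  sp <- make_primitive("sphere", 0.5, c(48, 48, 48), 0.025)
  ef_sp <- suppressWarnings(ellipsoid_factor(sp, n_seeds = 40, seed = 3))
  expect_lt(abs(ef_sp$ef_sample), 0.15)
  expect_gt(ef_sp$coverage, 0.8)

  expect_error(ellipsoid_factor(voxel_volume(array(0, c(8, 8, 8)), 1)),
               "empty")
})

test_that("profile aggregates all eight parameters consistently", {
  v <- make_trabecular(trabecular_spec(shape = c(48, 48, 48), seed = 6))
  p <- suppressWarnings(microarch_profile(v))
  expect_true(all(is.finite(unlist(p[c("bv_tv", "bs_bv", "tb_th", "tb_n",
                                       "tb_sp", "smi", "da", "ef")]))))
  expect_true(p$da >= 0 && p$da <= 1)
  expect_true(p$ef >= -1 && p$ef <= 1)
  expect_equal(p$tb_n, (p$bv_tv / 100) / p$tb_th)
  df <- as.data.frame(p)
  expect_identical(names(df), c("BV_TV", "BS_BV", "Tb_Th", "Tb_N", "Tb_Sp",
                                "SMI", "DA", "EF"))
  # determinism given the config seeds
  p2 <- suppressWarnings(microarch_profile(v))
  expect_identical(unlist(p), unlist(p2))
})

test_that("EF and SMI classify primitives on the same side", {
  rod <- make_primitive("cylinder", c(0.1, 10), c(48, 48, 64), 0.0125,
                        allow_span = TRUE)
  pl <- make_block(c(48, 48, 48), 0.025, 0.5)
  rod50 <- make_primitive("cylinder", c(0.1, 10), c(64, 64, 64), 0.05,
                          allow_span = TRUE)
  ef_rod <- suppressWarnings(ellipsoid_factor(rod50, n_seeds = 40, seed = 3))$ef_sample
  ef_pl <- suppressWarnings(ellipsoid_factor(make_primitive("plate",
    c(10, 10, 0.2), c(64, 64, 64), 0.05, allow_span = TRUE),
    n_seeds = 40, seed = 3))$ef_sample
  expect_lt(ef_pl, 0)
  expect_gt(ef_rod, 0)
  expect_lt(smi(pl), 1.5)
  expect_gt(smi(rod), 1.5)
})

test_that("RMSCV follows its definition and degenerate rules", {
  mk <- function(vals) data.frame(BV_TV = vals)
  # identical replicates: 0 for every parameter
  expect_equal(unname(rmscv(list(list(mk(10), mk(10), mk(10))))["BV_TV"]), 0)
  # one sample, mean 10, SD 1 -> 10%
  reps <- list(data.frame(X = 9), data.frame(X = 10), data.frame(X = 11))
  expect_equal(unname(rmscv(list(reps))["X"]), 100 * sd(c(9, 10, 11)) / 10)
  # zero mean -> NA
  zz <- list(data.frame(X = -1), data.frame(X = 1))
  expect_true(is.na(rmscv(list(zz))["X"]))
  expect_error(rmscv(list(list(mk(1)))), "replicates")
})
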