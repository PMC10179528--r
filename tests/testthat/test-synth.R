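test_that("make_block fills the requested z-slab exactly", {
  solid <- make_block(c(10, 10, 10), 0.05, 1.0)
  expect_equal(bv_tv(solid), 100)
  half <- make_block(c(10, 10, 10), 0.05, 0.5)
  expect_equal(bv_tv(half), 50)
  expect_true(all(half$data[, , 1:5] == 1) && all(half$data[, , 6:10] == 0))
  v <- make_block(c(8, 8, 8), 0.05)
  expect_equal(dim(v$data) * v$spacing_mm, c(0.4, 0.4, 0.4))
  expect_error(make_block(c(10, 10, 10), -1), "positive")
  expect_error(make_block(c(10, 10, 10), 0.05, 1.5), "fill_fraction")
})

test_that("voxelized primitives match analytic volumes and converge", {
  vol_true <- 4 / 3 * pi * 0.5^3
  s1 <- make_primitive("sphere", 0.5, c(48, 48, 48), 0.025)
  err1 <- abs(sum(s1$data) * 0.025^3 - vol_true) / vol_true
  expect_lt(err1, 0.02)
  # halving the spacing shrinks the voxelization error
  s2 <- make_primitive("sphere", 0.5, c(96, 96, 96), 0.0125)
  err2 <- abs(sum(s2$data) * 0.0125^3 - vol_true) / vol_true
  expect_lt(err2, err1)
  expect_lt(err2, 0.01)

  cyl <- make_primitive("cylinder", c(0.1, 2), c(24, 24, 220), 0.025)
  occ <- which(cyl$data > 0, arr.ind = TRUE)
  len_vox <- diff(range(occ[, 3])) + 1
  dia_vox <- diff(range(occ[, 1])) + 1
  expect_gt(len_vox / dia_vox, 9) # 10:1 aspect rod by construction

  pl <- make_primitive("plate", c(1, 1, 0.1), c(50, 50, 20), 0.025)
  occ <- which(pl$data > 0, arr.ind = TRUE)
  ext <- apply(occ, 2, function(x) diff(range(x)) + 1)
  expect_equal(unname(ext[1]), unname(ext[2])) # two equal semi-axes, one small
  expect_lt(ext[3], ext[1] / 4)

  expect_error(make_primitive("sphere", 2, c(20, 20, 20), 0.05), "exceeds")
  expect_error(make_primitive("sphere", 0.5, c(48, 48, 48), -0.025), "positive")
})

test_that("trabecular generator is seed-deterministic and well-formed", {
  spec <- trabecular_spec(shape = c(48, 48, 48), seed = 7)
  v1 <- make_trabecular(spec)
  v2 <- make_trabecular(spec)
  expect_identical(v1$data, v2$data)
  v3 <- make_trabecular(trabecular_spec(shape = c(48, 48, 48), seed = 8))
  expect_false(identical(v1$data, v3$data))

  expect_gt(mean(v1$data), 0)
  expect_lt(mean(v1$data), 1)
  expect_equal(v1$meta$achieved_bvtv, mean(v1$data))
  # single 26-connected component after cleanup (independent flood fill on a
  # downsampled check would be slow; the invariant is checked directly)
  lab <- daefbone:::.label_components_cpp(as.vector(v1$data > 0), dim(v1$data), 26L)
  expect_equal(max(lab), 1L)

  expect_error(trabecular_spec(thickness_mm = 0.05, spacing_mm = 0.05),
               "resolvable")
  expect_error(trabecular_spec(rod_fraction = 1.2), "rod_fraction")
})

test_that("generator defaults land in the target trabecular ranges", {
  v <- make_trabecular(trabecular_spec(seed = 11))
  expect_gt(bv_tv(v), 30.9 - 6)
  expect_lt(bv_tv(v), 30.9 + 6)
  th <- tb_th(v)
  expect_gt(th, 0.2 - 0.02)
  expect_lt(th, 0.2 + 0.02)
})

test_that("generator extremes classify as plates or aligned rods downstream", {
  vp <- make_trabecular(trabecular_spec(seed = 5, rod_fraction = 0, kappa = 0))
  efp <- suppressWarnings(ellipsoid_factor(vp, n_seeds = 300, seed = 1))
  expect_lt(efp$ef_sample, 0) # plate-dominated

  vr <- make_trabecular(trabecular_spec(seed = 5, rod_fraction = 1, kappa = 50))
  fab <- suppressWarnings(mil_fabric(vr))
  expect_gt(degree_of_anisotropy(fab), 0.5) # aligned rods
})

test_that("repeat scans reproduce the sample under zero noise and fixed seed", {
  v <- make_trabecular(trabecular_spec(shape = c(32, 32, 32), seed = 3))
  clean <- make_repeat_scans(v, noise_sd = 0, n = 3)
  rebin <- lapply(clean, otsu_threshold)
  for (b in rebin) expect_identical(b$data, v$data)

  noisy1 <- make_repeat_scans(v, noise_sd = 20, n = 3, seed = 9)
  noisy2 <- make_repeat_scans(v, noise_sd = 20, n = 3, seed = 9)
  expect_identical(noisy1[[2]]$data, noisy2[[2]]$data)
  expect_false(identical(noisy1[[1]]$data, noisy1[[2]]$data))
  expect_error(make_repeat_scans(v, 10, n = 1), "n")
})

test_that("regression fixture recovers its coefficients", {
  d0 <- make_regression_dataset(2, -3, 0.5, noise_sd = 0, n = 12, seed = 4)
  f0 <- multilinear_fit(d0$Y, d0$DA, d0$EF)
  expect_equal(c(f0$beta0, f0$beta1, f0$beta2), c(2, -3, 0.5), tolerance = 1e-10)

  # beta2 = 0: its 95% CI covers zero
  d1 <- make_regression_dataset(0, 1, 0, noise_sd = 0.3, n = 40, seed = 6)
  ci <- stats::confint(multilinear_fit(d1$Y, d1$DA, d1$EF)$lm)["EF", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_error(make_regression_dataset(0, 1, 1, 0, n = 2), "n")
})
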