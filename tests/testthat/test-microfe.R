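test_that("hex meshing counts elements and deduplicated nodes correctly", {
  m <- build_hex_mesh(make_block(c(2, 2, 2), 0.05))
  expect_equal(nrow(m$elems), 8)
  expect_equal(nrow(m$nodes), 27)

  # 1x1x10 voxel column inside a wider grid: 10 elements, 4*(10+1) nodes
  d <- array(0, c(3, 3, 10))
  d[2, 2, ] <- 1
  m2 <- build_hex_mesh(voxel_volume(d, 0.05))
  expect_equal(nrow(m2$elems), 10)
  expect_equal(nrow(m2$nodes), 44)

  # L-shaped solid: node count equals brute-force unique corner coordinates
  dl <- array(0, c(5, 5, 5))
  dl[1:4, 1:2, 1:2] <- 1
  dl[1:2, 1:2, 1:5] <- 1
  ml <- build_hex_mesh(voxel_volume(dl, 0.1))
  vox <- which(dl > 0, arr.ind = TRUE)
  corners <- unique(do.call(rbind, lapply(1:8, function(l)
    sweep(vox - 1, 2, daefbone:::HEX_OFFSETS[l, ], "+"))))
  expect_equal(nrow(ml$nodes), nrow(corners))

  expect_error(build_hex_mesh(voxel_volume(array(0, c(3, 3, 3)), 1)), "empty")

  # two blocks separated along z: largest kept, no load path
  d2 <- array(0, c(4, 4, 8))
  d2[, , 1:3] <- 1
  d2[1:2, 1:2, 6:8] <- 1
  expect_error(suppressMessages(build_hex_mesh(voxel_volume(d2, 0.05))),
               "load path")
})

test_that("patch test: solid block reproduces the analytic uniaxial state", {
  v <- make_block(c(6, 6, 10), 0.1)
  r <- fe_compress(v) # defaults: E 15 GPa, nu 0.3, 0.2% strain
  f <- r$fields
  expect_lt(max(abs(f$eps_z + 0.002)) / 0.002, 1e-6)
  expect_lt(max(abs(f$sigma_z + 30)) / 30, 1e-6)
  expect_lt(max(abs(f$sigma_vm - 30)) / 30, 1e-6)
  expect_lt(max(abs(f$W_e - 0.03)) / 0.03, 1e-6)
  expect_lt(r$energy$relative_error, 1e-6)
  # lateral Poisson expansion: transverse strain ratio ~ nu
  sol <- r$solution
  width <- max(sol$mesh$nodes[, 1]) - min(sol$mesh$nodes[, 1])
  ux_range <- max(sol$u[, 1]) - min(sol$u[, 1])
  expect_rel(ux_range / width, 0.3 * 0.002, 1e-4)
})

test_that("stacked columns of different cross-section balance their reactions", {
  d <- array(0, c(4, 4, 8))
  d[, , 1:4] <- 1       # 4x4 base
  d[2:3, 2:3, 5:8] <- 1 # 2x2 upper column
  sol <- fe_solve(build_hex_mesh(voxel_volume(d, 0.1)), elastic_material(),
                  compression_bc())
  fr <- daefbone:::.fe_matvec_cpp(sol$mesh$elems - 1L, sol$Ke,
                                  as.vector(t(sol$u)))
  topz <- sum(fr[3 * (sol$mesh$top_nodes - 1) + 3])
  botz <- sum(fr[3 * (sol$mesh$bottom_nodes - 1) + 3])
  expect_rel(abs(topz), abs(botz), 1e-6)
})

test_that("strain energy identity holds on an irregular structure", {
  v <- make_trabecular(trabecular_spec(shape = c(24, 24, 24), seed = 9,
                                       spacing_mm = 0.08))
  r <- fe_compress(v)
  sol <- r$solution
  uvec <- as.vector(t(sol$u))
  ku <- daefbone:::.fe_matvec_cpp(sol$mesh$elems - 1L, sol$Ke, uvec)
  expect_rel(0.5 * sum(uvec * ku),
             sum(r$fields$W_e) * sol$mesh$spacing_mm^3, 1e-8)
  expect_lt(r$energy$relative_error, 1e-6)
  expect_gt(r$profile$mean_W_e, 0)
})

test_that("solution scales linearly with the applied strain", {
  d <- array(0, c(4, 4, 6))
  d[, , 1:6] <- 1
  d[1, 1, 3:4] <- 0 # a notch for inhomogeneity
  v <- voxel_volume(d, 0.1)
  r1 <- fe_compress(v, bc = compression_bc(0.002), tol = 1e-12)
  r2 <- fe_compress(v, bc = compression_bc(0.004), tol = 1e-12)
  expect_equal(r2$fields$eps_z, 2 * r1$fields$eps_z, tolerance = 1e-9)
  expect_equal(r2$fields$sigma_z, 2 * r1$fields$sigma_z, tolerance = 1e-9)
  expect_equal(r2$fields$W_e, 4 * r1$fields$W_e, tolerance = 1e-9)
})

test_that("refining the voxel grid leaves the mean fields nearly unchanged", {
  coarse <- make_primitive("cylinder", c(0.3, 10), c(12, 12, 10), 0.1,
                           allow_span = TRUE)
  fine <- make_primitive("cylinder", c(0.3, 10), c(24, 24, 20), 0.05,
                         allow_span = TRUE)
  pc <- fe_compress(coarse)$profile
  pf <- fe_compress(fine)$profile
  for (fld in c("mean_eps_z", "mean_sigma_z", "mean_sigma_vm", "mean_W_e"))
    expect_rel(pf[[fld]], pc[[fld]], 0.03)
})

test_that("removing a load-bearing strut increases the survivor's strain", {
  d <- array(0, c(6, 6, 8))
  d[2, 2, ] <- 1
  d[5, 5, ] <- 1
  d[, , 1] <- 1
  d[, , 8] <- 1 # end plates tie the struts together
  both <- fe_compress(voxel_volume(d, 0.1))
  d1 <- d
  d1[5, 5, 2:7] <- 0
  one <- fe_compress(voxel_volume(d1, 0.1))
  strut_elems <- function(r, ij) {
    mesh <- r$solution$mesh
    ctr <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 7], ]) / 2
    which(abs(ctr[, 1] - (ij[1] - 0.5) * 0.1) < 0.04 &
            abs(ctr[, 2] - (ij[2] - 0.5) * 0.1) < 0.04 &
            ctr[, 3] > 0.15 & ctr[, 3] < 0.65)
  }
  eps_both <- mean(abs(both$fields$eps_z[strut_elems(both, c(2, 2))]))
  eps_one <- mean(abs(one$fields$eps_z[strut_elems(one, c(2, 2))]))
  expect_gt(eps_one, eps_both)
})

test_that("material and BC validation matches the physical bounds", {
  expect_error(elastic_material(-1, 0.3), "E")
  expect_error(elastic_material(15000, 0.5), "nu")
  expect_error(compression_bc(0), "positive")
  expect_equal(top_displacement(compression_bc(0.002), 8), -0.016)
})
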