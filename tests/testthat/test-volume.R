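test_that("voxel_volume validates its invariants", {
  expect_error(voxel_volume(matrix(0, 3, 3), 0.05), "3D")
  expect_error(voxel_volume(array(0, c(1, 4, 4)), 0.05), ">= 2")
  expect_error(voxel_volume(array(0, c(4, 4, 4)), 0), "positive")
  v <- voxel_volume(array(c(0, 1), c(4, 4, 4)), 0.05)
  expect_true(is_binary(v))
  set.seed(1)
  expect_false(is_binary(voxel_volume(array(runif(64), c(4, 4, 4)), 1)))
})

test_that("NRRD round trip is lossless and preserves spacing", {
  set.seed(1)
  v <- voxel_volume(array(as.numeric(runif(32^3) > 0.7), c(32, 32, 32)),
                    spacing_mm = 0.0079, origin_mm = c(1, 2, 3))
  f <- file.path(tempdir(), "rt.nrrd")
  write_volume(v, f)
  w <- read_volume(f)
  expect_identical(w$data, v$data)
  expect_equal(w$spacing_mm, 0.0079)
  expect_equal(w$origin_mm, c(1, 2, 3))
  expect_true(file.exists(paste0(f, ".json")))
})

test_that("TIFF round trip works but requires an explicit spacing", {
  set.seed(2)
  v <- voxel_volume(array(as.numeric(runif(16^3) > 0.5), c(16, 16, 16)), 0.05)
  f <- file.path(tempdir(), "rt.tif")
  write_volume(v, f, sidecar = FALSE)
  expect_error(read_volume(f), "spacing")
  w <- read_volume(f, spacing_mm = 0.05)
  expect_identical(w$data, v$data)

  g <- voxel_volume(array(round(runif(16^3) * 255), c(16, 16, 16)), 0.05)
  fg <- file.path(tempdir(), "gray.tif")
  write_volume(g, fg, sidecar = FALSE)
  expect_equal(read_volume(fg, spacing_mm = 0.05)$data, g$data)
})

test_that("anisotropic NRRD spacing is rejected with a resampling hint", {
  f <- file.path(tempdir(), "aniso.nrrd")
  con <- file(f, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 2 2 2",
               "endian: little", "encoding: raw",
               "space directions: (0.01,0,0) (0,0.01,0) (0,0,0.02)", ""),
             con)
  writeBin(rep(0, 8), con, size = 8, endian = "little")
  close(con)
  expect_error(read_volume(f), "resample")
})
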