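test_that("analytic test meshes have the expected counts, closure and volumes", {
  for (r in 0:3) {
    m <- make_test_mesh("sphere", refinement = r)
    expect_equal(nrow(m$vertices), 10 * 4^r + 2)
    expect_true(m$closed)
  }
  m3 <- make_test_mesh("sphere", refinement = 3)
  expect_lt(abs(mesh_volume(m3) - 4 / 3 * pi) / (4 / 3 * pi), 0.02)
  cu <- make_test_mesh("cube", scale = 1.7, refinement = 1)
  expect_true(cu$closed)
  expect_equal(mesh_volume(cu), 1.7^3, tolerance = 1e-12)
  el <- make_test_mesh("ellipsoid", refinement = 2, axes = c(1, 1, 1))
  sp <- make_test_mesh("sphere", refinement = 2)
  expect_equal(el$vertices, sp$vertices)
})

test_that("OFF and PLY round-trip a mesh", {
  m <- make_test_mesh("ellipsoid", refinement = 1, axes = c(1, 1.5, 0.7))
  for (ext in c("off", "ply")) {
    path <- file.path(withr::local_tempdir(), paste0("m.", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
  }
})

test_that("extract_surface reproduces a ball's volume and handles edge cases", {
  d <- c(26, 26, 26); cx <- 13.5; R <- 9
  idx <- as.matrix(expand.grid(1:26, 1:26, 1:26))
  a <- array(0L, d)
  a[idx[rowSums((idx - cx)^2) <= R^2, ]] <- 1L
  m <- extract_surface(a, 1L)
  expect_true(m$closed)
  expect_lt(abs(mesh_volume(m) - 4 / 3 * pi * R^3) / (4 / 3 * pi * R^3),
            0.05)
  # physical units scale the volume by prod(voxel_size)
  m2 <- extract_surface(a, 1L, voxel_size = c(1, 2, 0.5))
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-10)
  # single voxel: closed cuboid of 12 triangles with unit volume
  b <- array(0L, c(3, 3, 3)); b[2, 2, 2] <- 1L
  mb <- extract_surface(b, 1L)
  expect_true(mb$closed)
  expect_equal(nrow(mb$faces), 12)
  expect_equal(mesh_volume(mb), 1)
  expect_error(extract_surface(b, 9L), "absent")
})

test_that("NIfTI label volumes round-trip through RNifti", {
  a <- array(0L, c(8, 8, 8)); a[3:6, 3:6, 3:6] <- 2L
  path <- file.path(withr::local_tempdir(), "lab.nii")
  img <- RNifti::asNifti(structure(a, pixdim = c(0.5, 0.5, 0.5)))
  RNifti::writeNifti(img, path)
  vol <- read_label_volume(path)
  expect_equal(as.integer(vol$data), as.integer(a))
  expect_equal(vol$voxel_size, c(0.5, 0.5, 0.5), ignore_attr = TRUE)
  m <- extract_surface(vol$data, 2L, vol$voxel_size)
  expect_equal(mesh_volume(m), 64 * 0.125, tolerance = 1e-10)
})

test_that("smoothing is the identity at zero iterations and rounds cube corners", {
  cu <- make_test_mesh("cube", refinement = 2)
  expect_identical(smooth_mesh(cu, 0), cu)
  sm <- smooth_mesh(cu, 3)
  expect_equal(sm$faces, cu$faces)
  # corner vertices (3 coordinates at the extremes) must move
  corners <- which(rowSums(matrix(cu$vertices %in% c(0, 1),
                                  nrow(cu$vertices))) == 3)
  disp <- sqrt(rowSums((sm$vertices - cu$vertices)^2))
  expect_true(all(disp[corners] > 0))
  expect_lt(mesh_area(sm), mesh_area(cu))
})

test_that("smoothing moves a voxelized ball's spectrum toward the analytic sphere", {
  d <- c(26, 26, 26); cx <- 13.5
  idx <- as.matrix(expand.grid(1:26, 1:26, 1:26))
  a <- array(0L, d)
  a[idx[rowSums((idx - cx)^2) <= 81, ]] <- 1L
  m <- extract_surface(a, 1L)
  ref <- shape_descriptor(make_test_mesh("sphere", refinement = 4),
                          n_modes = 10, smooth_iterations = 0)
  err <- function(iters)
    sum(abs(shape_descriptor(m, 10, iters)$values - ref$values))
  expect_lt(err(3), err(0))
})
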