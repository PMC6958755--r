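test_that("volume I/O round-trips data and geometry through NIfTI", {
  a <- array(rnorm(8 * 7 * 6), c(8, 7, 6))
  img <- volumetric_image(a, spacing = c(1.5, 1.5, 5), origin = c(10, -4, 2))
  f <- tempfile(fileext = ".nii.gz")
  save_volume(img, f)
  back <- load_volume(f)
  expect_identical(back$data[, , ], a)
  expect_equal(back$spacing, c(1.5, 1.5, 5))
  expect_equal(back$origin, c(10, -4, 2))
  expect_equal(back$direction, diag(3), tolerance = 1e-6)

  # masks round-trip as binary
  m <- make_mask(c(8, 7, 6), cbind(2:4, 2:4, 2:4), spacing = c(1.5, 1.5, 5))
  m$origin <- c(10, -4, 2)
  save_volume(m, f)
  m2 <- load_mask(f)
  expect_identical(m2$data[, , ], m$data)
})

test_that("degenerate volumes are rejected at construction and load", {
  expect_error(volumetric_image(matrix(1, 4, 4)), "expected 3D volume")
  expect_error(volumetric_image(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  bad <- array(1, c(2, 2, 2))
  bad[1] <- NA
  expect_error(volumetric_image(bad), "non-finite")
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(16), 4, 4)), f)
  expect_error(load_volume(f), "expected 3D volume")
  expect_error(load_volume(tempfile()), "not found")
})

test_that("dilation matches the physical-distance oracle, incl. anisotropy", {
  # single voxel, isotropic 1 mm, radius 1 mm -> centre + 6 face neighbours
  m <- make_mask(c(5, 5, 5), cbind(3, 3, 3))
  d <- dilate_mask(m, 1)
  expect_equal(voxel_count(d), 7)
  expect_identical(d$data, dilate_oracle(m$data, c(1, 1, 1), 1))

  # radius 0 is the identity
  expect_identical(dilate_mask(m, 0)$data, m$data)
  expect_error(dilate_mask(m, -1), "non-negative")

  # anisotropic spacing: 4 mm ball on (1, 1, 4) mm voxels reaches +-1 slice
  # axially and +-4 voxels in-plane
  m2 <- make_mask(c(11, 11, 7), cbind(6, 6, 4), spacing = c(1, 1, 4))
  d2 <- dilate_mask(m2, 4)
  expect_identical(d2$data, dilate_oracle(m2$data, c(1, 1, 4), 4))
  zr <- range(which(apply(d2$data, 3, any)))
  xr <- range(which(apply(d2$data, 1, any)))
  expect_equal(zr, c(3, 5))
  expect_equal(xr, c(2, 10))

  # random masks against the oracle
  for (s in 1:5) {
    set.seed(s)
    mr <- binary_mask(array(runif(10 * 9 * 8) < 0.05, c(10, 9, 8)),
                      spacing = c(1, 2, 3))
    r <- runif(1, 0, 5)
    expect_identical(dilate_mask(mr, r)$data,
                     dilate_oracle(mr$data, c(1, 2, 3), r))
  }
})

test_that("dilation is monotone in the mask and in the radius", {
  set.seed(42)
  m <- binary_mask(array(runif(16^3) < 0.02, c(16, 16, 16)))
  d1 <- dilate_mask(m, 1.5)
  d2 <- dilate_mask(m, 3)
  expect_true(all(d1$data[m$data]))        # input contained in output
  expect_true(all(d2$data[d1$data]))       # r1 <= r2 nesting
})

test_that("connected components match a flood-fill oracle", {
  # empty mask
  empty <- make_mask(c(4, 4, 4))
  expect_equal(n_components(connected_components(empty)), 0)

  # corner-touching voxels: one component at 26-connectivity, two at 6
  corner <- make_mask(c(4, 4, 4), rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(n_components(connected_components(corner, 26)), 1)
  expect_equal(n_components(connected_components(corner, 6)), 2)

  # 5-voxel cross is a single component of 5 voxels
  cross <- make_mask(c(5, 5, 5), rbind(c(3, 3, 3), c(2, 3, 3), c(4, 3, 3),
                                       c(3, 2, 3), c(3, 4, 3)))
  cc <- connected_components(cross, 6)
  expect_equal(cc$components$voxel_count, 5)

  # random 16^3 masks against the oracle under all connectivities
  for (s in 1:100) {
    set.seed(s)
    m <- binary_mask(array(runif(16^3) < 0.12, c(16, 16, 16)))
    conn <- c(6, 18, 26)[(s %% 3) + 1]
    got <- connected_components(m, conn)
    want <- flood_fill_oracle(m$data, conn)
    expect_identical(got$labels, want)
    expect_equal(sum(got$components$voxel_count), sum(m$data))
  }
})

test_that("component volumes and bookkeeping are consistent", {
  m <- make_mask(c(6, 6, 6), rbind(c(1, 1, 1), c(1, 2, 1), c(5, 5, 5)),
                 spacing = c(2, 2, 2))
  cc <- connected_components(m)
  expect_equal(nrow(cc$components), 2)
  expect_equal(cc$components$volume_ml,
               cc$components$voxel_count * 8 / 1000)
  expect_equal(volume_ml(m), 3 * 8 / 1000)
})

test_that("mask algebra: union, subtraction and their identities", {
  a <- make_mask(c(6, 6, 6), cbind(1:5, rep(1, 5), rep(1, 5)))
  b <- make_mask(c(6, 6, 6), cbind(rep(1, 5), 1:5, rep(1, 5)))
  expect_identical(mask_union(a, a)$data, a$data)          # idempotent
  ab <- mask_union(a, b)
  expect_equal(voxel_count(ab), voxel_count(a) + voxel_count(b) - 1)
  expect_identical(mask_subtract(a, make_mask(c(6, 6, 6)))$data, a$data)
  expect_equal(voxel_count(mask_subtract(a, a)), 0)
  # (a union b) minus b is contained in a
  d <- mask_subtract(ab, b)
  expect_true(all(a$data[d$data]))
  # grid mismatch is an error, never an implicit resample
  c2 <- make_mask(c(6, 6, 6), spacing = c(2, 1, 1))
  expect_error(mask_union(a, c2), "not compatible")
  expect_error(mask_subtract(a, c2), "not compatible")
  expect_error(dice(a, c2), "not compatible")
})
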