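cfg_fast <- function(seed = 7, ...) {
  registration_config(seed = seed, ...)
}

test_that("identity chain leaves images and masks unchanged", {
  pair <- generate_phantom_pair(small_spec(seed = 51))
  img <- pair$dwi_high
  id <- identity_chain(img)
  out <- apply_transform(img, id, img)
  expect_lt(max(abs(out$data - img$data)), 1e-6)
  m <- pair$truth$skeleton_mask
  expect_identical(warp_mask(m, id, img)$data, m$data)
})

test_that("translation round trip stays within interpolation tolerance", {
  # smooth phantom so linear interpolation error is tiny away from edges
  pair <- generate_phantom_pair(small_spec(seed = 52, noise_sigma = 0))
  img <- mmseg:::smooth_image(pair$dwi_high, 1.5)
  ctr <- mmseg:::phys_center(img)
  fwd <- rigid_chain(translation_mm = c(10, 0, 0), center = ctr)
  bwd <- rigid_chain(translation_mm = c(-10, 0, 0), center = ctr)
  there <- apply_transform(img, fwd, img)
  back <- apply_transform(there, bwd, img)
  d <- dim(img$data)
  core <- list(9:(d[1] - 8), 9:(d[2] - 8), 9:(d[3] - 8))
  err <- abs(back$data[core[[1]], core[[2]], core[[3]]] -
               img$data[core[[1]], core[[2]], core[[3]]])
  expect_lt(max(err) / diff(range(img$data)), 0.02)
})

test_that("warped cube centroid moves by the prescribed translation", {
  pair <- generate_phantom_pair(small_spec(seed = 53))
  img <- pair$dwi_high
  cube <- make_mask(dim(img$data), as.matrix(expand.grid(20:25, 12:17, 30:35)),
                    spacing = img$spacing)
  tr <- c(6, -4, 8)
  ch <- rigid_chain(translation_mm = tr, center = mmseg:::phys_center(img))
  w <- warp_mask(cube, ch, img)
  # chains map reference to source space, so content moves by -tr
  centroid <- function(m) colMeans(which(m$data, arr.ind = TRUE) * 2)
  expect_lt(max(abs(centroid(w) - (centroid(cube) - tr))), 2)
  # output is strictly binary by construction
  expect_type(w$data, "logical")
})

test_that("self-registration is close to the identity", {
  pair <- generate_phantom_pair(small_spec(seed = 54))
  img <- pair$dwi_high
  ch <- register_pair(img, img, cfg_fast())
  set.seed(1)
  pts <- mmseg:::voxel_world_coords(img, sample.int(prod(dim(img$data)), 3000))
  disp <- chain_apply(ch, pts) - pts
  med_vox <- median(sqrt(rowSums(disp^2))) / min(img$spacing)
  expect_lt(med_vox, 0.5)
})

test_that("known rigid translations are recovered within 1 mm", {
  pair <- generate_phantom_pair(small_spec(seed = 55))
  img <- pair$dwi_high
  ctr <- mmseg:::phys_center(img)
  for (tr in list(c(6, -4, 2), c(-8, 5, 9))) {
    moved <- apply_transform(img, rigid_chain(translation_mm = tr, center = ctr),
                             img)
    ch <- register_pair(img, moved,
                        cfg_fast(affine_levels = 0, ffd_levels = 0))
    # the resampling chain carries the inverse mapping, so recover -tr
    expect_lt(max(abs(ch$rigid$translation + tr)), 1)
  }
})

test_that("registration is reproducible for a fixed seed", {
  pair <- generate_phantom_pair(small_spec(seed = 56))
  img <- pair$dwi_high
  moved <- apply_transform(img, rigid_chain(translation_mm = c(4, 3, -5),
                                            center = mmseg:::phys_center(img)),
                           img)
  cfg <- cfg_fast(seed = 123, affine_levels = 0, ffd_levels = 0)
  ch1 <- register_pair(img, moved, cfg)
  ch2 <- register_pair(img, moved, cfg)
  expect_identical(ch1, ch2)
})

test_that("degenerate registration inputs are rejected", {
  flat <- volumetric_image(array(5, c(8, 8, 8)))
  pair <- generate_phantom_pair(small_spec(seed = 57))
  expect_error(register_pair(flat, pair$dwi_high, cfg_fast()), "constant")
  expect_error(register_pair(pair$dwi_high, flat, cfg_fast()), "constant")
})

test_that("full-volume mask warps cover the reference interior", {
  pair <- generate_phantom_pair(small_spec(seed = 58))
  img <- pair$dwi_high
  full <- binary_mask(array(TRUE, dim(img$data)), img$spacing)
  ch <- rigid_chain(c(0.01, -0.01, 0.02), c(2, -2, 1),
                    center = mmseg:::phys_center(img))
  w <- warp_mask(full, ch, img)
  d <- dim(img$data)
  interior <- w$data[4:(d[1] - 3), 4:(d[2] - 3), 4:(d[3] - 3)]
  expect_gt(mean(interior), 0.99)
})

test_that("rigid T1-to-b0 alignment: self and known-shift recovery", {
  pair <- generate_phantom_pair(small_spec(seed = 59))
  # already-aligned volumes stay put
  aligned <- align_t1(pair$t1, pair$dwi_b0, cfg_fast())
  expect_lt(median(abs(aligned$data - pair$t1$data)) /
              diff(range(pair$t1$data)), 0.01)
  ch <- attr(aligned, "chain")
  expect_null(ch$affine)   # rigid-only by construction
  expect_null(ch$ffd)
  # T1 shifted 5 mm from b0 is brought back within 1 mm
  shift <- rigid_chain(translation_mm = c(5, 0, 0),
                       center = mmseg:::phys_center(pair$t1))
  t1_moved <- apply_transform(pair$t1, shift, pair$t1)
  aligned2 <- align_t1(t1_moved, pair$dwi_b0, cfg_fast())
  ch2 <- attr(aligned2, "chain")
  # resampling chain carries the inverse mapping of the applied shift
  expect_lt(max(abs(ch2$rigid$translation + c(5, 0, 0))), 1)
})
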