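test_that("IQR threshold matches the sort-based quartile oracle", {
  # worked example: {1,2,3,4,100}, k = 4 -> Q1 = 2, Q3 = 4, threshold 12
  expect_equal(compute_iqr_threshold(c(1, 2, 3, 4, 100), k = 4), 12)

  # constant input: threshold collapses to the constant, with a warning
  expect_warning(thr <- compute_iqr_threshold(rep(7, 10), k = 3),
                 "interquartile")
  expect_equal(thr, 7)

  expect_error(compute_iqr_threshold(c(1, 2, 3), 4), "at least 4")
  expect_error(compute_iqr_threshold(1:10, k = -1), "positive")

  set.seed(11)
  for (i in 1:1000) {
    x <- rnorm(sample(4:60, 1), sample(-5:5, 1), runif(1, 0.1, 10))
    k <- runif(1, 0.5, 8)
    expect_equal(compute_iqr_threshold(x, k), iqr_threshold_oracle(x, k),
                 tolerance = 1e-12)
  }
})

test_that("threshold segmentation isolates a constructed hot blob", {
  dims <- c(24, 24, 24)
  set.seed(12)
  img <- volumetric_image(array(rnorm(prod(dims), 100, 5), dims))
  region <- binary_mask(array(TRUE, dims))
  # 50-voxel blob at intensity 400, far above Q3 + 4 IQR of the background
  blob <- make_mask(dims, cbind(rep(10:14, 10),
                                rep(rep(10:11, each = 5), 5),
                                rep(10:14, each = 10)))
  img$data[blob$data] <- 400
  seg <- threshold_segment(img, region, k = 4)
  expect_equal(n_components(seg), 1)
  expect_equal(seg$components$voxel_count, 50)
  expect_identical(seg$labels > 0L, blob$data)

  # enormous k on a bounded image finds nothing
  expect_equal(n_components(threshold_segment(img, region, k = 1e6)), 0)

  # all segmented voxels lie inside the search region
  half <- binary_mask(array(rep(c(TRUE, FALSE), each = prod(dims) / 2), dims))
  seg2 <- threshold_segment(img, half, k = 2.5)
  expect_true(all(half$data[seg2$labels > 0L]))

  expect_error(threshold_segment(img, make_mask(dims), 4), "empty")
})

test_that("candidate set is antitone in k", {
  pat <- generate_phantom_pair(small_spec(seed = 21, n_lesions = 3))
  region <- mask_subtract(dilate_mask(pat$truth$skeleton_mask, 6),
                          dilate_mask(pat$truth$organ_mask, 4))
  prev <- NULL
  for (k in c(2.5, 4, 5.5, 7.5)) {
    cand <- threshold_segment(pat$dwi_high, region, k)$labels > 0L
    if (!is.null(prev)) expect_true(all(prev[cand]))  # cand subset of prev
    prev <- cand
  }
})

test_that("psoas reference mean is the arithmetic mean inside the mask", {
  dims <- c(6, 6, 6)
  img <- volumetric_image(array(0, dims))
  m <- make_mask(dims, rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1)))
  img$data[1:3] <- c(100, 200, 300)
  expect_equal(psoas_reference_mean(img, m), 200)
  img$data[m$data] <- 200
  expect_equal(psoas_reference_mean(img, m), 200)
  expect_error(psoas_reference_mean(img, make_mask(dims)), "empty")
  # sampling bound on a noisy reference region
  set.seed(13)
  big <- volumetric_image(array(rnorm(prod(dims), 150, 10), dims))
  all_m <- binary_mask(array(TRUE, dims))
  expect_lt(abs(psoas_reference_mean(big, all_m) - 150),
            3 * 10 / sqrt(prod(dims)))
})

test_that("T1 filter removes whole components at the voxel-fraction cutoff", {
  dims <- c(12, 4, 4)
  # component 1: 10 voxels, 9 above the psoas mean -> removed at 0.90
  # component 2: 10 voxels, 8 above -> kept
  # component 3: entirely hypointense -> kept
  lab <- array(0L, dims)
  lab[1:10] <- 1L
  lab[17:26] <- 2L
  lab[33:42] <- 3L
  comps <- labeled_components(lab)
  t1 <- volumetric_image(array(0, dims))
  t1$data[1:9] <- 200
  t1$data[17:24] <- 200
  filtered <- t1_component_filter(comps, t1, psoas_mean = 100,
                                  pct_cutoff = 0.90)
  expect_equal(n_components(filtered), 2)
  info <- attr(filtered, "filter_info")
  expect_equal(info$bright_fraction, c(0.9, 0.8, 0))
  expect_equal(info$kept, c(FALSE, TRUE, TRUE))
  # survivors keep their voxel membership, relabelled in order
  expect_identical(which(filtered$labels == 1L), 17:26)
  expect_identical(which(filtered$labels == 2L), 33:42)

  # cutoff 1 removes only fully bright components
  t1$data[1:10] <- 200
  f2 <- t1_component_filter(comps, t1, 100, pct_cutoff = 1)
  expect_equal(n_components(f2), 2)

  # surviving set is antitone in (1 - cutoff): lower cutoff removes more
  k_at <- function(cut) n_components(t1_component_filter(comps, t1, 100, cut))
  cuts <- c(0.5, 0.8, 0.95, 1)
  expect_true(all(diff(vapply(cuts, k_at, numeric(1))) >= 0))
})

test_that("segmentation-to-filter flow on a truth-region phantom", {
  # registration-free variant: search region built from ground-truth masks
  pat <- generate_phantom_pair(small_spec(seed = 22, n_lesions = 3,
                                          n_confounders = 1))
  region <- mask_subtract(dilate_mask(pat$truth$skeleton_mask, 6),
                          dilate_mask(pat$truth$organ_mask, 4))
  cand <- threshold_segment(pat$dwi_high, region, 4)
  gt <- connected_components(pat$truth$lesion_mask)
  # candidates include the confounder
  m0 <- match_lesions(cand, gt)
  expect_equal(m0$n_gs_detected, 3)
  expect_gt(m0$n_pred, m0$n_pred_correct)
  # the T1 filter removes it and keeps every lesion
  psoas_mean <- psoas_reference_mean(pat$t1, pat$truth$psoas_mask)
  final <- t1_component_filter(cand, pat$t1, psoas_mean, 0.90)
  m1 <- match_lesions(final, gt)
  expect_equal(m1$sensitivity, 1)
  expect_equal(m1$ppv, 1)
  # no confounder voxel survives
  expect_equal(sum(final$labels > 0L & pat$truth$confounder_mask$data), 0)
})
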