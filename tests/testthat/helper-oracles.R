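# Independent oracles and small constructors shared across test files.

# mask with given voxels set (n x 3 index matrix, 1-based)
make_mask <- function(dims, voxels = NULL, spacing = c(1, 1, 1),
                      role = "lesion") {
  a <- array(FALSE, dims)
  if (!is.null(voxels)) a[voxels] <- TRUE
  binary_mask(a, spacing = spacing, role = role)
}

# brute-force spherical dilation: physical distance check between every
# voxel-centre pair
dilate_oracle <- function(mask_arr, spacing, radius_mm) {
  d <- dim(mask_arr)
  src <- which(mask_arr, arr.ind = TRUE)
  out <- array(FALSE, d)
  all_idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  for (j in seq_len(nrow(all_idx))) {
    p <- all_idx[j, ]
    dd <- sweep(src, 2, p)
    dist2 <- (dd[, 1] * spacing[1])^2 + (dd[, 2] * spacing[2])^2 +
      (dd[, 3] * spacing[3])^2
    if (any(dist2 <= radius_mm^2)) out[p[1], p[2], p[3]] <- TRUE
  }
  out
}

# flood-fill connected-component oracle (breadth-first, plain R)
flood_fill_oracle <- function(mask_arr, connectivity = 26) {
  d <- dim(mask_arr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[s > 0 & s <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  labels <- array(0L, d)
  nxt <- 0L
  for (p in which(mask_arr)) {
    if (labels[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    labels[p] <- nxt
    while (length(queue) > 0) {
      q <- queue[1]
      queue <- queue[-1]
      q0 <- q - 1L
      co <- c(q0 %% d[1], (q0 %/% d[1]) %% d[2], q0 %/% (d[1] * d[2])) + 1L
      for (a in seq_len(nrow(offs))) {
        nb <- co + offs[a, ]
        if (any(nb < 1) || any(nb > d)) next
        r <- nb[1] + d[1] * (nb[2] - 1L + d[2] * (nb[3] - 1L))
        if (mask_arr[r] && labels[r] == 0L) {
          labels[r] <- nxt
          queue <- c(queue, r)
        }
      }
    }
  }
  labels
}

# sort-based quantile oracle (linear interpolation of order statistics)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

iqr_threshold_oracle <- function(x, k) {
  q1 <- quantile_oracle(x, 0.25)
  q3 <- quantile_oracle(x, 0.75)
  q3 + k * (q3 - q1)
}

# compact phantom spec used where full size is unnecessary
small_spec <- function(...) {
  phantom_spec(shape = c(48, 32, 80), ...)
}

# apply a random rigid pose to a generated phantom (volumes + truth masks)
posed_phantom <- function(pair, pose_seed, max_trans_mm = 6, max_rot_rad = 0.025) {
  set.seed(pose_seed)
  pose <- rigid_chain(runif(3, -max_rot_rad, max_rot_rad),
                      runif(3, -max_trans_mm, max_trans_mm),
                      mmseg:::phys_center(pair$dwi_high))
  list(dwi_high = apply_transform(pair$dwi_high, pose, pair$dwi_high),
       dwi_b0 = apply_transform(pair$dwi_b0, pose, pair$dwi_b0),
       t1 = apply_transform(pair$t1, pose, pair$t1),
       truth = lapply(pair$truth, function(m)
         warp_mask(m, pose, pair$dwi_high)),
       pose = pose)
}

# atlas bundle built from a clean lesion-free phantom and its truth masks
phantom_atlas <- function(seed = 990) {
  base <- generate_phantom_pair(phantom_spec(seed = seed, n_lesions = 0,
                                             noise_sigma = 0))
  atlas_bundle(base$dwi_high, base$truth$organ_mask, base$truth$skeleton_mask)
}
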