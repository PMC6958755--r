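#' Registration configuration
#'
#' Parameters of the multi-stage registration used throughout the pipeline:
#' a rigid stage initialised at the images' geometric centres, an affine
#' refinement, and a cubic B-spline free-form deformation (FFD). Rigid and
#' affine stages run multi-resolution (4 levels by default) maximising
#' mutual information on a seeded random sample of voxels; the FFD runs at a
#' single resolution on a control-point grid of `ffd_grid_spacing_mm`,
#' minimising the sum of squared intensity differences by gradient descent
#' (intended for same-modality alignment, as in atlas propagation). Setting
#' a stage's level count to 0 skips that stage (e.g. rigid-only T1-to-b0
#' alignment).
#'
#' @param rigid_levels,affine_levels number of multi-resolution levels for
#'   the rigid and affine stages (default 4 each; 0 skips the stage).
#' @param ffd_levels 1 to run the free-form stage, 0 to skip (default 1).
#' @param max_iterations optimiser iteration cap per stage and level
#'   (default 255).
#' @param ffd_grid_spacing_mm control-point spacing of the FFD grid in mm
#'   (default 32).
#' @param mi_bins number of histogram bins per axis for mutual information
#'   (default 32).
#' @param n_samples number of fixed-image voxels sampled for the similarity
#'   metric at each level (default 15000).
#' @param seed RNG seed controlling metric sampling; with a fixed seed the
#'   registration is bitwise reproducible.
#' @export
registration_config <- function(rigid_levels = 4, affine_levels = 4,
                                ffd_levels = 1, max_iterations = 255,
                                ffd_grid_spacing_mm = 32, mi_bins = 32,
                                n_samples = 15000, seed = 0) {
  stopifnot(rigid_levels >= 0, affine_levels >= 0, ffd_levels >= 0,
            max_iterations >= 1, ffd_grid_spacing_mm > 0, mi_bins >= 4,
            n_samples >= 100)
  structure(list(rigid_levels = rigid_levels, affine_levels = affine_levels,
                 ffd_levels = ffd_levels, max_iterations = max_iterations,
                 similarity = "mutual_information",
                 optimizer = "nelder_mead",
                 image_interpolation = "linear",
                 ffd_grid_spacing_mm = ffd_grid_spacing_mm,
                 mi_bins = mi_bins, n_samples = n_samples, seed = seed),
            class = "registration_config")
}

# ---- transform algebra ------------------------------------------------------

rot_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# 3x4 matrix of y = A (x - c) + c + t
centered_matrix <- function(a, t, center) {
  cbind(a, as.numeric(center - a %*% center + t))
}

compose34 <- function(outer, inner) {
  # outer(inner(x)); both 3x4
  cbind(outer[, 1:3] %*% inner[, 1:3], outer[, 1:3] %*% inner[, 4] + outer[, 4])
}

# combined linear (rigid then affine) 3x4 matrix of a chain
chain_linear <- function(chain) {
  m <- cbind(diag(3), c(0, 0, 0))
  if (!is.null(chain$rigid))
    m <- compose34(centered_matrix(rot_matrix(chain$rigid$angles),
                                   chain$rigid$translation, chain$center), m)
  if (!is.null(chain$affine))
    m <- compose34(centered_matrix(chain$affine$A, chain$affine$t,
                                   chain$center), m)
  m
}

#' Apply a transform chain to physical points
#'
#' Maps points from fixed-image physical space to moving-image physical
#' space: rigid, then affine, then the additive free-form displacement
#' (evaluated at the fixed-space points).
#'
#' @param chain a `transform_chain` from [register_pair()] or
#'   [rigid_chain()].
#' @param pts n x 3 matrix of physical coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
chain_apply <- function(chain, pts) {
  m <- chain_linear(chain)
  out <- pts %*% t(m[, 1:3])
  out <- sweep(out, 2, m[, 4], "+")
  if (!is.null(chain$ffd)) {
    f <- chain$ffd
    pre <- ffd_precompute_cpp(pts, f$origin, f$spacing, f$dims)
    out <- out + ffd_disp_cpp(pre$base, pre$w, f$dims, f$coefs)
  }
  out
}

#' Construct a pure rigid transform chain
#'
#' Convenience constructor, mainly for tests and phantom pose perturbation.
#' @param angles rotations about x, y, z in radians.
#' @param translation_mm length-3 translation in mm.
#' @param center rotation centre in physical mm.
#' @export
rigid_chain <- function(angles = c(0, 0, 0), translation_mm = c(0, 0, 0),
                        center = c(0, 0, 0)) {
  structure(list(center = as.numeric(center),
                 rigid = list(angles = as.numeric(angles),
                              translation = as.numeric(translation_mm)),
                 affine = NULL, ffd = NULL),
            class = "transform_chain")
}

#' Identity transform chain
#' @param reference image whose centre is used as the (irrelevant) rotation
#'   centre.
#' @export
identity_chain <- function(reference) {
  rigid_chain(center = phys_center(reference))
}

#' @export
print.transform_chain <- function(x, ...) {
  cat("<transform_chain>\n")
  if (!is.null(x$rigid))
    cat(sprintf("  rigid: angles (%s) rad, translation (%s) mm\n",
                paste(signif(x$rigid$angles, 3), collapse = ", "),
                paste(signif(x$rigid$translation, 3), collapse = ", ")))
  if (!is.null(x$affine))
    cat(sprintf("  affine: |A - I| max %.3g, translation (%s) mm\n",
                max(abs(x$affine$A - diag(3))),
                paste(signif(x$affine$t, 3), collapse = ", ")))
  if (!is.null(x$ffd))
    cat(sprintf("  ffd: %s control grid, %.1f mm spacing, max |disp| %.2f mm\n",
                paste(x$ffd$dims, collapse = "x"), x$ffd$spacing,
                max(abs(x$ffd$coefs))))
  invisible(x)
}

# ---- image pyramid ----------------------------------------------------------

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_image <- function(img, sigma_vox) {
  v <- img$data
  d <- dim(v)
  for (ax in 0:2) {
    k <- gauss_kernel(sigma_vox)
    if (length(k) > 1)
      v <- array(conv_axis_cpp(as.numeric(v), d, k, ax), d)
  }
  volumetric_image(v, img$spacing, img$origin, img$direction)
}

downsample_image <- function(img, factor) {
  if (factor == 1) return(img)
  sm <- smooth_image(img, sigma_vox = factor / 2)
  d <- dim(sm$data)
  ix <- seq(1, d[1], by = factor)
  iy <- seq(1, d[2], by = factor)
  iz <- seq(1, d[3], by = factor)
  volumetric_image(sm$data[ix, iy, iz, drop = FALSE], img$spacing * factor,
                   img$origin, img$direction)
}

# ---- mutual information -----------------------------------------------------

mutual_information <- function(fvals, mvals, bins, frange, mrange) {
  fb <- pmin(pmax(floor((fvals - frange[1]) / max(diff(frange), 1e-12) * bins),
                  0), bins - 1)
  mb <- pmin(pmax(floor((mvals - mrange[1]) / max(diff(mrange), 1e-12) * bins),
                  0), bins - 1)
  joint <- tabulate(fb + bins * mb + 1L, nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)
  px <- rowSums(pm)
  py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / (px[row(pm)[nz]] * py[col(pm)[nz]])))
}

# negative-MI objective at one pyramid level for a parametric linear stage
make_mi_objective <- function(fx, mv, cfg, make_chain) {
  nvox <- length(fx$data)
  n <- min(cfg$n_samples, nvox)
  sub <- if (n == nvox) seq_len(nvox) else sample.int(nvox, n)
  pts <- voxel_world_coords(fx, sub)
  fvals <- as.numeric(fx$data[sub])
  frange <- range(fvals)
  fill <- min(mv$data)
  mrange <- range(mv$data)
  w2i <- w2i_matrix(mv)
  # keep the joint histogram well populated at coarse levels (~30 samples
  # per occupied cell), otherwise the MI estimate is too noisy to optimise
  bins <- min(cfg$mi_bins, max(8, floor(sqrt(n / 30))))
  function(par) {
    ch <- make_chain(par)
    y <- chain_apply(ch, pts)
    ci <- sweep(y %*% t(w2i[1:3, 1:3]), 2, w2i[1:3, 4], "+")
    mvals <- interp_cpp(as.numeric(mv$data), dim(mv$data), ci, FALSE, fill)
    -mutual_information(fvals, mvals, bins, frange, mrange)
  }
}

# Exhaustive translation search on a coarse level; Nelder-Mead then refines
# from inside the correct basin of attraction.
translation_grid_search <- function(fixed, moving, cfg, t0, center,
                                    range_mm = 12, step_mm = 4) {
  f <- min(4, 2^(max(cfg$rigid_levels, 1) - 1))
  fx <- fixed(f)
  mv <- moving(f)
  obj <- make_mi_objective(fx, mv, cfg,
                           function(p) rigid_chain(c(0, 0, 0), p, center))
  offs <- seq(-range_mm, range_mm, by = step_mm)
  best <- t0
  bestv <- obj(t0)
  for (dz in offs) for (dy in offs) for (dx in offs) {
    v <- obj(t0 + c(dx, dy, dz))
    if (v < bestv) {
      bestv <- v
      best <- t0 + c(dx, dy, dz)
    }
  }
  best
}

level_factors <- function(levels) rev(2^(seq_len(levels) - 1))

# ---- stages -----------------------------------------------------------------

# memoising pyramid accessor shared by the stages of one registration
make_pyramid <- function(img) {
  cache <- list()
  function(f) {
    key <- as.character(f)
    if (is.null(cache[[key]])) cache[[key]] <<- downsample_image(img, f)
    cache[[key]]
  }
}

optimize_linear_stage <- function(fixed, moving, cfg, levels, par0, make_chain,
                                  parscale, stage_name, polish_idx = NULL) {
  par <- par0
  for (f in level_factors(levels)) {
    fx <- fixed(f)
    mv <- moving(f)
    obj <- make_mi_objective(fx, mv, cfg, make_chain)
    # restart Nelder-Mead once per level: a fresh simplex escapes the
    # premature collapse the method is prone to
    for (restart in 1:2) {
      opt <- optim(par, obj, method = "Nelder-Mead",
                   control = list(maxit = cfg$max_iterations,
                                  parscale = parscale, reltol = 1e-9))
      if (opt$convergence != 0)
        mmseg_log("%s stage (level factor %d): iteration cap reached, keeping best-so-far",
                  stage_name, f)
      par <- opt$par
    }
    if (f == 1 && !is.null(polish_idx)) {
      # 1D line polish of the translations: the MI optimum can be sharper
      # than the final simplex, which Nelder-Mead then straddles
      for (round in 1:2) {
        for (j in polish_idx) {
          f1 <- function(v) {
            p <- par
            p[j] <- v
            obj(p)
          }
          grid <- par[j] + seq(-6, 6, by = 0.5)
          vals <- vapply(grid, f1, numeric(1))
          best <- grid[which.min(vals)]
          par[j] <- stats::optimize(f1, interval = best + c(-0.5, 0.5),
                                    tol = 0.02)$minimum
        }
      }
    }
  }
  par
}

optimize_ffd_stage <- function(fixed, moving, chain, cfg) {
  h <- cfg$ffd_grid_spacing_mm
  d <- dim(fixed$data)
  cidx <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1), c(0, d[3] - 1)))
  cw <- sweep(cidx %*% t(fixed$direction %*% diag(fixed$spacing)), 2,
              fixed$origin, "+")
  lo <- apply(cw, 2, min)
  hi <- apply(cw, 2, max)
  gorigin <- lo - h
  gdims <- pmax(4L, as.integer(floor((hi - lo) / h) + 5))
  nvox <- prod(d)
  n <- min(nvox, 2L * cfg$n_samples)
  sub <- if (n == nvox) seq_len(nvox) else sample.int(nvox, n)
  pts <- voxel_world_coords(fixed, sub)
  fvals <- as.numeric(fixed$data[sub])
  m <- chain_linear(chain)
  y0 <- sweep(pts %*% t(m[, 1:3]), 2, m[, 4], "+")
  pre <- ffd_precompute_cpp(pts, gorigin, h, gdims)
  # index-space gradient volumes of the moving image (central differences)
  grad_vol <- function(v, ax) {
    dd <- dim(v)
    g <- array(0, dd)
    n1 <- dd[ax]
    if (n1 < 3) return(g)
    if (ax == 1) g[2:(n1 - 1), , ] <- (v[3:n1, , ] - v[1:(n1 - 2), , ]) / 2
    if (ax == 2) g[, 2:(n1 - 1), ] <- (v[, 3:n1, ] - v[, 1:(n1 - 2), ]) / 2
    if (ax == 3) g[, , 2:(n1 - 1)] <- (v[, , 3:n1] - v[, , 1:(n1 - 2)]) / 2
    g
  }
  mvd <- moving$data
  gx <- grad_vol(mvd, 1); gy <- grad_vol(mvd, 2); gz <- grad_vol(mvd, 3)
  invjt <- t(solve(moving$direction %*% diag(moving$spacing)))
  w2i <- w2i_matrix(moving)
  coefs <- matrix(0, prod(gdims), 3)
  eval_at <- function(cf, want_grad) {
    ffd_ssd_grad_cpp(pre$base, pre$w, gdims, cf, y0, fvals,
                     as.numeric(mvd), dim(mvd), w2i,
                     as.numeric(gx), as.numeric(gy), as.numeric(gz),
                     invjt, want_grad)
  }
  res <- eval_at(coefs, TRUE)
  ssd <- res$ssd
  step <- 0.05 * h
  for (it in seq_len(cfg$max_iterations)) {
    g <- res$grad
    gmax <- max(abs(g))
    if (gmax == 0) break
    trial <- coefs - (step / gmax) * g
    ssd_t <- eval_at(trial, FALSE)$ssd
    if (ssd_t < ssd) {
      improved <- (ssd - ssd_t) / max(ssd, 1e-12)
      coefs <- trial
      ssd <- ssd_t
      res <- eval_at(coefs, TRUE)
      step <- step * 1.2
      if (improved < 1e-5) break
    } else {
      step <- step / 2
      if (step < 1e-3 * h) break
    }
  }
  list(origin = gorigin, spacing = h, dims = gdims, coefs = coefs)
}

#' Register a moving image to a fixed image
#'
#' Multi-stage registration: a rigid stage initialised by aligning the two
#' images' geometric centres, an affine refinement, then a cubic B-spline
#' free-form deformation. Rigid and affine stages maximise mutual
#' information over a multi-resolution pyramid; the free-form stage
#' minimises squared intensity differences with analytic gradients on the
#' control-point displacements. The returned chain maps fixed-image physical
#' coordinates into moving-image physical coordinates (the resampling
#' convention), so [apply_transform()] pulls the moving image onto the fixed
#' grid. Deterministic for a fixed `cfg$seed`.
#'
#' @param fixed,moving `volumetric_image` objects with non-constant
#'   intensities.
#' @param cfg a [registration_config()].
#' @return A `transform_chain`.
#' @export
register_pair <- function(fixed, moving, cfg = registration_config()) {
  if (sd(fixed$data) == 0 || sd(moving$data) == 0)
    stop("constant image: similarity metric is undefined")
  with_seed(cfg$seed, {
    center <- phys_center(fixed)
    t0 <- phys_center(moving) - center
    chain <- structure(list(center = center,
                            rigid = list(angles = c(0, 0, 0), translation = t0),
                            affine = NULL, ffd = NULL),
                       class = "transform_chain")
    fx_pyr <- make_pyramid(fixed)
    mv_pyr <- make_pyramid(moving)
    if (cfg$rigid_levels > 0) {
      t0 <- translation_grid_search(fx_pyr, mv_pyr, cfg, t0, center)
      par <- c(0, 0, 0, t0)
      par <- optimize_linear_stage(
        fx_pyr, mv_pyr, cfg, cfg$rigid_levels, par,
        function(p) {
          ch <- chain
          ch$rigid <- list(angles = p[1:3], translation = p[4:6])
          ch
        },
        parscale = c(rep(0.2, 3), rep(20, 3)), stage_name = "rigid",
        polish_idx = 4:6)
      chain$rigid <- list(angles = par[1:3], translation = par[4:6])
    }
    if (cfg$affine_levels > 0) {
      par <- c(as.vector(diag(3)), 0, 0, 0)
      par <- optimize_linear_stage(
        fx_pyr, mv_pyr, cfg, cfg$affine_levels, par,
        function(p) {
          ch <- chain
          ch$affine <- list(A = matrix(p[1:9], 3, 3), t = p[10:12])
          ch
        },
        parscale = c(rep(0.1, 9), rep(10, 3)), stage_name = "affine")
      chain$affine <- list(A = matrix(par[1:9], 3, 3), t = par[10:12])
    }
    if (cfg$ffd_levels > 0)
      chain$ffd <- optimize_ffd_stage(fixed, moving, chain, cfg)
    chain
  })
}

#' Resample an image through a transform chain
#'
#' Pulls `moving` onto the grid of `reference`: each reference voxel centre
#' is mapped through the chain into moving-image space and the moving image
#' is interpolated there (linear by default, the convention for intensity
#' images). Points falling outside the moving volume take the moving image's
#' minimum intensity.
#'
#' @param moving image to resample.
#' @param chain `transform_chain` mapping reference space to moving space.
#' @param reference image providing the output grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @export
apply_transform <- function(moving, chain, reference,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  pts <- voxel_world_coords(reference)
  y <- chain_apply(chain, pts)
  w2i <- w2i_matrix(moving)
  ci <- sweep(y %*% t(w2i[1:3, 1:3]), 2, w2i[1:3, 4], "+")
  fill <- min(moving$data)
  vals <- interp_cpp(as.numeric(moving$data), dim(moving$data), ci,
                     interpolation == "nearest", fill)
  volumetric_image(array(vals, dim(reference$data)), reference$spacing,
                   reference$origin, reference$direction)
}

#' Warp a binary mask through a transform chain
#'
#' Nearest-neighbour resampling so the output is strictly binary (linear
#' interpolation would create fractional labels); the intensity-image
#' convention of linear resampling does not apply to masks.
#'
#' @param mask `binary_mask` in moving-image space.
#' @param chain `transform_chain` mapping reference space to mask space.
#' @param reference image providing the output grid.
#' @export
warp_mask <- function(mask, chain, reference) {
  pts <- voxel_world_coords(reference)
  y <- chain_apply(chain, pts)
  w2i <- w2i_matrix(mask)
  ci <- sweep(y %*% t(w2i[1:3, 1:3]), 2, w2i[1:3, 4], "+")
  vals <- interp_cpp(as.numeric(mask$data), dim(mask$data), ci, TRUE, 0)
  binary_mask(array(vals > 0.5, dim(reference$data)), reference$spacing,
              reference$origin, reference$direction, mask$role)
}
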