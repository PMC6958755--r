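#' Specification of a synthetic whole-body DWI/T1 phantom
#'
#' The phantom emulates the image properties the lesion detector relies on:
#' a soft-tissue "torso" (elliptical cylinder) over an air background; a
#' skeleton made of a spine tube and two leg tubes (the head end of the
#' volume carries no skeleton, mirroring atlas drawings that exclude the
#' head); bright organ blobs away from the skeleton (kidneys, bladder by
#' default); a psoas-like reference box anterior to the spine; and bright
#' lesion spheres placed strictly inside the skeleton, hypointense on T1
#' relative to the psoas. The b = 0 companion volume is generated from the
#' high-b volume through the mono-exponential forward model with per-tissue
#' ADC values, so ADC estimation can be validated exactly in the noise-free
#' case. Optional "confounder" blobs are DWI-bright *and* T1-bright spheres
#' inside the skeleton band: they survive organ removal and thresholding and
#' must be caught by the T1 false-positive filter.
#'
#' Lesion DWI intensity is `marrow + lesion_dwi_contrast * 1.349 * sigma`,
#' i.e. a fixed multiple of the background interquartile range (1.349 sigma
#' for Gaussian noise); the default of 6 IQRs gives the default detector
#' (k = 4) a clear margin. With `noise_sigma = 0` a nominal sigma of 5 is
#' used for the contrast scale so noise-free phantoms still contain lesions.
#'
#' @param shape volume dimensions in voxels (default 96 x 64 x 160).
#' @param spacing voxel spacing in mm (default 2 mm isotropic).
#' @param n_lesions number of lesion spheres (default 5; may be 0).
#' @param lesion_radius_mm min/max lesion radius in mm (default 4-8).
#' @param lesion_dwi_contrast lesion contrast in multiples of the background
#'   IQR (default 6).
#' @param n_confounders number of T1-bright confounder spheres in the
#'   skeleton (default 0).
#' @param noise_sigma noise standard deviation on all volumes (default 5).
#' @param noise_model `"rician"` (magnitude-MRI, default) or `"gaussian"`.
#' @param b_high higher b-value in s/mm^2 (default 800).
#' @param seed RNG seed; generation is bitwise reproducible per seed.
#' @param organ_blobs list of organ descriptions (`center_frac`, `radii_mm`,
#'   `dwi`, `t1`, `adc`); defaults to two kidneys and a bladder, all more
#'   than 10 mm clear of the skeleton.
#' @param skeleton_geometry spine/leg tube parameters (fractions of the
#'   volume extent plus radii in mm).
#' @param psoas_region reference-box parameters.
#' @param intensities,adc_values per-tissue DWI/T1 intensities and ADC
#'   values (mm^2/s).
#' @return A `phantom_spec` object for [generate_phantom_pair()].
#' @export
phantom_spec <- function(shape = c(96, 64, 160), spacing = c(2, 2, 2),
                         n_lesions = 5, lesion_radius_mm = c(4, 8),
                         lesion_dwi_contrast = 6, n_confounders = 0,
                         noise_sigma = 5,
                         noise_model = c("rician", "gaussian"),
                         b_high = 800, seed = 1,
                         organ_blobs = NULL, skeleton_geometry = NULL,
                         psoas_region = NULL, intensities = NULL,
                         adc_values = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(shape) == 3, all(shape >= 16), all(spacing > 0),
            n_lesions >= 0, n_confounders >= 0, noise_sigma >= 0,
            lesion_radius_mm[1] > 0,
            lesion_radius_mm[2] >= lesion_radius_mm[1],
            lesion_dwi_contrast > 0, b_high > 0)
  organ_blobs <- organ_blobs %||% list(
    list(name = "kidney_left", center_frac = c(0.30, 0.45, 0.62),
         radii_mm = c(14, 10, 18), dwi = 300, t1 = 120, adc = 1.2e-3),
    list(name = "kidney_right", center_frac = c(0.70, 0.45, 0.62),
         radii_mm = c(14, 10, 18), dwi = 300, t1 = 120, adc = 1.2e-3),
    list(name = "bladder", center_frac = c(0.50, 0.30, 0.30),
         radii_mm = c(14, 12, 12), dwi = 280, t1 = 100, adc = 1.6e-3))
  skeleton_geometry <- skeleton_geometry %||% list(
    spine = list(center_frac = c(0.50, 0.62), radius_mm = 12,
                 z_frac = c(0.10, 0.78)),
    legs = list(x_frac = c(0.35, 0.65), y_frac = 0.50, radius_mm = 8,
                z_frac = c(0.08, 0.30)))
  psoas_region <- psoas_region %||% list(
    center_frac = c(0.50, 0.35), half_mm = c(6, 6), z_frac = c(0.38, 0.60))
  intensities <- intensities %||% list(
    air_dwi = 10, air_t1 = 5, soft_dwi = 100, soft_t1 = 150,
    marrow_dwi = 100, marrow_t1 = 180, lesion_t1 = 80, psoas_t1 = 150,
    confounder_t1 = 300)
  adc_values <- adc_values %||% list(
    air = 0, soft = 1.5e-3, marrow = 0.7e-3, lesion = 0.8e-3,
    psoas = 1.4e-3, confounder = 1.0e-3)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_dwi_contrast = lesion_dwi_contrast,
                 n_confounders = as.integer(n_confounders),
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 b_high = b_high, seed = seed, organ_blobs = organ_blobs,
                 skeleton_geometry = skeleton_geometry,
                 psoas_region = psoas_region, intensities = intensities,
                 adc_values = adc_values),
            class = "phantom_spec")
}

# squared-distance building blocks ------------------------------------------

axis_mm <- function(n, sp) (seq_len(n) - 1) * sp

ellipsoid_arr <- function(shape, spacing, center_mm, radii_mm) {
  a1 <- ((axis_mm(shape[1], spacing[1]) - center_mm[1]) / radii_mm[1])^2
  a2 <- ((axis_mm(shape[2], spacing[2]) - center_mm[2]) / radii_mm[2])^2
  a3 <- ((axis_mm(shape[3], spacing[3]) - center_mm[3]) / radii_mm[3])^2
  outer(outer(a1, a2, "+"), a3, "+") <= 1
}

ztube_arr <- function(shape, spacing, cx_mm, cy_mm, radius_mm, z_mm) {
  a1 <- (axis_mm(shape[1], spacing[1]) - cx_mm)^2
  a2 <- (axis_mm(shape[2], spacing[2]) - cy_mm)^2
  zz <- axis_mm(shape[3], spacing[3])
  inplane <- outer(a1, a2, "+") <= radius_mm^2
  zin <- zz >= z_mm[1] & zz <= z_mm[2]
  outer(inplane, zin, "&")
}

erode_by_ball <- function(mask_arr, shape, spacing, radius_mm) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dz * spacing[3])^2 <= radius_mm^2
  off <- as.matrix(g[keep, , drop = FALSE])
  array(erode_cpp(as.logical(mask_arr), shape, off), shape)
}

dilate_arr <- function(mask_arr, shape, spacing, radius_mm) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dz * spacing[3])^2 <= radius_mm^2
  off <- as.matrix(g[keep, , drop = FALSE])
  array(dilate_cpp(as.logical(mask_arr), shape, off), shape)
}

sphere_arr <- function(shape, spacing, center_mm, radius_mm) {
  ellipsoid_arr(shape, spacing, center_mm, rep(radius_mm, 3))
}

#' Generate a paired DWI/T1 phantom with ground-truth masks
#'
#' See [phantom_spec()] for what the phantom emulates. The high-b DWI is
#' built from per-tissue intensities, the b = 0 volume follows the forward
#' mono-exponential model `S0 = S_high * exp(b * ADC)` voxelwise with the
#' per-tissue ADC map, and the T1 volume places lesions below the psoas
#' reference intensity. Noise (Rician by default) is injected last, into all
#' three volumes independently. Lesions (and confounders) are placed by
#' seeded rejection sampling strictly inside the skeleton tubes, away from
#' organs and from each other; if a sphere cannot be placed the generator
#' errors rather than bending the constraints.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `dwi_high`, `dwi_b0`, `t1` (`volumetric_image`s), `adc`
#'   (the noise-free per-tissue ADC array, mm^2/s), and `truth` (masks:
#'   `lesion_mask`, `organ_mask`, `skeleton_mask`, `psoas_mask`,
#'   `confounder_mask`).
#' @export
generate_phantom_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sh <- spec$shape
    sp <- spec$spacing
    ext <- (sh - 1) * sp
    ints <- spec$intensities
    adcv <- spec$adc_values
    sigma_eff <- if (spec$noise_sigma > 0) spec$noise_sigma else 5
    lesion_dwi <- ints$marrow_dwi +
      spec$lesion_dwi_contrast * 1.349 * sigma_eff

    # torso: elliptical cylinder of soft tissue spanning the whole z range
    a1 <- ((axis_mm(sh[1], sp[1]) - 0.5 * ext[1]) / (0.45 * ext[1]))^2
    a2 <- ((axis_mm(sh[2], sp[2]) - 0.5 * ext[2]) / (0.45 * ext[2]))^2
    body <- outer(outer(a1, a2, "+"), rep(0, sh[3]), "+") <= 1

    sg <- spec$skeleton_geometry
    spine <- ztube_arr(sh, sp, sg$spine$center_frac[1] * ext[1],
                       sg$spine$center_frac[2] * ext[2], sg$spine$radius_mm,
                       sg$spine$z_frac * ext[3])
    skel <- spine
    for (xf in sg$legs$x_frac) {
      skel <- skel | ztube_arr(sh, sp, xf * ext[1], sg$legs$y_frac * ext[2],
                               sg$legs$radius_mm, sg$legs$z_frac * ext[3])
    }

    pr <- spec$psoas_region
    px <- abs(axis_mm(sh[1], sp[1]) - pr$center_frac[1] * ext[1]) <= pr$half_mm[1]
    py <- abs(axis_mm(sh[2], sp[2]) - pr$center_frac[2] * ext[2]) <= pr$half_mm[2]
    pz <- axis_mm(sh[3], sp[3]) >= pr$z_frac[1] * ext[3] &
      axis_mm(sh[3], sp[3]) <= pr$z_frac[2] * ext[3]
    psoas <- outer(outer(px, py, "&"), pz, "&")

    organ <- array(FALSE, sh)
    organ_list <- list()
    for (ob in spec$organ_blobs) {
      m <- ellipsoid_arr(sh, sp, ob$center_frac * ext, ob$radii_mm)
      organ_list[[length(organ_list) + 1]] <- list(mask = m, blob = ob)
      organ <- organ | m
    }

    # sphere placement inside the skeleton, away from organs and each other
    exclusion <- dilate_arr(organ, sh, sp, 8)
    erosion_cache <- list()
    place_sphere <- function(radius_mm, taken) {
      # conservative fit test at the next whole mm, so erosions are cached
      r_fit <- ceiling(radius_mm)
      key <- sprintf("%d", r_fit)
      if (is.null(erosion_cache[[key]]))
        erosion_cache[[key]] <<- erode_by_ball(skel, sh, sp, r_fit)
      ok <- erosion_cache[[key]] & !taken & !exclusion
      idx <- which(ok)
      if (length(idx) == 0)
        stop("lesions not placeable inside skeleton")
      pick <- idx[sample.int(length(idx), 1)]
      s0 <- pick - 1L
      c(s0 %% sh[1], (s0 %/% sh[1]) %% sh[2], s0 %/% (sh[1] * sh[2])) * sp
    }

    taken <- array(FALSE, sh)
    confounder <- array(FALSE, sh)
    if (spec$n_confounders > 0) {
      for (i in seq_len(spec$n_confounders)) {
        ctr <- place_sphere(6, taken)
        s <- sphere_arr(sh, sp, ctr, 6)
        confounder <- confounder | s
        taken <- taken | dilate_arr(s, sh, sp, 10)
      }
    }
    lesion <- array(FALSE, sh)
    lesion_radii <- numeric(0)
    if (spec$n_lesions > 0) {
      for (i in seq_len(spec$n_lesions)) {
        r <- runif(1, spec$lesion_radius_mm[1], spec$lesion_radius_mm[2])
        ctr <- place_sphere(r, taken)
        s <- sphere_arr(sh, sp, ctr, r)
        lesion <- lesion | s
        lesion_radii <- c(lesion_radii, r)
        taken <- taken | dilate_arr(s, sh, sp, r + 4)
      }
    }

    # paint intensity and ADC volumes, later tissues override earlier ones
    dwi <- array(ints$air_dwi, sh)
    t1 <- array(ints$air_t1, sh)
    adc <- array(adcv$air, sh)
    paint <- function(m, d, t, a) {
      dwi[m] <<- d; t1[m] <<- t; adc[m] <<- a
      invisible(NULL)
    }
    paint(body, ints$soft_dwi, ints$soft_t1, adcv$soft)
    paint(psoas, ints$soft_dwi, ints$psoas_t1, adcv$psoas)
    for (ol in organ_list)
      paint(ol$mask, ol$blob$dwi, ol$blob$t1, ol$blob$adc)
    paint(skel, ints$marrow_dwi, ints$marrow_t1, adcv$marrow)
    paint(confounder, lesion_dwi, ints$confounder_t1, adcv$confounder)
    paint(lesion, lesion_dwi, ints$lesion_t1, adcv$lesion)

    b0 <- dwi * exp(spec$b_high * adc)

    add_noise <- function(v, sigma) {
      if (sigma == 0) return(v)
      if (spec$noise_model == "gaussian")
        v + array(rnorm(length(v), 0, sigma), dim(v))
      else
        sqrt((v + array(rnorm(length(v), 0, sigma), dim(v)))^2 +
               array(rnorm(length(v), 0, sigma), dim(v))^2)
    }
    dwi_n <- add_noise(dwi, spec$noise_sigma)
    b0_n <- add_noise(b0, spec$noise_sigma)
    t1_n <- add_noise(t1, spec$noise_sigma)

    as_img <- function(v) volumetric_image(v, sp)
    as_mask <- function(m, role) binary_mask(m, sp, role = role)
    out <- list(
      dwi_high = as_img(dwi_n), dwi_b0 = as_img(b0_n), t1 = as_img(t1_n),
      adc = adc,
      truth = list(lesion_mask = as_mask(lesion, "lesion"),
                   organ_mask = as_mask(organ, "organ"),
                   skeleton_mask = as_mask(skel, "skeleton"),
                   psoas_mask = as_mask(psoas, "muscle_reference"),
                   confounder_mask = as_mask(confounder, "lesion")),
      lesion_radii_mm = lesion_radii,
      spec = spec)
    out
  })
}

#' Generate a cohort of pose-perturbed phantom subjects
#'
#' Produces `n_subjects` phantoms from a shared base specification, each
#' with its own noise realisation (per-subject seed, logged in the output),
#' a random rigid pose perturbation (translations up to
#' `deformation_scale` mm per axis, rotations up to 2 degrees) applied to
#' all volumes and truth masks, and a small multiplicative intensity jitter.
#' With `deformation_scale = 0` every subject keeps the base pose (only the
#' noise differs, and with `intensity_jitter = 0` and a shared seed they are
#' identical). The cohort exercises atlas building and search-region
#' propagation.
#'
#' @param n_subjects at least 2.
#' @param base_spec a [phantom_spec()].
#' @param deformation_scale maximum per-axis translation in mm.
#' @param seed cohort-level seed.
#' @param intensity_jitter standard deviation of the per-subject intensity
#'   scale factor (default 0.02).
#' @param vary_noise_seed give each subject its own noise realisation
#'   (default TRUE).
#' @return List of phantom pairs (see [generate_phantom_pair()]); each has
#'   extra fields `subject_seed` and `pose_chain` (the applied rigid chain,
#'   `NULL` when the scale is 0).
#' @export
generate_cohort <- function(n_subjects, base_spec = phantom_spec(),
                            deformation_scale = 6, seed = 1,
                            intensity_jitter = 0.02, vary_noise_seed = TRUE) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  with_seed(seed, {
    subject_seeds <- sample.int(.Machine$integer.max %/% 2, n_subjects)
    lapply(seq_len(n_subjects), function(i) {
      sp_i <- base_spec
      if (vary_noise_seed) sp_i$seed <- subject_seeds[i]
      pair <- generate_phantom_pair(sp_i)
      chain <- NULL
      if (deformation_scale > 0) {
        trans <- runif(3, -deformation_scale, deformation_scale)
        angles <- runif(3, -1, 1) * (2 * pi / 180)
        chain <- rigid_chain(angles, trans, phys_center(pair$dwi_high))
        pair$dwi_high <- apply_transform(pair$dwi_high, chain, pair$dwi_high)
        pair$dwi_b0 <- apply_transform(pair$dwi_b0, chain, pair$dwi_b0)
        pair$t1 <- apply_transform(pair$t1, chain, pair$t1)
        pair$truth <- lapply(pair$truth, function(m)
          warp_mask(m, chain, pair$dwi_high))
      }
      if (intensity_jitter > 0) {
        f <- 1 + rnorm(1, 0, intensity_jitter)
        for (nm in c("dwi_high", "dwi_b0", "t1"))
          pair[[nm]]$data <- pair[[nm]]$data * f
      }
      pair$subject_seed <- sp_i$seed
      pair$pose_chain <- chain
      pair
    })
  })
}
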