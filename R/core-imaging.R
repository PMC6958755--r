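#' Construct a volumetric image
#'
#' A `volumetric_image` is a 3D scalar grid with physical geometry: voxel
#' spacing in mm, the physical position of the first voxel centre (origin),
#' and a 3x3 direction (axis orientation) matrix. All spatial operations in
#' the package are grid-aware: voxel indices are mapped to physical mm
#' coordinates through `origin + direction %*% (spacing * index)`.
#'
#' @param data 3D numeric array, finite everywhere.
#' @param spacing length-3 positive numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, physical coordinate (mm) of voxel (1,1,1).
#' @param direction 3x3 direction cosine matrix (default identity).
#' @return An object of class `volumetric_image`.
#' @export
volumetric_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction),
            class = "volumetric_image")
}

#' @export
print.volumetric_image <- function(x, ...) {
  cat(sprintf("<volumetric_image> %s voxels, spacing %s mm, origin (%s)\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary mask on an image grid
#'
#' @param data 3D logical (or coercible) array.
#' @param spacing,origin,direction grid geometry, as [volumetric_image()].
#' @param role one of `"organ"`, `"skeleton"`, `"search_region"`, `"lesion"`,
#'   `"muscle_reference"`, `"reader"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3), role = "lesion") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume")
  role <- match.arg(role, c("organ", "skeleton", "search_region", "lesion",
                            "muscle_reference", "reader"))
  storage.mode(data) <- "logical"
  if (any(is.na(data))) stop("mask contains NA")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction,
                 role = role),
            class = "binary_mask")
}

#' Build a mask sharing an image's grid
#' @param image a `volumetric_image` (or another mask) providing the grid.
#' @param data logical array (defaults to all-false).
#' @param role mask role, see [binary_mask()].
#' @export
mask_like <- function(image, data = NULL, role = "lesion") {
  if (is.null(data)) data <- array(FALSE, dim(image$data))
  binary_mask(data, image$spacing, image$origin, image$direction, role)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask role=%s> %s voxels, %d set (%.3f ml)\n",
              x$role, paste(dim(x$data), collapse = "x"),
              voxel_count(x), volume_ml(x)))
  invisible(x)
}

#' Number of set voxels in a mask
#' @param mask a `binary_mask`.
#' @export
voxel_count <- function(mask) sum(mask$data)

#' Mask volume in millilitres
#'
#' Voxel count times the voxel volume (product of spacings), divided by 1000
#' (mm^3 to ml).
#' @param mask a `binary_mask`.
#' @export
volume_ml <- function(mask) voxel_count(mask) * prod(mask$spacing) / 1000

#' Are two images/masks defined on the same grid?
#'
#' Shape must match exactly; spacing, origin and direction must agree within
#' `tol`. No operation in the package resamples implicitly: a grid mismatch
#' is always an error at the call site.
#' @param a,b `volumetric_image` or `binary_mask` objects.
#' @param tol numeric tolerance on the geometry fields.
#' @export
grid_compatible <- function(a, b, tol = 1e-4) {
  da <- if (is.null(a$data)) a$labels else a$data
  db <- if (is.null(b$data)) b$labels else b$data
  identical(dim(da), dim(db)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

stop_if_incompatible <- function(a, b) {
  if (!grid_compatible(a, b)) stop("grids are not compatible")
  invisible(NULL)
}

# voxel index (1-based) -> physical mm, as 4x4 homogeneous matrix on 0-based
# indices
i2w_matrix <- function(img) {
  rbind(cbind(img$direction %*% diag(img$spacing), img$origin), c(0, 0, 0, 1))
}

w2i_matrix <- function(img) solve(i2w_matrix(img))

# physical coordinates of all voxel centres (n x 3), 0-based index order
voxel_world_coords <- function(img, subset = NULL) {
  d <- dim(img$data)
  if (is.null(subset)) subset <- seq_len(prod(d))
  s0 <- subset - 1L
  ix <- s0 %% d[1]
  iy <- (s0 %/% d[1]) %% d[2]
  iz <- s0 %/% (d[1] * d[2])
  idx <- cbind(ix, iy, iz)
  sweep(idx %*% t(img$direction %*% diag(img$spacing)), 2, img$origin, "+")
}

# physical centre of the image domain
phys_center <- function(img) {
  d <- dim(img$data)
  as.numeric(img$origin + img$direction %*% (img$spacing * (d - 1) / 2))
}

#' Read a 3D volume from a NIfTI file
#'
#' Geometry (spacing, origin, direction) is taken from the NIfTI header; a
#' file without usable spacing, or holding non-3D or non-finite data, is an
#' error rather than silently defaulting.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volumetric_image()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.array(img), d[1:3])
  } else if (length(d) == 3L) {
    img2 <- as.array(img)
  } else stop("expected 3D volume")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in header")
  xf <- RNifti::xform(img)
  direction <- xf[1:3, 1:3] %*% diag(1 / sp)
  origin <- xf[1:3, 4]
  if (any(!is.finite(img2))) stop("volume contains non-finite values")
  volumetric_image(img2, sp, origin, direction)
}

#' Write a volume (or mask / label map) to NIfTI
#'
#' Masks are written as 8-bit integers, label maps as 32-bit integers,
#' intensity images as their native numeric type. Geometry round-trips
#' through [load_volume()].
#'
#' @param x a `volumetric_image`, `binary_mask` or `labeled_components`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @export
save_volume <- function(x, path) {
  if (inherits(x, "labeled_components")) {
    arr <- x$labels
    storage.mode(arr) <- "integer"
    geom <- x
  } else if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$data), dim(x$data))
    geom <- x
  } else {
    arr <- x$data
    geom <- x
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geom$spacing
  m <- rbind(cbind(geom$direction %*% diag(geom$spacing), geom$origin),
             c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a NIfTI file as a binary mask
#' @param path file path; nonzero voxels become `TRUE`.
#' @param role mask role, see [binary_mask()].
#' @export
load_mask <- function(path, role = "lesion") {
  v <- load_volume(path)
  binary_mask(v$data != 0, v$spacing, v$origin, v$direction, role)
}

#' Dilate a mask by a physical spherical radius
#'
#' Spacing-aware binary dilation: the output contains exactly the voxels
#' whose centre lies within `radius_mm` (Euclidean physical distance, closed
#' ball) of the centre of some input voxel. With anisotropic spacing the
#' structuring element therefore spans a different number of voxels along
#' each axis. `radius_mm = 0` is the identity.
#'
#' @param mask a `binary_mask`.
#' @param radius_mm non-negative dilation radius in mm.
#' @export
dilate_mask <- function(mask, radius_mm) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || is.na(radius_mm) ||
      radius_mm < 0)
    stop("radius_mm must be a single non-negative number")
  sp <- mask$spacing
  r <- floor(radius_mm / sp)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (g$dx * sp[1])^2 + (g$dy * sp[2])^2 + (g$dz * sp[3])^2 <= radius_mm^2
  off <- as.matrix(g[keep, , drop = FALSE])
  out <- dilate_cpp(as.logical(mask$data), dim(mask$data), off)
  binary_mask(array(out, dim(mask$data)), mask$spacing, mask$origin,
              mask$direction, mask$role)
}

#' Label connected components of a mask
#'
#' Two voxels share a label iff they are joined by a chain of neighbours
#' under the chosen connectivity (6 = faces, 18 = faces+edges, 26 = full
#' neighbourhood, the default). Labels are 1..K, assigned by the raster-order
#' position of each component's first voxel, so the labelling is
#' deterministic. An empty mask yields zero components.
#'
#' @param mask a `binary_mask`.
#' @param connectivity 6, 18 or 26.
#' @return A `labeled_components` object: integer `labels` array plus a
#'   `components` data frame (id, voxel_count, volume_ml, bounding box).
#' @export
connected_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  lab <- cc_label_cpp(as.logical(mask$data), dim(mask$data),
                      as.integer(connectivity))
  labels <- array(lab, dim(mask$data))
  labeled_components(labels, mask$spacing, mask$origin, mask$direction)
}

#' Construct a labeled-components object from a label array
#'
#' @param labels 3D integer array, 0 = background, components labelled 1..K
#'   contiguously.
#' @param spacing,origin,direction grid geometry.
#' @export
labeled_components <- function(labels, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0), direction = diag(3)) {
  storage.mode(labels) <- "integer"
  k <- max(labels, 0L)
  vox_ml <- prod(spacing) / 1000
  if (k > 0) {
    counts <- tabulate(labels[labels > 0L], nbins = k)
    if (any(counts == 0)) stop("label ids must be contiguous 1..K")
    idx <- which(labels > 0L)
    d <- dim(labels)
    s0 <- idx - 1L
    co <- cbind((s0 %% d[1]) + 1L, ((s0 %/% d[1]) %% d[2]) + 1L,
                (s0 %/% (d[1] * d[2])) + 1L)
    lv <- labels[idx]
    comp <- data.frame(
      id = seq_len(k), voxel_count = counts, volume_ml = counts * vox_ml,
      x_min = tapply(co[, 1], lv, min), x_max = tapply(co[, 1], lv, max),
      y_min = tapply(co[, 2], lv, min), y_max = tapply(co[, 2], lv, max),
      z_min = tapply(co[, 3], lv, min), z_max = tapply(co[, 3], lv, max),
      row.names = NULL)
  } else {
    comp <- data.frame(id = integer(), voxel_count = integer(),
                       volume_ml = numeric(), x_min = integer(),
                       x_max = integer(), y_min = integer(), y_max = integer(),
                       z_min = integer(), z_max = integer())
  }
  structure(list(labels = labels, components = comp,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 direction = direction),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d component(s), %d voxel(s) total\n",
              nrow(x$components), sum(x$components$voxel_count)))
  if (nrow(x$components) > 0) print(utils::head(x$components, 10))
  invisible(x)
}

#' Number of components
#' @param x a `labeled_components` object.
#' @export
n_components <- function(x) nrow(x$components)

# binarized view of a label map, as a mask
components_mask <- function(x, role = "lesion") {
  binary_mask(x$labels > 0L, x$spacing, x$origin, x$direction, role)
}

#' Union of binary masks
#'
#' Voxelwise OR over any number of grid-compatible masks. This is how the
#' per-reader organ drawings are merged into a single organ mask (a voxel is
#' organ if any reader marked it).
#'
#' @param ... `binary_mask` objects, or a single list of them.
#' @param role role of the result (default: role of the first input).
#' @export
mask_union <- function(..., role = NULL) {
  masks <- list(...)
  if (length(masks) == 1 && is.list(masks[[1]]) && !inherits(masks[[1]], "binary_mask"))
    masks <- masks[[1]]
  if (length(masks) == 0) stop("no masks given")
  acc <- masks[[1]]$data
  for (m in masks[-1]) {
    stop_if_incompatible(masks[[1]], m)
    acc <- acc | m$data
  }
  binary_mask(acc, masks[[1]]$spacing, masks[[1]]$origin,
              masks[[1]]$direction, role %||% masks[[1]]$role)
}

#' Set difference of binary masks
#'
#' Voxels of `a` not in `b`; used to carve the hyperintense organs out of the
#' skeleton search band.
#' @param a,b grid-compatible `binary_mask` objects.
#' @export
mask_subtract <- function(a, b) {
  stop_if_incompatible(a, b)
  binary_mask(a$data & !b$data, a$spacing, a$origin, a$direction, a$role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
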