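#' Bundle an atlas template with its organ and skeleton masks
#'
#' An atlas is a representative mean DWI image of a population together with
#' pre-drawn masks: the union of the readers' hyperintense-organ drawings
#' (spleen, kidneys, spinal cord, bladder, testis) and a band around the
#' skeleton (head excluded at atlas-authoring time). Per-gender atlases are
#' simply two bundles with different `gender_tag`s.
#'
#' @param template `volumetric_image` mean template.
#' @param organ_mask,skeleton_mask `binary_mask`s grid-compatible with the
#'   template.
#' @param gender_tag `"male"`, `"female"` or `"generic"`.
#' @export
atlas_bundle <- function(template, organ_mask, skeleton_mask,
                         gender_tag = c("generic", "male", "female")) {
  gender_tag <- match.arg(gender_tag)
  stop_if_incompatible(template, organ_mask)
  stop_if_incompatible(template, skeleton_mask)
  structure(list(template = template, organ_mask = organ_mask,
                 skeleton_mask = skeleton_mask, gender_tag = gender_tag),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle gender=%s> template %s voxels; organs %d vox; skeleton %d vox\n",
              x$gender_tag, paste(dim(x$template$data), collapse = "x"),
              voxel_count(x$organ_mask), voxel_count(x$skeleton_mask)))
  invisible(x)
}

#' Persist an atlas bundle to a directory
#'
#' Writes `template.nii.gz`, `organs.nii.gz`, `skeleton.nii.gz` and a
#' `meta.json` with the gender tag.
#' @param atlas an [atlas_bundle()].
#' @param dir output directory (created if missing).
#' @export
save_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_volume(atlas$template, file.path(dir, "template.nii.gz"))
  save_volume(atlas$organ_mask, file.path(dir, "organs.nii.gz"))
  save_volume(atlas$skeleton_mask, file.path(dir, "skeleton.nii.gz"))
  jsonlite::write_json(list(gender_tag = atlas$gender_tag),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load an atlas bundle from a directory written by [save_atlas()]
#' @param dir atlas directory.
#' @export
load_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  atlas_bundle(load_volume(file.path(dir, "template.nii.gz")),
               load_mask(file.path(dir, "organs.nii.gz"), role = "organ"),
               load_mask(file.path(dir, "skeleton.nii.gz"), role = "skeleton"),
               gender_tag = meta$gender_tag)
}

#' Build a mean-template atlas by iterative registration and averaging
#'
#' One image is chosen as the first template; every image is registered to
#' it and the registered images are averaged into a new template. The
#' register-and-average round is repeated (3 rounds by default, after which
#' successive templates typically stop changing); an optional early stop
#' triggers when the mean template-to-template change drops below
#' `early_stop_tol` of the intensity range.
#'
#' With `normalize_pose = TRUE` (the default) each round's mean image is
#' additionally resampled through the inverse of the cohort's average linear
#' transform, the classic drift correction in iterative template building:
#' without it the template inherits the pose of the initial reference image
#' instead of converging to the cohort's average pose.
#'
#' @param images list of at least two `volumetric_image`s.
#' @param cfg a [registration_config()].
#' @param n_rounds number of register-and-average rounds (default 3).
#' @param initial_template_index which image seeds the first round.
#' @param early_stop_tol relative mean-change threshold for early stopping
#'   (`NULL` to always run all rounds).
#' @param normalize_pose correct template pose drift by the average linear
#'   transform (default TRUE).
#' @return The final mean template, with a `diagnostics` attribute holding
#'   the per-round mean absolute template change (relative to range).
#' @export
build_atlas <- function(images, cfg = registration_config(), n_rounds = 3,
                        initial_template_index = 1, early_stop_tol = NULL,
                        normalize_pose = TRUE) {
  if (length(images) < 2) stop("at least two images are required")
  stopifnot(initial_template_index >= 1,
            initial_template_index <= length(images))
  template <- images[[initial_template_index]]
  changes <- numeric(0)
  for (round in seq_len(n_rounds)) {
    chains <- lapply(images, function(img)
      register_pair(template, img, cfg))
    registered <- lapply(seq_along(images), function(i)
      apply_transform(images[[i]], chains[[i]], template)$data)
    mean_img <- Reduce(`+`, registered) / length(registered)
    mean_vol <- volumetric_image(mean_img, template$spacing, template$origin,
                                 template$direction)
    if (normalize_pose) {
      mbar <- Reduce(`+`, lapply(chains, chain_linear)) / length(chains)
      ainv <- solve(mbar[, 1:3])
      inv_chain <- structure(list(center = c(0, 0, 0), rigid = NULL,
                                  affine = list(A = ainv,
                                                t = as.numeric(-ainv %*% mbar[, 4])),
                                  ffd = NULL),
                             class = "transform_chain")
      mean_vol <- apply_transform(mean_vol, inv_chain, template)
    }
    rng <- diff(range(template$data))
    change <- mean(abs(mean_vol$data - template$data)) / max(rng, 1e-12)
    changes <- c(changes, change)
    mmseg_log("atlas round %d: mean template change %.3g of range", round, change)
    template <- mean_vol
    if (!is.null(early_stop_tol) && change < early_stop_tol) break
  }
  attr(template, "diagnostics") <- list(round_mean_change = changes)
  template
}
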