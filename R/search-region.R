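#' Search-region construction parameters
#'
#' Dilation radii applied to the warped atlas masks before the organ
#' removal: 4 mm on the organ mask (so organs are removed with a safety
#' margin) and 6 mm on the skeleton band (so the appendicular skeleton and
#' nearby marrow are included).
#'
#' @param organ_dilation_mm spherical dilation of the warped organ mask
#'   (default 4).
#' @param skeleton_dilation_mm spherical dilation of the warped skeleton
#'   mask (default 6).
#' @export
region_params <- function(organ_dilation_mm = 4, skeleton_dilation_mm = 6) {
  stopifnot(organ_dilation_mm >= 0, skeleton_dilation_mm >= 0)
  structure(list(organ_dilation_mm = organ_dilation_mm,
                 skeleton_dilation_mm = skeleton_dilation_mm),
            class = "region_params")
}

#' Build the per-patient lesion search region
#'
#' Registers the atlas template to the patient's high-b-value DWI (patient
#' image fixed), propagates the atlas organ and skeleton masks with the
#' resulting chain, dilates both, and removes the dilated organs from the
#' dilated skeleton band. The subtraction happens after both dilations so
#' hyperintense organs are removed with their full safety margin.
#'
#' @param patient_dwi patient high-b-value DWI `volumetric_image`.
#' @param atlas an [atlas_bundle()].
#' @param cfg a [registration_config()] for the atlas-to-patient
#'   registration.
#' @param params a [region_params()].
#' @param chain optional precomputed `transform_chain` (patient space to
#'   atlas space); when supplied the registration step is skipped.
#' @return A `binary_mask` with role `"search_region"` on the patient grid;
#'   the chain used is attached as attribute `"chain"`.
#' @export
build_search_region <- function(patient_dwi, atlas,
                                cfg = registration_config(),
                                params = region_params(), chain = NULL) {
  if (is.null(chain))
    chain <- register_pair(patient_dwi, atlas$template, cfg)
  skel <- warp_mask(atlas$skeleton_mask, chain, patient_dwi)
  org <- warp_mask(atlas$organ_mask, chain, patient_dwi)
  skel_d <- dilate_mask(skel, params$skeleton_dilation_mm)
  org_d <- dilate_mask(org, params$organ_dilation_mm)
  region <- mask_subtract(skel_d, org_d)
  region$role <- "search_region"
  if (voxel_count(region) == 0)
    stop("search region empty - check registration")
  mmseg_log("search region: %d voxels (skeleton %d, organs removed %d)",
            voxel_count(region), voxel_count(skel_d),
            sum(skel_d$data & org_d$data))
  attr(region, "chain") <- chain
  region
}
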