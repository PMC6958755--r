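# mmseg

Semi-automatic segmentation of multiple-myeloma (MM) bone lesions on
whole-body diffusion-weighted MRI (WB-DWI), with ADC quantification and a
lesion-level validation toolkit.

## The problem

MM infiltrates the bone marrow at many sites at once. On high-b-value DWI the
lesions are bright, but so are several normal organs (spleen, kidneys, spinal
cord, bladder, testis), and manual slice-by-slice delineation of dozens of
lesions is slow and poorly reproducible between radiologists. `mmseg`
implements an atlas-guided detector for radiology and imaging researchers who
need total-lesion-burden segmentations and per-lesion ADC statistics without
manual contouring.

## The method

1. **Atlas propagation.** A mean DWI template with pre-drawn organ and
   skeleton masks is registered to the patient's high-b DWI (rigid, then
   affine, then cubic B-spline free-form deformation; mutual-information
   metric, 4 multi-resolution levels for the linear stages, one for the
   free-form, at most 255 optimizer iterations per stage). The masks follow
   the transform; organs are dilated by a 4 mm ball, the skeleton band by
   6 mm, and the search region is `dilate(skeleton, 6) − dilate(organs, 4)`.
2. **Quartile-outlier thresholding.** Inside the search region a voxel is a
   lesion candidate when

   `I ≥ Q3 + k (Q3 − Q1)`

   with Q1, Q3 the quartiles of the region's intensity distribution and `k`
   adjustable per patient (default 4, typical range 2.5–7.5). Candidates are
   split into 3D connected components (26-connectivity). No size criterion is
   applied.
3. **T1 false-positive filter.** The T1-weighted volume is rigidly aligned to
   the b = 0 DWI. A component is removed when the fraction of its voxels with
   T1 intensity above the mean psoas-muscle intensity reaches the cutoff
   (default 0.90, typical range 0.60–0.99) — MM lesions are at or below
   muscle intensity on T1, organs and fat are not.
4. **Quantification.** The ADC map follows the two-point mono-exponential
   model `ADC = −ln(S_i/S_0)/(b_i − b_0)` (mm²/s); each lesion gets volume
   and ADC histogram metrics (median, mean, 5th/25th/75th/95th percentiles,
   Fisher skewness and excess kurtosis).
5. **Validation.** Reader masks merge into a gold standard by majority vote
   (≥ 3 of 4). Agreement is measured by Dice; detection by lesion-level
   sensitivity and PPV under partial-overlap matching; measurement agreement
   by ICC(2,1) with its F-test.

A seeded synthetic whole-body phantom generator (paired high-b/b0 DWI and T1
volumes plus ground-truth masks) makes the whole pipeline testable end to end
without any patient data.

## Worked example

```r
library(mmseg)

# synthetic patient with 5 lesions and 2 T1-bright confounders,
# plus a lesion-free atlas phantom
atlas_pair <- generate_phantom_pair(phantom_spec(seed = 99, n_lesions = 0,
                                                 noise_sigma = 0))
atlas <- atlas_bundle(atlas_pair$dwi_high, atlas_pair$truth$organ_mask,
                      atlas_pair$truth$skeleton_mask)
pat <- generate_phantom_pair(phantom_spec(seed = 11, n_lesions = 5,
                                          n_confounders = 2))

res <- run_pipeline(pat$dwi_high, pat$dwi_b0, pat$t1, atlas,
                    pat$truth$psoas_mask, k = 4, t1_cutoff = 0.90,
                    cfg = registration_config(seed = 5))
match_lesions(res$components, connected_components(pat$truth$lesion_mask))
#> <detection_metrics> DSC 0.989 | sensitivity 1.000 (5/5) | PPV 1.000 (5/5)

match_lesions(res$candidates, connected_components(pat$truth$lesion_mask))
#> <detection_metrics> DSC 0.804 | sensitivity 1.000 (5/5) | PPV 0.714 (5/7)
```

The first matching is the full pipeline: every planted lesion found, nothing
false. The second is the same run before the T1 filter (the DWI-only mode):
the two T1-bright confounders survive thresholding and drag PPV down to 5/7 —
the filter is what removes them.

```r
adc <- compute_adc(pat$dwi_high, pat$dwi_b0, b_high = 800)
lesion_report(res$components, adc)[, c("id", "volume_ml", "median", "p25", "p75")]
#>          id volume_ml       median          p25          p75
#> 1         1     0.720 0.0008093010 0.0007708189 0.0008366007
#> 2         2     0.264 0.0008015942 0.0007807286 0.0008298187
#> 3         3     0.968 0.0007885097 0.0007635371 0.0008166857
#> 4         4     1.976 0.0007948000 0.0007644305 0.0008261423
#> 5         5     0.248 0.0008070675 0.0007787100 0.0008229965
#> 6 aggregate     4.176 0.0007974340 0.0007656496 0.0008262282
```

One row per lesion (volume in ml, ADC metrics in mm²/s) plus an aggregate
row over all lesions; the recovered medians sit on the phantom's planted
lesion ADC of 0.8×10⁻³ mm²/s.

A thin CLI wraps the same functions, e.g.

```sh
Rscript inst/cli/mmseg.R run --dwi-high hb.nii.gz --dwi-b0 b0.nii.gz \
  --t1 t1.nii.gz --atlas-dir atlas/ --psoas psoas.nii.gz \
  --k 4 --t1-cutoff 0.9 --out-dir out/
```

writing `lesions.nii.gz`, `lesions.csv` and `provenance.json`.

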