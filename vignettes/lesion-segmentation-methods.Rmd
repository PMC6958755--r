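---
title: "Atlas-guided MM lesion segmentation on WB-DWI: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-guided MM lesion segmentation on WB-DWI: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mmseg)
```

This vignette explains the models behind `mmseg`, the parameters that matter,
the numerical choices, and what the synthetic phantoms do and do not
demonstrate.

## The imaging model

Multiple-myeloma lesions are hypercellular bone-marrow infiltrates. On
high-b-value DWI they are bright; on T1-weighted spin echo they are at or
below muscle intensity; their apparent diffusion coefficient is low. Several
normal structures share the DWI brightness (spleen, kidneys, spinal cord,
bladder, testis), which is why brightness alone cannot segment lesions. The
pipeline encodes three facts:

* lesions live in (or within a few millimetres of) the skeleton,
* normally bright organs can be localised by an atlas and removed,
* anything bright on both DWI and T1 is not marrow infiltrate.

## Registration

`register_pair()` maps fixed-image physical coordinates to moving-image
coordinates through three composed stages — rigid (6 parameters), affine (12),
and a cubic B-spline free-form deformation — the standard coarse-to-fine
decomposition for whole-body alignment. Rigid and affine stages maximise
mutual information (MI) over a 4-level multi-resolution pyramid on a seeded
random sample of voxels (`n_samples`, default 15 000; `mi_bins`, default 32,
reduced automatically at coarse levels to keep roughly 30 samples per occupied
histogram cell). The optimiser is Nelder–Mead capped at `max_iterations`
(default 255) per stage and level, preceded by an exhaustive translation
search on a coarse level (±12 mm, 4 mm steps) and followed by a 1D
line-search polish of the translations at full resolution. The grid search
and polish exist because a simplex method started far from a narrow MI peak
can stall on a plateau; the combination recovered all tested rigid offsets up
to 10 mm per axis to well under 1 mm on phantoms.

The free-form stage runs at a single resolution on an isotropic control-point
grid (`ffd_grid_spacing_mm`, default 32 mm — coarse relative to whole-body
anatomy, cheap at desk scale, and sufficient because the subsequent mask
dilations absorb residual boundary error). It minimises the sum of squared
intensity differences with analytic gradients with respect to the
control-point displacements. SSD is appropriate here because the stage is
only used within-modality (DWI template to patient DWI); the multimodal
T1-to-b0 alignment is rigid-only and uses MI. Masks are warped with
nearest-neighbour interpolation so they stay strictly binary; intensity
images use linear interpolation, edge-clamped within half a voxel of the
volume border.

All stochastic pieces (metric sampling) derive from `cfg$seed`, so a chain is
bitwise reproducible.

## Atlas construction

`build_atlas()` iterates register-all-then-average, seeded by one
representative image, for `n_rounds` (default 3 — in practice the template
stops changing by then, and an `early_stop_tol` is available). Intensities
are averaged arithmetically without prior normalisation; a configurable
pre-normalisation hook was considered and left out because the phantom
cohorts only carry a few percent of intensity jitter, which the average
absorbs. Each round's mean image is resampled through the inverse of the
cohort-average linear transform (classic drift correction in iterative
template building). Without this, the template inherits the pose of the seed
image: registrations can be individually accurate while the template sits
several millimetres from the cohort's average pose, which is exactly what we
observed before adding the correction.

## Search region

`build_search_region()` computes
`dilate(warp(skeleton), 6 mm) − dilate(warp(organs), 4 mm)` on the patient
grid. The subtraction happens after both dilations, so organs are removed
with their full safety margin — the order matters and is deliberate: a lesion
adjacent to an organ is better lost to the margin than an organ voxel
admitted as a candidate. Dilation is a closed ball in physical millimetres
(voxel-centre distance ≤ radius), so anisotropic grids dilate by different
voxel counts per axis. Head exclusion is an atlas-authoring property (the
atlas skeleton mask simply ends below the head), not a runtime crop. An empty
region is an explicit error, since it almost always means a failed
registration.

## Lesion detection

The detector treats lesion intensities as upper outliers of the
search-region distribution: threshold `Q3 + k(Q3 − Q1)` with quartiles by
linear interpolation of order statistics (the ubiquitous type-7 convention;
the test oracle uses an independent sort-based implementation of the same
convention). Classic outlier screens use k = 1.5 or 3; marrow distributions
are tighter, and k defaults to 4 with a sensible range of 2.5–7.5 — this is
the "semi-automatic" dial, exposed per case in `run_pipeline()` and the CLI.
Quartiles are computed over search-region voxels only, not the full volume:
the threshold should reflect marrow statistics, not air or viscera. The
comparison is inclusive (≥). A zero interquartile range degenerates the
threshold to the constant value; the package warns and returns zero
components, because thresholding a constant region is meaningless.

Candidates are split by 26-connectivity: the most permissive connectivity,
chosen so a single lesion is never split across diagonal voxel chains. The T1 filter computes, per component, the fraction of voxels with
T1 intensity strictly above the mean psoas intensity and removes the
component when that fraction reaches the cutoff (default 0.90, range
0.60–0.99, again a per-case dial). Removal is all-or-nothing: the filter
never edits a surviving component's voxels, and no size criterion exists
anywhere. The psoas mask is an input (drawn manually or propagated from an
atlas); the reference muscle only needs to be low-fat and present on several
slices. An N4-style bias-correction hook can be injected ahead of the T1
alignment; the algorithm itself is delegated, not reimplemented.

A voxel-fraction reading of the filter is implemented; a variant comparing
single-lesion intensity percentiles against the psoas mean would be a
one-line change in `t1_component_filter()` and is deliberately not included.

## ADC quantification

`compute_adc()` inverts the two-point mono-exponential decay
`S_i = S_0 exp(−b · ADC)`; b-values are s/mm², ADC mm²/s. ADC is undefined
wherever either signal is non-positive — those voxels are flagged invalid
(NA), never ±Inf. Negative ADC values (noise pushing `S_i > S_0`) are kept by
default so histogram shape is unbiased; `clip_negative` exists for users who
want a physical floor. Histogram metrics use the same percentile convention
as the detector; skewness is Fisher g1 and kurtosis Fisher excess g2 (normal
distribution → 0), reported as NA below 3 values or at zero variance.

## Validation metrics

The gold standard is a voxelwise majority vote (≥ 3 of 4 readers by
default). Detection matching is lesion-level and overlap-based: one shared
voxel is enough, and every lesion or prediction counts once however many
partners it overlaps (so one blob covering two lesions detects both but is a
single correct prediction). Sensitivity and PPV with empty denominators are
undefined (NA), never 0. Dice is voxelwise on the binarised maps. The ICC is
the two-way random-effects, absolute-agreement, single-measures form
(ICC(2,1)) computed from ANOVA mean squares, with the subject-effect F-test;
the model choice is isolated in one function so another form can be swapped
in. Printed detection metrics are truncated toward zero at three decimals
(4/6 prints as 0.666); full precision is kept internally. Distribution
comparisons (e.g. Wilcoxon signed-rank between agreement samples) are
delegated to `stats::wilcox.test()`.

## The phantom generator

`generate_phantom_pair()` emulates exactly the properties the pipeline
relies on: an air background and a soft-tissue torso (elliptical cylinder); a
skeleton of a spine tube plus two leg tubes, ending below the head region; a
psoas-like reference box anterior to the spine, disjoint from the skeleton;
bright organ blobs (two kidneys, one bladder by default) more than 10 mm
clear of the skeleton at the default scale; lesion spheres (radius 4–8 mm)
placed by seeded rejection sampling strictly inside the skeleton, away from
organs and from each other; and optional confounder spheres inside the band
that are bright on both DWI and T1 — the cases only the T1 filter can reject.
Noise is Rician (magnitude MRI) by default, Gaussian on request for analytic
work.

Lesion DWI intensity is `marrow + contrast × 1.349 σ`, i.e. a fixed multiple
of the background IQR; the default contrast of 6 IQRs leaves the default
detector (k = 4) a comfortable margin (threshold ≈ Q3 + 4 IQR ≈ 4.7 IQR
above the median), and with σ = 0 a nominal σ of 5 keeps lesions visible in
noise-free phantoms. The b = 0 volume comes from the forward model
`S_0 = S_high · exp(b · ADC)` with per-tissue ADC values (lesions
0.8×10⁻³ mm²/s, marrow 0.7×10⁻³, soft tissue 1.5×10⁻³), so ADC estimation is
exact before noise injection. `generate_cohort()` adds per-subject noise
realisations, random rigid poses (up to a chosen translation scale, ±2°
rotations) and small multiplicative intensity jitter — enough to exercise
template building and mask propagation.

What the phantoms do **not** emulate: anatomy beyond tubes and blobs,
station-stitching artefacts, coil-profile hyperintensities at the field-of-view
edges (a real false-positive source), bias fields, partial-volume mixtures at
tissue interfaces, or heterogeneous lesions. Passing the detection criteria on
phantoms therefore demonstrates that the machinery is correct — thresholding,
mask algebra, registration, filtering, matching — not that clinical
performance on patient data would match; on real whole-body exams overlap
agreement is far lower for any segmentation method (manual ones included),
though the qualitative ordering holds: adding the T1 filter trades a little
sensitivity for better PPV.

## Problem sizes and numerical choices

* Default phantom: 96×64×160 voxels at 2 mm isotropic — a deliberately
  low-resolution whole-body scale so a full pipeline run (two registrations
  plus mask algebra) takes tens of seconds on one CPU.
* Test suite: detection recovery runs the full pipeline on 20 seeded
  default-size phantoms (3–8 lesions, 8 subjects with confounders, random
  poses up to 6 mm / 2°); registration and atlas properties use half-size
  phantoms (48×32×80) and 2 atlas rounds, which keeps the whole suite around
  20 minutes.
* Interpolation: linear for intensities, nearest-neighbour for masks; points
  within half a voxel outside a volume are edge-clamped, beyond that they
  take the moving image's minimum (treating out-of-field as background).
* Ties and determinism: component labels follow raster order of first
  voxels; all sampling is seed-derived; registration, phantom generation and
  the pipeline are bitwise reproducible given their seeds.
* Degenerate inputs fail loudly: non-3D or non-finite volumes, grid
  mismatches (no silent resampling anywhere), empty search regions, empty
  psoas masks, constant images in registration, quartiles of fewer than 4
  values.

## Known limitations

* The free-form stage's SSD metric assumes comparable intensity scales
  between template and patient; strong global intensity differences should
  be normalised upstream (the linear stages, using MI, are unaffected).
* Lesion-level matching accepts a single shared voxel as a detection;
  with very noisy predictions this flatters sensitivity — the phantom PPV
  criteria guard the other side.
* ICC(2,1) is the only implemented ICC form.
* The CLI reads whole volumes into memory; multi-station scanner output must
  be stitched into single volumes beforehand, which is out of scope.
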