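---
title: "Quantifying bilateral symmetry of paired bone surfaces"
author: "bisym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bilateral symmetry of paired bone surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

In preoperative 3D planning of tibial plateau fractures the mirrored,
unfractured contralateral tibia is used as a reduction template. That is only
valid if left and right tibial plateaus are near-mirror images of each other.
`bisym` implements the measurement that underlies this question: given
triangle meshes of a left and a right bone, how far apart are corresponding
surface points once one side is mirrored and optimally superimposed on the
other?

## The procedure

For one subject, `run_subject()` executes:

1. **Mirroring.** The left surface is reflected across a sagittal plane,
   converting left chirality to right. The plane itself is immaterial: any
   two reflections differ by a proper rigid motion, which the subsequent
   registration absorbs. The default plane passes through the centroid with
   its normal along the shortest principal axis of the vertex covariance; a
   user-supplied plane (`mirror_plane` in the configuration) is honoured.
2. **Rigid superimposition (full surfaces).** The mirrored surface is
   registered onto the contralateral surface with rigid Coherent Point Drift
   (CPD). CPD treats the moving points as centroids of an isotropic Gaussian
   mixture with one shared variance $\sigma^2$ plus a uniform outlier
   component of weight $w$, and alternates posterior correspondence
   probabilities (E-step) with closed-form updates of rotation, translation
   and $\sigma^2$ (M-step). The rotation update projects the SVD of the
   posterior-weighted cross-covariance onto $\det R = +1$: registration is
   never allowed to absorb a reflection — the chirality flip is exclusively
   the mirroring step's job.
3. **Cropping.** The long axis is the dominant principal axis of the fixed
   surface's vertex covariance, with its proximal sign fixed by requiring the
   wide (condylar) end to have the larger cross-sectional spread. Both
   surfaces are cut 15 mm below the tibial plateau (the maximum projection
   onto the axis) in an axial plane. One shared axis and level, measured on
   the fixed surface, is used for both crops so they cover the same
   anatomical band.
4. **Re-registration.** The cropped surfaces are registered again, so the
   alignment of the proximal region is not dragged by distal surface points
   outside the region of interest.
5. **Correspondence and summary.** Each vertex of the moving crop is matched
   to its nearest point on the fixed crop (point-to-triangle projection by
   default, nearest-vertex as an exactly testable alternative). The
   Euclidean distances, in mm, are summarised as mean, RMS, maximum (with
   its location) and percentiles, and attached to the moving crop as a
   per-vertex `distance_mm` heatmap field for PLY export.

`run_cohort()` repeats this over a manifest of pairs, aggregates per-subject
means into cohort mean, SD and SEM, and pools all point distances into Tukey
boxplot statistics. A failed subject is skipped and reported, never silently
dropped. Because the dispersion convention behind a published
"mean ± x" is often ambiguous, both SD and SEM are always written together
with `n`, so either reading can be checked.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `registration$w` | 0.1 | uniform outlier weight; absorbs segmentation debris (e.g. near the tibiofibular junction) |
| `registration$tolerance` | 1e-8 | relative change of the negative log-likelihood at which EM stops |
| `registration$max_iterations` | 150 | EM iteration cap |
| `registration$subsample_n` | 2000 | point budget per surface; vertices are used directly when they fit the budget, area-weighted surface samples beyond it |
| `registration$prealign` | TRUE | moment-based global seed (see below) |
| `registration$second_pass` | TRUE | re-registration of the crops |
| `crop$depth_mm` | 15 | cut depth below the plateau |
| `correspondence$mode` | "surface" | point-to-triangle vs nearest-vertex distances |
| `correspondence$mask_band_mm` | 0 | cut-edge exclusion band (0 = off) |

$\sigma^2$ is initialised from the mean squared distance between the two
point sets (parameter-free); scale fitting is off by default because a
similarity fit between two bones of the same subject could mask true size
asymmetry.

## Numerical choices

* **Global seeding of CPD.** EM is a local optimiser, and the mirror-plane
  convention can leave an arbitrarily large residual rotation (two distinct
  reflections compose to a rotation, often near 180°). The pipeline
  therefore seeds the first pass with a moment matching step: centroids and
  principal axes are aligned and the four proper sign assignments of the
  axes are scored by mean nearest-neighbour distance. This makes the whole
  report invariant (to within the registration accuracy floor) under
  arbitrary rigid motion of either input.
* **Variance collapse.** On clean, exactly corresponding clouds $\sigma^2$
  shrinks geometrically; it is clamped at $10^{-12}\,\mathrm{mm}^2$ and the
  fit marked converged. The E-step uses per-point log-sum-exp shifts so
  posteriors stay finite throughout the collapse.
* **Accuracy floor.** Noise-free transform recovery is exact to well below
  $10^{-3}$ mm point RMSE; $10^{-3}$ mm is quoted as the registration
  accuracy floor, and pose-invariance comparisons use twice that.
* **Crop semantics.** Faces crossing the cut plane are dropped, not split.
  This reproduces — deliberately — the open cut edge around which
  correspondence is ill-posed; the band mask in the correspondence stage
  exists to discount those artifacts explicitly rather than hide them.
  Summaries are always reported raw and masked.
* **Ties and degeneracies.** Eigen-decompositions use a fixed solver order;
  a spherical cloud has no preferred mirror plane but the call still
  succeeds (logged), while axis estimation refuses isotropic clouds unless
  a `proximal_hint` resolves the ambiguity.

## The synthetic validation cohort

No suitable paired bone meshes are publicly deposited, so validation runs on
a parametric generator (`generate_tibia()`): a tapering shaft blending into
a superellipse plateau with two smooth condylar elevations of unequal height
and an angularly offset tuberosity. The unequal condyles make the shape
genuinely chiral, as real tibias are — a property the tests witness by
showing that proper-rigid registration of a mesh onto its own mirror image
leaves a residual orders of magnitude above the symmetric baseline.

`make_bilateral_pair()` builds the left side as the exact mirror of the
right and then injects known asymmetry: localised patches (displacement
along the outward normal with a cosine falloff that reaches zero at the
patch radius, so no cut-like discontinuities are introduced), an optional
global scale offset, i.i.d. Gaussian vertex noise applied independently to
both surfaces at CT-voxel-scale defaults (0.1–0.4 mm), and a rigid
perturbation emulating scanner pose. The named patch site
`"medial_plateau_posterior"` resolves to an interior vertex of the posterior
medial plateau, pulled inward from the rim: at a rim corner the
nearest-feature assignment of point-to-surface distance is discontinuous,
and a defect placed there would measure its own corner geometry rather than
its magnitude.

**What the generator does not emulate.** Real CT-derived meshes carry
spatially smooth reconstruction error; i.i.d. per-vertex noise is rougher
at the mesh-edge scale. This matters most for extreme-value statistics: the
per-trial standard deviation of the reported maximum under i.i.d. noise on
both surfaces is about $1.3\sigma$. A recovery check asking the maximum to
sit within ±15% (±0.24 mm) of a 1.6 mm injected patch is therefore a
≥3-sigma test only for $\sigma \lesssim 0.06$ mm; the patch-recovery
experiments run at $\sigma = 0.05$ mm with a 2 mm cut-edge mask, while the
noise-floor experiments — whose target is the mean, not the maximum — run
at $\sigma = 0.3$ mm. Passing tests show the measurement machinery is
correct and unbiased; they do not certify behaviour on real segmentation
artifacts such as a fused tibiofibular joint, for which the spherical
exclusion regions exist.

**Problem sizes.** The test and acceptance runs use generator meshes at
resolution 2–3 (≈580–1300 vertices), 500-point clouds for the registration
recovery trials, 10–20 seeded trials per property, and cohorts of 12–20
synthetic subjects; these sizes make every stage's behaviour measurable
while keeping a full validation run in the minutes range on one CPU.

## Known limitations

* Correspondence is nearest-point, not probabilistic: the CPD posteriors are
  used only to produce the transform, because nearest-point correspondence
  is reproducible without the mixture internals.
* The long-axis heuristic assumes the proximal end is the wider one; heavily
  truncated or exotic inputs should pass an explicit axis.
* O(MN) EM and O(M·F) point-to-triangle scans are exact but quadratic;
  desk-scale meshes (≤ a few thousand points after subsampling) are the
  intended regime.
* Distances are reported from the mirrored (moving) surface to the fixed
  one; the reverse-direction mean is included as a diagnostic, and both are
  bounded by the symmetric Hausdorff distance.
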