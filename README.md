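# bisym — bilateral symmetry analysis of paired bone surface meshes

In preoperative 3D planning of tibial plateau fractures, the mirrored,
unfractured contralateral tibia is used as a reduction template for the
fractured side. Whether that is justified is a measurable question: after
mirroring one side and rigidly superimposing it on the other, how far apart
are corresponding surface points? `bisym` is an R package for exactly that
measurement on paired 3D triangle meshes (PLY/STL/OBJ, coordinates in mm),
aimed at orthopaedic and morphometrics researchers working with
CT/MRI-derived bone surfaces.

## Method

For a left/right pair the per-subject pipeline is:

1. mirror the left surface across a sagittal plane (chirality flip);
2. superimpose it on the right surface with **rigid Coherent Point Drift**
   (CPD): the moving points are Gaussian-mixture centroids with shared
   variance σ² plus a uniform outlier component of weight *w*; EM alternates
   posterior correspondences with closed-form rotation (SVD projected to
   det R = +1), translation and σ² updates;
3. cut both surfaces 15 mm below the tibial plateau in an axial plane
   (long axis and plateau level estimated on the right surface, shared by
   both crops);
4. re-register the cropped surfaces, so distal points cannot drag the
   proximal alignment;
5. match each moving vertex to its nearest point on the fixed crop and
   summarise the Euclidean distances d₁…dₙ (mm):
   mean, RMS = √(Σdᵢ²/n), maximum with location, percentiles — plus a
   per-vertex `distance_mm` heatmap field exported as PLY.

Cohorts are aggregated as mean ± SD (and SEM) of per-subject means plus
pooled Tukey boxplot statistics. Registration never performs a reflection —
a proper rotation cannot absorb chirality — and the reported distances are
invariant to the mirror-plane choice and to arbitrary rigid motion of either
input.

Because no paired bone meshes are publicly deposited, the package ships a
parametric generator of chiral proximal-tibia-like mesh pairs
(`make_bilateral_pair()`, `make_cohort()`) with known injected asymmetry
(localised patches, vertex noise, rigid perturbation) against which every
stage is validated.

## Worked example

Inject a known 1.6 mm defect on the posterior medial plateau of the left
side, plus 0.05 mm vertex noise and an arbitrary scanner pose, then measure
it back:

```r
library(bisym)
spec <- asymmetry_spec(
  patches = list(asym_patch("medial_plateau_posterior", radius = 8, magnitude = 1.6)),
  noise_sigma = 0.05,
  rigid_perturbation = random_rigid_transform(20, 10, seed = 2))
pair <- make_bilateral_pair(spec = spec, seed = 1)
report <- run_subject(pair$left, pair$right, run_config(seed = 1))
report
#> subject_symmetry_report 'subject': n = 397 correspondence points
#>   mean 0.0698 mm | RMS 0.1290 mm | max 1.6807 mm

pair$truth$displacement[report$max_vertex_input]
#> [1] 1.6
```

The surface is symmetric to within the noise floor (mean 0.07 mm) except at
the injected defect: the maximum distance (1.68 mm) sits at the vertex whose
true displacement was 1.6 mm. `write_mesh(report$heatmap, "heatmap.ply")`
exports the distance field for any mesh viewer; `write_subject_report()`
writes the full JSON report.

A shell interface wraps the same functions:

```sh
Rscript inst/cli/bisym.R simulate --subjects 5 --seed 1 --out cohort/
Rscript inst/cli/bisym.R compare --left L.ply --right R.ply --out rep.json --heatmap hm.ply
Rscript inst/cli/bisym.R cohort --manifest cohort/manifest.csv --out results/
```

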